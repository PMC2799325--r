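# Orchestration: tracks -> regions -> targets/PREs -> activity -> states,
# for one condition in memory, and file-to-file across conditions.

#' Call chromatin states for one condition
#'
#' Runs the full single-condition pipeline: replicate averaging and
#' smoothing per antibody, bound-region calling with per-antibody max-gap
#' parameters, PcG target-region definition (H3K27me3 + PC + E(Z)),
#' computational PREs with occupancy, joint ASH1/TRX N-ter domains, gene
#' activity (Pol II at TSS + H3K4me3 at +500), and the four-way state
#' classification.
#'
#' @param tracks Named list: antibody -> `probe_track` or list of replicate
#'   `probe_track`s (see [chip_antibodies] for the expected labels; absent
#'   antibodies contribute no evidence).
#' @param genes Annotation tibble (see [read_annotation()]).
#' @param params Per-antibody calling parameters ([default_call_params()]).
#' @param smoothing_window_bp Smoothing half-window (default 500).
#' @param pre_max_span Maximum PRE span (default 2000).
#' @param tss_window_bp TSS half-window for Pol II and evidence tests.
#' @param target_catalogue Gene ids that are PcG targets in any condition;
#'   defaults to the genes overlapping this condition's own target regions.
#'   Supply the cross-condition catalogue to make the "void" state callable.
#' @param condition Condition label stamped on the outputs.
#' @return A `state_call` list: `states` (per-gene calls + evidence),
#'   `regions` (per antibody), `target_regions`, `pres`, `ash1_domains`,
#'   `activity`, `smoothed` (per-antibody averaged smoothed tracks),
#'   `condition`, `log` (per-stage counts).
#' @export
call_chromatin_states <- function(tracks, genes,
                                  params = default_call_params(),
                                  smoothing_window_bp = 500,
                                  pre_max_span = 2000,
                                  tss_window_bp = 250,
                                  target_catalogue = NULL,
                                  condition = NA_character_) {
  smoothed <- list()
  regions <- list()
  for (ab in names(tracks)) {
    tr <- tracks[[ab]]
    if (is.data.frame(tr)) tr <- list(tr)
    avg <- average_replicates(tr)
    sm <- if (is_smoothed(avg)) avg else smooth_track(avg, smoothing_window_bp)
    p <- params[params$antibody == ab, ]
    if (nrow(p) == 0) p <- default_call_params(ab)
    smoothed[[ab]] <- sm
    regions[[ab]] <- call_bound_regions(sm,
      fold_cutoff = p$fold_cutoff[1],
      max_distance_bp = p$max_distance_bp[1],
      min_probes = p$min_probes[1]
    )
  }
  rset <- function(ab) regions[[ab]] %||% empty_regions()

  targets <- call_target_regions(rset("H3K27me3"), rset("PC"), rset("E(Z)"),
    genes = genes
  )
  pres <- define_computational_pres(rset("PC"), rset("E(Z)"),
    pre_max_span = pre_max_span,
    pc_track = smoothed[["PC"]], ez_track = smoothed[["E(Z)"]]
  )
  occ_abs <- intersect(c("PC", "E(Z)", "TRX-C", "TRX-N"), names(regions))
  pres <- pre_occupancy(pres, regions[occ_abs])
  ash1_domains <- ash1_trxN_domain_call(rset("ASH1"), rset("TRX-N"))

  if (is.null(smoothed[["H3K4me3"]])) {
    abort("An H3K4me3 track is required for activity calling.", class = "pcg_precondition")
  }
  activity <- call_gene_activity(rset("PolII"), smoothed[["H3K4me3"]], genes,
    tss_window_bp = tss_window_bp
  )
  own_targets <- if (nrow(targets) > 0) {
    unique(unlist(targets$genes))
  } else {
    character(0)
  }
  catalogue <- union(target_catalogue %||% character(0), own_targets)
  evidence <- build_evidence(genes, activity, regions,
    pres = pres, ash1_trxN = ash1_domains,
    target_catalogue = catalogue, tss_window_bp = tss_window_bp
  )
  states <- classify_state(evidence)
  res <- list(
    states = states, regions = regions, target_regions = targets,
    pres = pres, ash1_domains = ash1_domains, activity = activity,
    smoothed = smoothed, condition = condition,
    log = tibble(
      stage = c(
        "bound_regions", "target_regions", "pres", "genes_classified",
        "genes_unknown_activity"
      ),
      n = c(
        sum(vapply(regions, nrow, integer(1))), nrow(targets), nrow(pres),
        nrow(states), attr(states, "n_unclassified") %||% 0L
      )
    )
  )
  class(res) <- "state_call"
  res
}

#' @export
print.state_call <- function(x, ...) {
  counts <- table(x$states$state)
  cat(sprintf(
    "chromatin-state call (%s): %d genes [%s]; %d target regions, %d PREs\n",
    x$condition %||% "?", nrow(x$states),
    paste(names(counts), counts, sep = "=", collapse = ", "),
    nrow(x$target_regions), nrow(x$pres)
  ))
  invisible(x)
}

#' Run the file-to-file pipeline
#'
#' Reads the input manifest (condition -> antibody -> replicate track
#' files) and annotation, calls chromatin states per condition with the
#' cross-condition target catalogue, detects state changes between
#' conditions, and writes all outputs (per-antibody region BED, target
#' regions, PREs, state tables, change table) plus a run manifest (tool
#' version, configuration hash, input checksums, seed, timestamp) to
#' `out_dir`. Per-stage counts are logged to standard error.
#'
#' @param config A configuration list (see [read_pipeline_config()]), or a
#'   path to a YAML file.
#' @param quiet Suppress the standard-error log.
#' @return Invisibly, a named list of `state_call`s plus `changes` and the
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$conditions) || length(config$conditions) == 0) {
    abort("Empty input manifest.", class = "pcg_bad_config")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- read_annotation(config$annotation)
  params <- default_call_params()
  if (!is.null(config$fold_cutoff)) params$fold_cutoff <- config$fold_cutoff
  if (!is.null(config$min_probes)) params$min_probes <- config$min_probes
  if (!is.null(config$max_distance_bp)) {
    for (ab in names(config$max_distance_bp)) {
      params$max_distance_bp[params$antibody == ab] <- config$max_distance_bp[[ab]]
    }
  }

  # two passes so that every condition sees the cross-condition catalogue
  calls <- list()
  for (cond in names(config$conditions)) {
    say("[%s] reading tracks", cond)
    tracks <- lapply(names(config$conditions[[cond]]), function(ab) {
      paths <- config$conditions[[cond]][[ab]]
      lapply(seq_along(paths), function(i) {
        read_track(paths[[i]],
          antibody = ab, condition = cond,
          replicate = paste0("rep", i)
        )
      })
    })
    names(tracks) <- names(config$conditions[[cond]])
    calls[[cond]] <- withCallingHandlers(
      call_chromatin_states(tracks, genes,
        params = params,
        smoothing_window_bp = config$smoothing_window_bp %||% 500,
        pre_max_span = config$pre_max_span %||% 2000,
        tss_window_bp = config$tss_window_bp %||% 250,
        condition = cond
      ),
      error = function(e) {
        abort(sprintf("Pipeline stage failed in condition '%s': %s", cond, conditionMessage(e)),
          class = "pcg_stage_error", parent = e
        )
      }
    )
  }
  catalogue <- unique(unlist(lapply(calls, function(x) {
    if (nrow(x$target_regions) > 0) unlist(x$target_regions$genes) else character(0)
  })))
  if (length(calls) > 1) {
    for (cond in names(calls)) {
      calls[[cond]]$states <- classify_state(build_evidence(
        genes, calls[[cond]]$activity, calls[[cond]]$regions,
        pres = calls[[cond]]$pres, ash1_trxN = calls[[cond]]$ash1_domains,
        target_catalogue = catalogue,
        tss_window_bp = config$tss_window_bp %||% 250
      ))
    }
  }

  for (cond in names(calls)) {
    x <- calls[[cond]]
    for (ab in names(x$regions)) {
      write_regions_bed(
        x$regions[[ab]],
        file.path(out_dir, sprintf("%s_regions_%s.bed", cond, sanitize_ab(ab)))
      )
    }
    tr_out <- x$target_regions
    tr_out$genes <- vapply(
      tr_out$genes %||% list(),
      function(g) paste(g, collapse = ","), character(1)
    )
    write_regions_bed(tr_out, file.path(out_dir, sprintf("%s_target_regions.bed", cond)))
    write_regions_bed(x$pres, file.path(out_dir, sprintf("%s_pres.bed", cond)))
    write_states(x$states, genes,
      file.path(out_dir, sprintf("%s_states.tsv", cond)),
      condition = cond,
      bed_path = file.path(out_dir, sprintf("%s_states.bed", cond))
    )
    for (row in seq_len(nrow(x$log))) {
      say("[%s] %s: %d", cond, x$log$stage[row], x$log$n[row])
    }
  }
  changes <- NULL
  if (length(calls) > 1) {
    states_by_cond <- lapply(calls, function(x) x$states)
    changes <- detect_changes(states_by_cond)
    readr::write_tsv(changes, file.path(out_dir, "state_changes.tsv"))
    say(
      "changes %s -> %s: %d", names(calls)[1], names(calls)[2],
      nrow(changes)
    )
  }
  manifest <- list(
    tool = "pcgstates",
    version = as.character(packageVersion("pcgstates")),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    inputs = as.list(tools::md5sum(c(
      config$annotation,
      unlist(config$conditions, use.names = FALSE)
    ))),
    seed = config$seed %||% NA,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(calls, list(changes = changes, manifest = manifest)))
}
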