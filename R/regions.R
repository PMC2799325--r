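# Interval helpers ------------------------------------------------------
#
# Regions are tibbles with chrom/start/end in 0-based half-open coordinates.
# Overlap arithmetic is delegated to GenomicRanges (1-based closed), so the
# conversion is start + 1 on the way in.

regions_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

gr_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

# Logical: does each row of `a` overlap (>= min_overlap_bp) any row of `b`?
overlaps_any <- function(a, b, min_overlap_bp = 1L) {
  if (nrow(a) == 0) {
    return(logical(0))
  }
  if (is.null(b) || nrow(b) == 0) {
    return(rep(FALSE, nrow(a)))
  }
  # the seqlevel-mismatch warning only says some chromosomes appear in one
  # set but not the other, which is ordinary input here
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    regions_gr(a), regions_gr(b),
    minoverlap = min_overlap_bp
  ))
  seq_len(nrow(a)) %in% S4Vectors::queryHits(hits)
}

# Intersection of the unions of two region sets, as a sorted disjoint tibble.
intersect_regions <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(regions_gr(a)),
    GenomicRanges::reduce(regions_gr(b))
  )
  gr_tbl(GenomicRanges::sort(gr))
}

merge_regions <- function(df) {
  if (nrow(df) == 0) {
    return(df[, c("chrom", "start", "end")])
  }
  gr_tbl(GenomicRanges::sort(GenomicRanges::reduce(regions_gr(df))))
}

empty_regions <- function(antibody = NA_character_, condition = NA_character_) {
  tibble(
    chrom = character(), start = numeric(), end = numeric(),
    n_probes = integer(), score = numeric(),
    antibody = character(0), condition = character(0)
  )
}

# Bound-region calling ---------------------------------------------------

#' Call bound regions from a smoothed track (max-gap/min-run segmentation)
#'
#' A probe qualifies when its smoothed fold ratio is at or above
#' `fold_cutoff` (the two-fold enrichment criterion by default). Maximal runs
#' of qualifying probes whose successive gaps are at most `max_distance_bp`
#' form candidate regions; candidates with fewer than `min_probes` probes are
#' discarded. The region span is `[first probe start, last probe start +
#' probe_step)`, and each region is scored with [region_enrichment()].
#'
#' @param track A smoothed `probe_track` (calling on unsmoothed ratios is a
#'   precondition error).
#' @param fold_cutoff Linear enrichment cutoff (> 1), default 2.
#' @param max_distance_bp Largest gap (bp) between qualifying probe starts
#'   joined into one region. See [default_call_params()] for per-antibody
#'   defaults.
#' @param min_probes Minimum qualifying probes per region, default 4.
#' @param k Probes per scoring window passed to [region_enrichment()].
#' @param probe_step_bp Probe spacing used to close the final half-open
#'   interval; inferred from the median inter-probe distance when `NULL`.
#' @return A sorted tibble of disjoint regions: `chrom`, `start`, `end`,
#'   `n_probes`, `score`, `antibody`, `condition`.
#' @export
call_bound_regions <- function(track, fold_cutoff = 2, max_distance_bp = 500,
                               min_probes = 4L, k = 6L, probe_step_bp = NULL) {
  stop_if_not_track(track)
  if (!is_smoothed(track)) {
    abort("call_bound_regions() requires a smoothed track.", class = "pcg_precondition")
  }
  if (fold_cutoff <= 1) abort("`fold_cutoff` must be > 1.", class = "pcg_bad_params")
  if (max_distance_bp < 0) abort("`max_distance_bp` must be >= 0.", class = "pcg_bad_params")
  if (min_probes < 1) abort("`min_probes` must be >= 1.", class = "pcg_bad_params")

  meta <- track_meta(track)
  pieces <- list()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    pos <- track$pos[sel]
    val <- track$value[sel]
    step <- probe_step_bp %||%
      (if (length(pos) > 1) median(diff(pos)) else 1)
    q <- which(!is.na(val) & val >= fold_cutoff)
    if (length(q) == 0) next
    run_id <- cumsum(c(1, as.integer(diff(pos[q]) > max_distance_bp)))
    runs <- split(q, run_id)
    runs <- runs[lengths(runs) >= min_probes]
    if (length(runs) == 0) next
    start <- unname(vapply(runs, function(r) pos[r[1]], numeric(1)))
    last <- unname(vapply(runs, function(r) pos[r[length(r)]], numeric(1)))
    end <- last + step
    # keep regions disjoint even if the gap between runs is below probe_step
    if (length(end) > 1) end <- pmin(end, c(start[-1], Inf))
    pieces[[ch]] <- tibble(
      chrom = ch, start = start, end = end,
      n_probes = unname(lengths(runs))
    )
  }
  if (length(pieces) == 0) {
    return(empty_regions())
  }
  out <- bind_rows(pieces) |> arrange(.data$chrom, .data$start)
  out$score <- score_regions(track, out, k = k)
  out$antibody <- meta$antibody
  out$condition <- meta$condition
  out
}

#' Keep regions confirmed by a second (independent-antibody) region set
#'
#' Retains regions of `set_a` that overlap at least `min_overlap_bp` with
#' some region of `set_b`, keeping the `set_a` coordinates. Used to form the
#' dual-antibody consensus (e.g. rabbit and rat anti-ASH1): only sites
#' detected by both antibodies survive.
#'
#' @param set_a,set_b Region tibbles (`chrom`, `start`, `end`, ...).
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return The confirmed subset of `set_a`.
#' @export
consensus_regions <- function(set_a, set_b, min_overlap_bp = 1L) {
  set_a[overlaps_any(set_a, set_b, min_overlap_bp), , drop = FALSE]
}

# Target regions and PREs -------------------------------------------------

#' Define PcG target regions (Class I / Class II)
#'
#' Each H3K27me3 domain is classified Class I when some position inside it is
#' covered by overlapping PC and E(Z) bound regions (a PC+E(Z) co-binding
#' site), Class II when a PC region overlaps the domain but no E(Z) region
#' does ("little or no detectable E(Z)" operationalised as zero overlapping
#' E(Z) regions at the standard cutoff), and is otherwise not a target region
#' (returned only when `keep_unclassified = TRUE`, with `class_label = NA`).
#'
#' @param h3k27me3 H3K27me3 domain tibble (from [call_bound_regions()]).
#' @param pc,ez PC and E(Z) bound-region tibbles from the same condition.
#' @param genes Optional gene annotation; when given, overlapping gene ids
#'   are attached as a list-column.
#' @param keep_unclassified Keep H3K27me3 domains with no PC for diagnostics.
#' @return A tibble of target regions with `class_label` ("I"/"II").
#' @export
call_target_regions <- function(h3k27me3, pc, ez, genes = NULL,
                                keep_unclassified = FALSE) {
  if (nrow(h3k27me3) == 0) {
    out <- tibble(
      chrom = character(), start = numeric(), end = numeric(),
      class_label = character(), condition = character()
    )
    return(out)
  }
  co_sites <- intersect_regions(pc, ez)
  class1 <- overlaps_any(h3k27me3, co_sites)
  has_pc <- overlaps_any(h3k27me3, pc)
  has_ez <- overlaps_any(h3k27me3, ez)
  label <- case_when(
    class1 ~ "I",
    has_pc & !has_ez ~ "II",
    TRUE ~ NA_character_
  )
  out <- h3k27me3 |>
    mutate(class_label = label) |>
    select("chrom", "start", "end", "class_label", dplyr::any_of(c("condition", "score", "n_probes")))
  if (!keep_unclassified) out <- out[!is.na(out$class_label), , drop = FALSE]
  if (!is.null(genes) && nrow(out) > 0) {
    hits <- GenomicRanges::findOverlaps(regions_gr(out), regions_gr(genes))
    out$genes <- lapply(seq_len(nrow(out)), function(i) {
      genes$gene_id[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
    })
  }
  arrange(out, .data$chrom, .data$start)
}

#' Define computational PREs from PC and E(Z) co-binding
#'
#' Every non-empty intersection interval between the PC and E(Z) bound-region
#' sets yields one candidate PRE. Its summit is the probe with the maximal
#' joint signal, min(PC, E(Z)) of the smoothed ratios, when the two tracks
#' are supplied (interval midpoint otherwise). Intervals longer than
#' `pre_max_span` are trimmed to `pre_max_span` centred on the summit;
#' intervals overlapping after trimming are merged (the merged summit is the
#' best summit of its parts).
#'
#' @param pc,ez Bound-region tibbles for PC and E(Z) in one condition.
#' @param pre_max_span Maximum PRE span in bp (default 2000; PREs are narrow
#'   elements).
#' @param pc_track,ez_track Optional smoothed tracks used to place summits.
#' @return A sorted tibble of non-overlapping PREs: `chrom`, `start`, `end`,
#'   `summit`, `source_condition`.
#' @export
define_computational_pres <- function(pc, ez, pre_max_span = 2000,
                                      pc_track = NULL, ez_track = NULL) {
  condition <- if (nrow(pc) > 0 && "condition" %in% names(pc)) pc$condition[1] else NA_character_
  iv <- intersect_regions(pc, ez)
  if (nrow(iv) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      summit = numeric(), source_condition = character()
    ))
  }
  iv$summit <- pre_summits(iv, pc_track, ez_track)
  # trim long intervals to pre_max_span centred on the summit
  long <- (iv$end - iv$start) > pre_max_span
  if (any(long)) {
    half <- pre_max_span / 2
    s <- pmax(iv$start[long], iv$summit[long] - half)
    e <- pmin(iv$end[long], s + pre_max_span)
    s <- pmax(iv$start[long], e - pre_max_span)
    iv$start[long] <- s
    iv$end[long] <- e
  }
  iv <- arrange(iv, .data$chrom, .data$start)
  # merge any overlaps introduced by trimming, keeping the strongest summit
  merged <- merge_regions(iv)
  hits <- GenomicRanges::findOverlaps(regions_gr(merged), regions_gr(iv))
  joint <- joint_signal_at(iv$summit, iv$chrom, pc_track, ez_track)
  merged$summit <- vapply(seq_len(nrow(merged)), function(i) {
    members <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    best <- members[which.max(joint[members] %||% 1)]
    iv$summit[best]
  }, numeric(1))
  merged$source_condition <- condition
  merged
}

# Summit per interval: probe position maximising min(PC, E(Z)) smoothed
# ratio; interval midpoint (probe-free fallback) when tracks are absent.
pre_summits <- function(iv, pc_track, ez_track) {
  mid <- floor((iv$start + iv$end) / 2)
  if (is.null(pc_track) || is.null(ez_track)) {
    return(mid)
  }
  out <- mid
  for (ch in unique(iv$chrom)) {
    sel <- which(pc_track$chrom == ch)
    pos <- pc_track$pos[sel]
    if (length(pos) == 0) next
    esel <- which(ez_track$chrom == ch)
    if (!isTRUE(all.equal(ez_track$pos[esel], pos))) {
      abort("PC and E(Z) tracks must share a probe grid for summit calling.",
        class = "pcg_grid_mismatch"
      )
    }
    joint <- pmin(pc_track$value[sel], ez_track$value[esel])
    for (i in which(iv$chrom == ch)) {
      idx <- probes_in_interval(pos, iv$start[i], iv$end[i])
      if (length(idx) == 0) next
      out[i] <- pos[idx[which.max(joint[idx])]]
    }
  }
  out
}

joint_signal_at <- function(summit, chrom, pc_track, ez_track) {
  if (is.null(pc_track) || is.null(ez_track)) {
    return(rep(1, length(summit)))
  }
  vapply(seq_along(summit), function(i) {
    sel <- which(pc_track$chrom == chrom[i] & pc_track$pos == summit[i])
    esel <- which(ez_track$chrom == chrom[i] & ez_track$pos == summit[i])
    if (length(sel) == 0 || length(esel) == 0) {
      return(1)
    }
    min(pc_track$value[sel[1]], ez_track$value[esel[1]])
  }, numeric(1))
}

#' Flag PRE occupancy by each antibody
#'
#' A PRE is occupied by an antibody when any bound region of that antibody
#' overlaps the PRE interval. Occupancy flags are added as `occ_<antibody>`
#' columns; catalogue-wide occupied fractions are attached as the
#' `"fractions"` attribute (also available via [pre_occupancy_summary()]).
#'
#' @param pres A PRE tibble from [define_computational_pres()].
#' @param regions_by_antibody Named list of bound-region tibbles.
#' @return `pres` with one logical `occ_*` column per antibody.
#' @export
pre_occupancy <- function(pres, regions_by_antibody) {
  for (ab in names(regions_by_antibody)) {
    pres[[paste0("occ_", sanitize_ab(ab))]] <-
      overlaps_any(pres, regions_by_antibody[[ab]])
  }
  fr <- vapply(names(regions_by_antibody), function(ab) {
    col <- pres[[paste0("occ_", sanitize_ab(ab))]]
    if (length(col) == 0) NA_real_ else mean(col)
  }, numeric(1))
  attr(pres, "fractions") <- tibble(
    antibody = names(regions_by_antibody),
    fraction_occupied = unname(fr)
  )
  pres
}

#' @rdname pre_occupancy
#' @export
pre_occupancy_summary <- function(pres) {
  attr(pres, "fractions") %||%
    abort("No occupancy fractions; run pre_occupancy() first.", class = "pcg_precondition")
}

sanitize_ab <- function(x) {
  tolower(gsub("[^A-Za-z0-9]+", "_", gsub("[()]", "", x)))
}

#' Merge PRE catalogues across conditions
#'
#' Overlapping PREs from different conditions are merged into one catalogue
#' entry; `source_condition` records every contributing condition
#' (comma-separated). This supports querying, e.g., TRX occupancy of a PRE in
#' conditions where PcG proteins are absent.
#'
#' @param per_condition Named list (condition -> PRE tibble).
#' @return The merged catalogue with `source_condition` and `summit` (from
#'   the first contributing condition, by name order).
#' @export
catalogue_pres_across_conditions <- function(per_condition) {
  if (length(per_condition) == 0) {
    abort("At least one condition is required.", class = "pcg_empty_input")
  }
  pooled <- bind_rows(lapply(names(per_condition), function(cn) {
    df <- per_condition[[cn]]
    if (nrow(df) == 0) {
      return(NULL)
    }
    df$source_condition <- cn
    df
  }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      summit = numeric(), source_condition = character()
    ))
  }
  merged <- merge_regions(pooled)
  hits <- GenomicRanges::findOverlaps(regions_gr(merged), regions_gr(pooled))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  merged$summit <- vapply(seq_len(nrow(merged)), function(i) {
    members <- sh[qh == i]
    pooled$summit[members[1]] %||% floor((merged$start[i] + merged$end[i]) / 2)
  }, numeric(1))
  merged$source_condition <- vapply(seq_len(nrow(merged)), function(i) {
    paste(sort(unique(pooled$source_condition[sh[qh == i]])), collapse = ",")
  }, character(1))
  merged
}
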