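# Readers/writers. Internal coordinates are 0-based half-open everywhere;
# WIG and GFF3 (1-based) are converted at the boundary. bedGraph and BED6+
# go through readr; WIG and GFF3 through rtracklayer.

#' Read a probe track from bedGraph or WIG
#'
#' bedGraph is read as a 0-based half-open four-column table; WIG (fixed or
#' variable step, 1-based) is imported via \pkg{rtracklayer} and converted,
#' so a `fixedStep start=1` first probe lands at internal position 0.
#' Probes are sorted; duplicate positions are a parse error reporting the
#' offending line.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"bedgraph"` or `"wig"`.
#' @param antibody,condition,replicate Metadata stamped on the track.
#' @param smoothed Whether the file holds smoothed ratios.
#' @return A `probe_track`.
#' @export
read_track <- function(path, format = c("auto", "bedgraph", "wig"),
                       antibody = NA_character_, condition = NA_character_,
                       replicate = NA_character_, smoothed = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedgraph"
  }
  if (format == "bedgraph") {
    lines <- readLines(path)
    body <- !grepl("^(track|#|browser)", lines) & nzchar(trimws(lines))
    fields <- strsplit(trimws(lines[body]), "\\s+")
    nf <- lengths(fields)
    if (any(nf != 4)) {
      bad <- which(body)[which(nf != 4)[1]]
      abort(sprintf("Malformed bedGraph line %d in %s (expected 4 fields).", bad, path),
        class = "pcg_parse_error"
      )
    }
    m <- do.call(rbind, fields)
    start <- suppressWarnings(as.numeric(m[, 2]))
    end <- suppressWarnings(as.numeric(m[, 3]))
    value <- suppressWarnings(as.numeric(m[, 4]))
    if (anyNA(start) || anyNA(end)) {
      bad <- which(body)[which(is.na(start) | is.na(end))[1]]
      abort(sprintf("Malformed bedGraph line %d in %s (non-numeric coordinate).", bad, path),
        class = "pcg_parse_error"
      )
    }
    df <- tibble(chrom = m[, 1], pos = start, value = value)
  } else {
    gr <- rtracklayer::import(path, format = "wig")
    df <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      pos = GenomicRanges::start(gr) - 1,
      value = gr$score
    )
  }
  dup <- duplicated(df[, c("chrom", "pos")])
  if (any(dup)) {
    abort(sprintf(
      "Duplicate probe position %s:%d in %s.",
      df$chrom[dup][1], df$pos[dup][1], path
    ), class = "pcg_parse_error")
  }
  df <- arrange(df, .data$chrom, .data$pos)
  new_probe_track(df,
    antibody = antibody, condition = condition,
    replicate = replicate, smoothed = smoothed, validate = TRUE
  )
}

#' Write a probe track as bedGraph
#'
#' Probes are written as `[pos, pos + step)` intervals, where `step` is the
#' probe spacing (inferred from the median inter-probe distance when not
#' given). Reading the file back yields the identical track.
#'
#' @param track A `probe_track`.
#' @param path Output path.
#' @param probe_step_bp Interval width; inferred when `NULL`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, probe_step_bp = NULL) {
  stop_if_not_track(track)
  step <- probe_step_bp %||%
    (if (nrow(track) > 1) median(diff(track$pos)) else 1)
  readr::write_tsv(
    tibble(
      chrom = track$chrom,
      start = format(track$pos, scientific = FALSE, trim = TRUE),
      end = format(track$pos + step, scientific = FALSE, trim = TRUE),
      value = track$value
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read a gene/transcription-unit annotation from GFF3
#'
#' Imports `gene` features (falling back to `mRNA` when no genes are
#' present), converts the 1-based closed GFF coordinates to internal 0-based
#' half-open, and derives the strand-aware TSS: a + strand gene at GFF
#' 100-200 has its TSS at internal position 99; a - strand gene at its end
#' coordinate. Strandless features are an error naming the feature.
#'
#' @param path GFF3 file path.
#' @return A tibble: `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type == "gene"
  if (!any(keep)) keep <- type == "mRNA"
  gr <- gr[keep]
  if (length(gr) == 0) {
    abort(sprintf("No gene/mRNA features found in %s.", path), class = "pcg_parse_error")
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids)) ids <- paste0("feature_", seq_along(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    abort(sprintf(
      "Strandless gene '%s' in %s.",
      ids[strand == "*"][1], path
    ), class = "pcg_parse_error")
  }
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- as.numeric(GenomicRanges::end(gr))
  tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0, strand = strand,
    tss = ifelse(strand == "-", end0 - 1, start0)
  ) |> arrange(.data$chrom, .data$start)
}

#' Write an annotation tibble as GFF3
#'
#' @param genes Annotation tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$source <- "pcgstates"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write/read region tables as BED6 with extra columns
#'
#' BED6 layout (chrom, start, end, name, score, strand) plus any further
#' columns of the tibble, so that `read_regions_bed()` restores the table
#' losslessly. Region names default to `region_<i>`; score is the
#' enrichment score (0 when absent); strand is ".".
#'
#' @param regions A region tibble.
#' @param path File path.
#' @return `write_regions_bed()` returns `path` invisibly;
#'   `read_regions_bed()` the restored tibble.
#' @export
write_regions_bed <- function(regions, path) {
  extra <- setdiff(names(regions), c("chrom", "start", "end", "score"))
  out <- tibble(
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    name = if ("name" %in% names(regions)) {
      regions$name
    } else if (nrow(regions) > 0) {
      paste0("region_", seq_len(nrow(regions)))
    } else {
      character(0)
    },
    score = if ("score" %in% names(regions)) regions$score else rep(0, nrow(regions)),
    strand = if ("strand" %in% names(regions)) regions$strand else rep(".", nrow(regions))
  )
  for (col in setdiff(extra, c("name", "strand"))) out[[col]] <- regions[[col]]
  readr::write_tsv(out, path, col_names = TRUE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write state calls as a delimited table and as coloured BED
#'
#' The table holds gene id, condition, state and the evidence booleans; the
#' optional BED9 companion colours genes by state for browser inspection
#' (repressed blue, active green, balanced orange, void grey, other black).
#'
#' @param states Output of [classify_state()].
#' @param genes Annotation tibble (for coordinates in the BED output).
#' @param path Output TSV path.
#' @param condition Condition label written into the table.
#' @param bed_path Optional BED9 output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, genes, path, condition = NA_character_,
                         bed_path = NULL) {
  tab <- states
  tab$condition <- condition
  readr::write_tsv(tab, path)
  if (!is.null(bed_path)) {
    colors <- c(
      repressed = "0,0,180", active = "0,150,0", balanced = "230,140,0",
      void = "140,140,140", other = "0,0,0"
    )
    g <- genes[match(states$gene_id, genes$gene_id), ]
    bed <- tibble(
      chrom = g$chrom, start = g$start, end = g$end,
      name = paste0(states$gene_id, "|", states$state),
      score = 0, strand = g$strand,
      thickStart = g$start, thickEnd = g$end,
      itemRgb = unname(colors[states$state])
    )
    readr::write_tsv(bed, bed_path, col_names = FALSE)
  }
  invisible(path)
}

#' Read and validate a pipeline configuration (YAML)
#'
#' The configuration names the annotation file, an input manifest
#' (condition -> antibody -> replicate file paths), the output directory and
#' optional parameter overrides (`fold_cutoff`, `smoothing_window_bp`,
#'   `seed`, per-antibody `max_distance_bp`). Unknown top-level keys are
#' rejected and every referenced file must exist at load time.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c(
    "annotation", "conditions", "out_dir", "fold_cutoff",
    "smoothing_window_bp", "min_probes", "max_distance_bp",
    "pre_max_span", "tss_window_bp", "seed"
  )
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s.", paste(unknown, collapse = ", ")),
      class = "pcg_bad_config"
    )
  }
  if (is.null(cfg$conditions) || length(cfg$conditions) == 0) {
    abort("Configuration must list at least one condition.", class = "pcg_bad_config")
  }
  files <- c(cfg$annotation, unlist(cfg$conditions, use.names = FALSE))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    abort(sprintf("Input file(s) not found: %s.", paste(missing, collapse = ", ")),
      class = "pcg_bad_config"
    )
  }
  cfg
}
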