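#' Build a probe-level signal track
#'
#' A probe track is a tibble with columns `chrom`, `pos` (0-based probe start
#' coordinate) and `value` (linear-scale ChIP/Input fold ratio), carrying the
#' antibody, condition, replicate and smoothing status as attributes.
#' Positions must be strictly increasing within each chromosome and values
#' must be positive; `NA`/`NaN` marks a missing probe.
#'
#' @param chrom Chromosome name per probe (recycled if length 1).
#' @param pos Integer probe start coordinates, 0-based.
#' @param value Linear-scale fold ratios (> 0, or `NA` for missing probes).
#' @param antibody,condition,replicate Labels attached as track metadata.
#' @param smoothed Logical; whether `value` already holds smoothed ratios.
#' @return A `probe_track` tibble.
#' @examples
#' probe_track("chr2L", seq(0, 360, 36), rep(1, 11), antibody = "PC")
#' @export
probe_track <- function(chrom, pos, value,
                        antibody = NA_character_,
                        condition = NA_character_,
                        replicate = NA_character_,
                        smoothed = FALSE) {
  df <- tibble(
    chrom = as.character(rep_len(chrom, length(pos))),
    pos = as.numeric(pos),
    value = as.numeric(value)
  )
  new_probe_track(df,
    antibody = antibody, condition = condition,
    replicate = replicate, smoothed = smoothed, validate = TRUE
  )
}

new_probe_track <- function(df, antibody = NA_character_,
                            condition = NA_character_,
                            replicate = NA_character_,
                            smoothed = FALSE, validate = FALSE) {
  if (validate) {
    if (length(df$pos) != length(df$value)) {
      abort("`pos` and `value` must have the same length.", class = "pcg_bad_track")
    }
    ord <- order(df$chrom, df$pos)
    if (is.unsorted(ord)) df <- df[ord, ]
    bad <- unlist(lapply(split(df$pos, df$chrom), function(p) any(diff(p) <= 0)))
    if (any(bad)) {
      abort("Probe positions must be strictly increasing within each chromosome.",
        class = "pcg_bad_track"
      )
    }
    neg <- !is.na(df$value) & df$value <= 0
    if (any(neg)) {
      abort(
        sprintf("Fold ratios must be positive; %d probe(s) are <= 0.", sum(neg)),
        class = "pcg_bad_track"
      )
    }
  }
  structure(
    df,
    class = c("probe_track", class(tibble())),
    antibody = antibody, condition = condition,
    replicate = replicate, smoothed = isTRUE(smoothed)
  )
}

#' Track metadata accessors
#'
#' @param track A `probe_track`.
#' @return `track_meta()` returns a one-row tibble with the antibody,
#'   condition, replicate and smoothing status; `is_smoothed()` a logical.
#' @export
track_meta <- function(track) {
  tibble(
    antibody = attr(track, "antibody") %||% NA_character_,
    condition = attr(track, "condition") %||% NA_character_,
    replicate = attr(track, "replicate") %||% NA_character_,
    smoothed = isTRUE(attr(track, "smoothed"))
  )
}

#' @rdname track_meta
#' @export
is_smoothed <- function(track) isTRUE(attr(track, "smoothed"))

stop_if_not_track <- function(track) {
  if (!is.data.frame(track) ||
    !all(c("chrom", "pos", "value") %in% names(track))) {
    abort("Expected a probe track with columns chrom, pos, value.",
      class = "pcg_bad_track"
    )
  }
  invisible(track)
}

#' Average replicate tracks on a shared probe grid
#'
#' Per-probe geometric mean of the linear fold ratios (arithmetic mean in log
#' space), so that ratios symmetric around 1 average to 1. A missing probe in
#' any replicate yields a missing probe in the average.
#'
#' @param tracks A list of `probe_track`s on identical probe grids (same
#'   chromosomes and positions).
#' @return A `probe_track` with `replicate = "averaged"`.
#' @examples
#' a <- probe_track("chr2L", c(0, 36), c(2, 2))
#' b <- probe_track("chr2L", c(0, 36), c(8, 8))
#' average_replicates(list(a, b))$value # 4 4
#' @export
average_replicates <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  if (length(tracks) == 0) {
    abort("At least one replicate track is required.", class = "pcg_empty_input")
  }
  lapply(tracks, stop_if_not_track)
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (nrow(t) != nrow(ref) ||
      !identical(t$chrom, ref$chrom) || !isTRUE(all.equal(t$pos, ref$pos))) {
      abort("Replicate tracks are on different probe grids.",
        class = "pcg_grid_mismatch"
      )
    }
  }
  logs <- vapply(tracks, function(t) log(t$value), numeric(nrow(ref)))
  if (is.null(dim(logs))) logs <- matrix(logs, nrow = nrow(ref))
  avg <- exp(rowMeans(logs)) # NA in any replicate propagates
  new_probe_track(
    tibble(chrom = ref$chrom, pos = ref$pos, value = avg),
    antibody = attr(ref, "antibody"), condition = attr(ref, "condition"),
    replicate = "averaged", smoothed = isTRUE(attr(ref, "smoothed"))
  )
}

#' Smooth a track over a positional window
#'
#' The smoothed value at probe i is the chosen estimator (mean or median of
#' log2 ratios) over all probes within `window_bp` of probe i on the same
#' chromosome, back-transformed to the linear scale. Missing probes are
#' skipped, not zero-filled; the probe grid is unchanged. `window_bp = 0` is
#' the identity.
#'
#' @param track An unsmoothed `probe_track`.
#' @param window_bp Half-window span in bp (default 500, about 28 probes at
#'   36 bp spacing).
#' @param estimator `"mean_log"` (default) or `"median_log"`.
#' @return A smoothed `probe_track`.
#' @export
smooth_track <- function(track, window_bp = 500,
                         estimator = c("mean_log", "median_log")) {
  stop_if_not_track(track)
  estimator <- match.arg(estimator)
  if (window_bp < 0) abort("`window_bp` must be >= 0.", class = "pcg_bad_params")
  if (is_smoothed(track)) {
    abort("Track is already smoothed.", class = "pcg_precondition")
  }
  out <- numeric(nrow(track))
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    pos <- track$pos[sel]
    l2 <- log2(track$value[sel])
    ok <- !is.na(l2)
    lo <- findInterval(pos - window_bp - 0.5, pos) + 1L
    hi <- findInterval(pos + window_bp + 0.5 - 1e-9, pos)
    if (estimator == "mean_log") {
      cs <- c(0, cumsum(ifelse(ok, l2, 0)))
      cn <- c(0, cumsum(as.numeric(ok)))
      s <- cs[hi + 1L] - cs[lo]
      n <- cn[hi + 1L] - cn[lo]
      m <- ifelse(n > 0, s / n, NA_real_)
    } else {
      m <- vapply(seq_along(pos), function(i) {
        w <- l2[lo[i]:hi[i]]
        w <- w[!is.na(w)]
        if (length(w) == 0) NA_real_ else median(w)
      }, numeric(1))
    }
    out[sel] <- 2^m
  }
  new_probe_track(
    tibble(chrom = track$chrom, pos = track$pos, value = out),
    antibody = attr(track, "antibody"), condition = attr(track, "condition"),
    replicate = attr(track, "replicate"), smoothed = TRUE
  )
}

# Indices of probes (of chromosome-subset positions `pos`, sorted) falling in
# the half-open interval [start, end).
probes_in_interval <- function(pos, start, end) {
  lo <- findInterval(start - 0.5, pos) + 1L
  hi <- findInterval(end - 0.5, pos)
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

#' Enrichment score of a region
#'
#' The score is the maximum, over all runs of `k` consecutive in-region
#' probes, of the mean fold ratio (the "top-k consecutive features"
#' statistic). Regions with fewer than `k` covered probes fall back to the
#' mean of all in-region probes (`method = "all_probes"`). Missing probes are
#' dropped before forming runs.
#'
#' @param track A `probe_track` (typically smoothed and replicate-averaged).
#' @param region A list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param k Number of consecutive probes in the scoring window (default 6).
#' @return A one-row tibble with `value`, `n_features`, `method`.
#' @export
region_enrichment <- function(track, region, k = 6L) {
  stop_if_not_track(track)
  if (is.data.frame(region)) region <- as.list(region[1, ])
  sel <- which(track$chrom == region$chrom)
  idx <- probes_in_interval(track$pos[sel], region$start, region$end)
  v <- track$value[sel][idx]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    abort(
      sprintf(
        "Region %s:%s-%s overlaps no covered probes.",
        region$chrom, format(region$start, scientific = FALSE),
        format(region$end, scientific = FALSE)
      ),
      class = "pcg_no_coverage"
    )
  }
  score_values(v, k)
}

score_values <- function(v, k = 6L) {
  n <- length(v)
  if (n < k) {
    return(tibble(value = mean(v), n_features = n, method = "all_probes"))
  }
  cs <- cumsum(v)
  means <- (cs[k:n] - c(0, cs)[seq_len(n - k + 1L)]) / k
  tibble(value = max(means), n_features = as.integer(k), method = "top_k_consecutive")
}

# Vectorised scoring of many regions against one track; returns a numeric
# score per row of `regions` (NA where the region has no covered probes).
score_regions <- function(track, regions, k = 6L) {
  if (nrow(regions) == 0) {
    return(numeric(0))
  }
  out <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    sel <- which(track$chrom == ch)
    pos <- track$pos[sel]
    val <- track$value[sel]
    rows <- which(regions$chrom == ch)
    for (i in rows) {
      idx <- probes_in_interval(pos, regions$start[i], regions$end[i])
      v <- val[idx]
      v <- v[!is.na(v)]
      if (length(v) > 0) out[i] <- score_values(v, k)$value
    }
  }
  out
}
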