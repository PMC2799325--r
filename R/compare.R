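# Cross-condition comparison: region matching, state changes, overlap and
# saturation statistics, knockdown quantification, anchored profiles.

#' Match regions between two conditions by greedy maximum overlap
#'
#' All overlapping pairs (overlap >= `min_overlap_bp`) are ranked by overlap
#' size; pairs are accepted greedily so that each region joins at most one
#' pair. Ties are broken by the leftmost partner (chromosome, then start, on
#' the `a` side then the `b` side).
#'
#' @param set_a,set_b Region tibbles, each sorted and disjoint within set.
#' @param min_overlap_bp Minimum overlap in bp to consider a pair (default 1).
#' @return A list of class `region_match`: `pairs` (indices `a_idx`, `b_idx`,
#'   `overlap_bp` plus the paired coordinates), `a_only`, `b_only`.
#' @export
match_regions <- function(set_a, set_b, min_overlap_bp = 1L) {
  empty_pairs <- tibble(
    a_idx = integer(), b_idx = integer(), overlap_bp = numeric(),
    chrom = character(), start_a = numeric(), end_a = numeric(),
    start_b = numeric(), end_b = numeric()
  )
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    res <- list(pairs = empty_pairs, a_only = set_a, b_only = set_b)
    class(res) <- "region_match"
    return(res)
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    regions_gr(set_a), regions_gr(set_b),
    minoverlap = min_overlap_bp
  ))
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(set_a$end[ai], set_b$end[bi]) - pmax(set_a$start[ai], set_b$start[bi])
  ord <- order(-ov, set_a$chrom[ai], set_a$start[ai], set_b$start[bi])
  used_a <- logical(nrow(set_a))
  used_b <- logical(nrow(set_b))
  keep <- logical(length(ord))
  for (j in ord) {
    if (!used_a[ai[j]] && !used_b[bi[j]]) {
      keep[j] <- TRUE
      used_a[ai[j]] <- TRUE
      used_b[bi[j]] <- TRUE
    }
  }
  ai <- ai[keep]
  bi <- bi[keep]
  pairs <- tibble(
    a_idx = ai, b_idx = bi, overlap_bp = ov[keep],
    chrom = set_a$chrom[ai],
    start_a = set_a$start[ai], end_a = set_a$end[ai],
    start_b = set_b$start[bi], end_b = set_b$end[bi]
  ) |> arrange(.data$chrom, .data$start_a)
  res <- list(
    pairs = pairs,
    a_only = set_a[!used_a, , drop = FALSE],
    b_only = set_b[!used_b, , drop = FALSE]
  )
  class(res) <- "region_match"
  res
}

#' @export
print.region_match <- function(x, ...) {
  cat(sprintf(
    "region match: %d pairs, %d a-only, %d b-only\n",
    nrow(x$pairs), nrow(x$a_only), nrow(x$b_only)
  ))
  invisible(x)
}

#' Detect state changes between conditions
#'
#' Compares per-gene state calls between two conditions over the genes they
#' share. A change is recorded when the state differs or when evidence
#' booleans were gained/lost. The transition summary (counts and fractions
#' per `state_from` -> `state_to`) is attached as attribute `"summary"`.
#'
#' @param states_by_condition Named list (condition -> [classify_state()]
#'   output). Must share gene ids; disjoint annotations are an error.
#' @param from,to Condition names to compare (default: first and second).
#' @return A tibble of changes: `gene_id`, `condition_from`, `condition_to`,
#'   `state_from`, `state_to`, `gained`, `lost` (comma-separated evidence
#'   fields).
#' @export
detect_changes <- function(states_by_condition, from = NULL, to = NULL) {
  if (length(states_by_condition) < 2) {
    abort("At least two conditions are required.", class = "pcg_empty_input")
  }
  from <- from %||% names(states_by_condition)[1]
  to <- to %||% names(states_by_condition)[2]
  a <- states_by_condition[[from]]
  b <- states_by_condition[[to]]
  shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) == 0) {
    abort("Conditions share no genes (disjoint annotations).",
      class = "pcg_annotation_mismatch"
    )
  }
  a <- a[match(shared, a$gene_id), ]
  b <- b[match(shared, b$gene_id), ]
  ev_cols <- intersect(
    c(
      "in_h3k27me3_domain", "pc_bound", "ez_bound", "trxC_at_pre",
      "trxN_at_pre", "ash1_trxN_domain_overlap", "ash1_trxN_at_tss",
      "h3k27ac_domain_overlap", "active"
    ),
    intersect(names(a), names(b))
  )
  gained <- lost <- rep("", length(shared))
  if (length(ev_cols) > 0) {
    for (i in seq_along(shared)) {
      av <- unlist(a[i, ev_cols])
      bv <- unlist(b[i, ev_cols])
      gained[i] <- paste(ev_cols[!av & bv], collapse = ",")
      lost[i] <- paste(ev_cols[av & !bv], collapse = ",")
    }
  }
  changed <- a$state != b$state | gained != "" | lost != ""
  out <- tibble(
    gene_id = shared,
    condition_from = from, condition_to = to,
    state_from = a$state, state_to = b$state,
    gained = gained, lost = lost
  )[changed, , drop = FALSE]
  transitions <- out |>
    filter(.data$state_from != .data$state_to) |>
    count(.data$state_from, .data$state_to, name = "n") |>
    mutate(fraction = .data$n / length(shared))
  attr(out, "summary") <- transitions
  attr(out, "n_genes") <- length(shared)
  out
}

#' Three-way exclusive overlap counts (Venn) of region sets
#'
#' Regions from the three sets are pooled and merged into overlap clusters
#' (single-linkage, >= `min_overlap_bp`); each cluster is counted once under
#' its membership pattern. The seven exclusive counts therefore sum to the
#' size of the union under the matching relation.
#'
#' @param sets Named list of exactly three region tibbles.
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return A tibble `pattern` (e.g. `"Sg4&BG3"`), `count`, with the union
#'   size as attribute `"total"`.
#' @export
venn_counts <- function(sets, min_overlap_bp = 1L) {
  if (length(sets) != 3 || is.null(names(sets))) {
    abort("`sets` must be a named list of three region tibbles.",
      class = "pcg_bad_params"
    )
  }
  pooled <- bind_rows(lapply(names(sets), function(nm) {
    df <- sets[[nm]]
    if (nrow(df) == 0) {
      return(NULL)
    }
    tibble(chrom = df$chrom, start = df$start, end = df$end, set = nm)
  }))
  nms <- names(sets)
  all_patterns <- unlist(lapply(1:3, function(k) {
    apply(combn(nms, k), 2, paste, collapse = "&")
  }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    out <- tibble(pattern = all_patterns, count = 0L)
    attr(out, "total") <- 0L
    return(out)
  }
  clusters <- merge_regions(pooled)
  hits <- GenomicRanges::findOverlaps(regions_gr(clusters), regions_gr(pooled),
    minoverlap = min_overlap_bp
  )
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  pattern <- vapply(seq_len(nrow(clusters)), function(i) {
    members <- sort(unique(pooled$set[sh[qh == i]]))
    paste(nms[nms %in% members], collapse = "&")
  }, character(1))
  counts <- table(factor(pattern, levels = all_patterns))
  out <- tibble(pattern = all_patterns, count = as.integer(counts))
  attr(out, "total") <- nrow(clusters)
  out
}

#' Saturation of the non-redundant target catalogue across conditions
#'
#' For each requested ordering of the conditions, the cumulative size of the
#' union of target-gene catalogues after each condition is added, together
#' with the per-step percentage increase.
#'
#' @param catalogues Named list (condition -> character vector of gene ids,
#'   or a tibble with a `gene_id` column).
#' @param orderings `"all"` (every permutation) or a list of character
#'   vectors of condition names.
#' @return A tibble: `ordering`, `step`, `condition`, `cumulative`,
#'   `pct_increase`.
#' @export
saturation_curve <- function(catalogues, orderings = "all") {
  if (length(catalogues) < 2) {
    abort("At least two conditions are required.", class = "pcg_empty_input")
  }
  catalogues <- lapply(catalogues, function(x) {
    if (is.data.frame(x)) unique(x$gene_id) else unique(as.character(x))
  })
  nms <- names(catalogues)
  if (identical(orderings, "all")) {
    perms <- apply(permutations_of(length(nms)), 1, function(ix) nms[ix], simplify = FALSE)
  } else {
    perms <- orderings
  }
  bind_rows(lapply(perms, function(ord) {
    acc <- character(0)
    cum <- integer(length(ord))
    for (i in seq_along(ord)) {
      acc <- union(acc, catalogues[[ord[i]]])
      cum[i] <- length(acc)
    }
    tibble(
      ordering = paste(ord, collapse = " -> "),
      step = seq_along(ord),
      condition = ord,
      cumulative = cum,
      pct_increase = c(NA_real_, 100 * diff(cum) / head(cum, -1))
    )
  }))
}

permutations_of <- function(n) {
  if (n == 1) {
    return(matrix(1L))
  }
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow = nrow(sub)))
  }))
}

#' Quantify a knockdown's effect on region enrichment
#'
#' Scores every region in a treated and a control track — by default the
#' average smoothed ratio over all in-region probes (`method =
#' "all_probes"`; the top-k-consecutive statistic of [region_enrichment()]
#' is available via `method = "top_k"`) — and reports the per-region
#' treated/control enrichment ratio,
#' alongside the same statistic for `n_background` randomly placed
#' intergenic background intervals (lengths resampled from the query
#' regions' length distribution; placements drawn without replacement from
#' the intergenic space, i.e. the complement of transcription units extended
#' by `flank_bp`). Treated and control are compared over the regions with a
#' paired Wilcoxon signed-rank test.
#'
#' @param regions Region tibble to assay (may be empty: background-only
#'   report).
#' @param treated,control `probe_track`s on the same probe grid.
#' @param genes Gene annotation used to derive the intergenic space.
#' @param n_background Number of background intervals (default 100).
#' @param seed Seed for the background sampling (recorded in the output).
#' @param flank_bp Flank excluded around transcription units (default 1000).
#' @param k Probes per scoring window when `method = "top_k"`.
#' @param method Region score: `"all_probes"` (mean over the region,
#'   default) or `"top_k"` (max mean of `k` consecutive probes).
#' @return A `knockdown_report`: list with `regions` and `background`
#'   tibbles (scores and ratios), group means, the paired test, and the seed.
#' @export
knockdown_effect <- function(regions, treated, control, genes,
                             n_background = 100, seed = 1,
                             flank_bp = 1000, k = 6L,
                             method = c("all_probes", "top_k")) {
  method <- match.arg(method)
  kk <- if (method == "all_probes") Inf else k
  stop_if_not_track(treated)
  stop_if_not_track(control)
  if (nrow(treated) != nrow(control) ||
    !isTRUE(all.equal(treated$pos, control$pos))) {
    abort("Treated and control tracks must share a probe grid.",
      class = "pcg_grid_mismatch"
    )
  }
  reg <- regions
  if (nrow(reg) > 0) {
    reg <- tibble(chrom = reg$chrom, start = reg$start, end = reg$end)
    reg$score_treated <- score_regions(treated, reg, kk)
    reg$score_control <- score_regions(control, reg, kk)
    reg$ratio <- reg$score_treated / reg$score_control
  } else {
    reg <- tibble(
      chrom = character(), start = numeric(), end = numeric(),
      score_treated = numeric(), score_control = numeric(), ratio = numeric()
    )
  }
  lengths_pool <- if (nrow(reg) > 0) reg$end - reg$start else 2000
  bg <- withr::with_seed(seed, sample_intergenic(
    genes, treated,
    n = n_background, lengths_pool = lengths_pool, flank_bp = flank_bp
  ))
  bg$score_treated <- score_regions(treated, bg, kk)
  bg$score_control <- score_regions(control, bg, kk)
  bg$ratio <- bg$score_treated / bg$score_control
  test <- if (nrow(reg) >= 2) {
    suppressWarnings(wilcox.test(reg$score_treated, reg$score_control, paired = TRUE))
  } else {
    NULL
  }
  res <- list(
    regions = reg, background = bg,
    mean_region_ratio = if (nrow(reg) > 0) mean(reg$ratio, na.rm = TRUE) else NA_real_,
    mean_background_ratio = mean(bg$ratio, na.rm = TRUE),
    mean_treated = if (nrow(reg) > 0) mean(reg$score_treated, na.rm = TRUE) else NA_real_,
    mean_control = if (nrow(reg) > 0) mean(reg$score_control, na.rm = TRUE) else NA_real_,
    p_value = if (is.null(test)) NA_real_ else test$p.value,
    seed = seed
  )
  class(res) <- "knockdown_report"
  res
}

#' @export
print.knockdown_report <- function(x, ...) {
  cat(sprintf(
    "knockdown report: %d regions (mean ratio %.3f), %d background (mean ratio %.3f), paired p = %s\n",
    nrow(x$regions), x$mean_region_ratio,
    nrow(x$background), x$mean_background_ratio,
    format(x$p_value, digits = 3)
  ))
  invisible(x)
}

# Random intergenic intervals with probe coverage, drawn without replacement
# (chosen intervals do not overlap each other).
sample_intergenic <- function(genes, track, n, lengths_pool, flank_bp = 1000) {
  space <- intergenic_space(genes, track, flank_bp)
  if (nrow(space) == 0) {
    abort("No intergenic space available for background sampling.",
      class = "pcg_no_space"
    )
  }
  # lengths follow the query distribution, truncated to what the intergenic
  # space can host
  lengths_pool <- pmin(lengths_pool, floor(0.9 * max(space$end - space$start)))
  if (sum(space$end - space$start) < 1.2 * n * mean(lengths_pool)) {
    abort("Intergenic space is too small for the requested background sample.",
      class = "pcg_no_space"
    )
  }
  chosen <- tibble(chrom = character(), start = numeric(), end = numeric())
  tries <- 0
  while (nrow(chosen) < n && tries < n * 200) {
    tries <- tries + 1
    len <- sample(lengths_pool, 1)
    gap_ok <- which((space$end - space$start) >= len)
    if (length(gap_ok) == 0) next
    g <- gap_ok[sample.int(length(gap_ok), 1,
      prob = (space$end - space$start)[gap_ok]
    )]
    start <- floor(runif(1, space$start[g], space$end[g] - len))
    cand <- tibble(chrom = space$chrom[g], start = start, end = start + len)
    if (any(overlaps_any(cand, chosen))) next
    sel <- which(track$chrom == cand$chrom)
    if (length(probes_in_interval(track$pos[sel], cand$start, cand$end)) < 1) next
    chosen <- bind_rows(chosen, cand)
  }
  if (nrow(chosen) < n) {
    abort("Could not place the requested number of background intervals.",
      class = "pcg_no_space"
    )
  }
  arrange(chosen, .data$chrom, .data$start)
}

# Complement of transcription units +/- flank, clipped to the probe extent.
intergenic_space <- function(genes, track, flank_bp = 1000) {
  pieces <- list()
  for (ch in unique(track$chrom)) {
    pos <- track$pos[track$chrom == ch]
    lo <- min(pos)
    hi <- max(pos) + 1
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) {
      pieces[[ch]] <- tibble(chrom = ch, start = lo, end = hi)
      next
    }
    blocked <- merge_regions(tibble(
      chrom = ch,
      start = pmax(lo, g$start - flank_bp),
      end = pmin(hi, g$end + flank_bp)
    ))
    starts <- c(lo, blocked$end)
    ends <- c(blocked$start, hi)
    keep <- ends > starts
    if (any(keep)) {
      pieces[[ch]] <- tibble(chrom = ch, start = starts[keep], end = ends[keep])
    }
  }
  if (length(pieces) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  bind_rows(pieces)
}

#' Superposed anchor-centred signal profile
#'
#' Pools the (offset, log2 ratio) observations of all probes within
#' `window_bp` of each anchor, oriented so that downstream of the anchor is a
#' positive offset, and fits a smooth curve (cubic smoothing spline with
#' GCV-selected smoothness, or lowess with span 2/3) evaluated on a fixed
#' offset grid. Anchors without probe coverage are dropped and counted
#' (attribute `n_dropped`).
#'
#' @param track A `probe_track` (values are log2-transformed internally).
#' @param anchors Tibble with `chrom`, `pos` and optionally `strand`
#'   (anchors on "-" are mirrored).
#' @param window_bp Half-width of the window (default 5000, i.e. 10 kb
#'   windows).
#' @param fit `"cubic_spline"` (default), `"lowess"` or `"none"`.
#' @param grid_bp Offset grid step for the fitted curve (default 50).
#' @param min_points Minimum pooled points required to fit (default 10).
#' @return A `profile_matrix`: list with `samples` (anchor, offset,
#'   log2_ratio), `fit` (offset, fit), and the window parameters.
#' @export
superposed_profile <- function(track, anchors, window_bp = 5000,
                               fit = c("cubic_spline", "lowess", "none"),
                               grid_bp = 50, min_points = 10) {
  stop_if_not_track(track)
  fit <- match.arg(fit)
  if (nrow(anchors) == 0) {
    abort("At least one anchor is required.", class = "pcg_empty_input")
  }
  strand <- if ("strand" %in% names(anchors)) anchors$strand else rep("+", nrow(anchors))
  samples <- list()
  dropped <- 0
  for (i in seq_len(nrow(anchors))) {
    sel <- which(track$chrom == anchors$chrom[i])
    pos <- track$pos[sel]
    idx <- probes_in_interval(pos, anchors$pos[i] - window_bp, anchors$pos[i] + window_bp + 1)
    v <- track$value[sel][idx]
    keep <- !is.na(v)
    if (!any(keep)) {
      dropped <- dropped + 1
      next
    }
    off <- (pos[idx][keep] - anchors$pos[i]) * (if (strand[i] == "-") -1 else 1)
    samples[[length(samples) + 1]] <- tibble(
      anchor = i, offset = off, log2_ratio = log2(v[keep])
    )
  }
  if (length(samples) == 0) {
    abort("No anchor has probe coverage.", class = "pcg_no_coverage")
  }
  samples <- bind_rows(samples)
  grid <- seq(-window_bp, window_bp, by = grid_bp)
  fitted <- tibble(offset = numeric(), fit = numeric())
  if (fit != "none" && nrow(samples) >= min_points) {
    rng <- range(samples$offset)
    g <- grid[grid >= rng[1] & grid <= rng[2]]
    if (fit == "cubic_spline") {
      sp <- smooth.spline(samples$offset, samples$log2_ratio)
      fitted <- tibble(offset = g, fit = predict(sp, g)$y)
    } else {
      lw <- lowess(samples$offset, samples$log2_ratio, f = 2 / 3)
      fitted <- tibble(
        offset = g,
        fit = stats::approx(lw$x, lw$y, xout = g, rule = 2)$y
      )
    }
  }
  res <- list(
    samples = samples, fit = fitted,
    window_bp = window_bp, fit_method = fit, n_anchors = nrow(anchors) - dropped
  )
  attr(res, "n_dropped") <- dropped
  class(res) <- "profile_matrix"
  res
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "superposed profile: %d anchors, %d probe observations, +/-%d bp, fit = %s\n",
    x$n_anchors, nrow(x$samples), x$window_bp, x$fit_method
  ))
  invisible(x)
}

#' Location of the fitted profile maximum
#'
#' @param profile A `profile_matrix`.
#' @return The offset (bp) at which the fitted curve is maximal.
#' @export
profile_peak <- function(profile) {
  if (nrow(profile$fit) == 0) {
    abort("Profile has no fitted curve (fit = 'none'?).", class = "pcg_precondition")
  }
  profile$fit$offset[which.max(profile$fit$fit)]
}

#' Binned observation-density matrix of a profile
#'
#' Counts pooled (offset, log2 ratio) observations in a fixed rectangular
#' binning — the exportable form of the density-coloured scatter rendering.
#'
#' @param profile A `profile_matrix`.
#' @param offset_bin Bin width in bp (default 250).
#' @param value_bin Bin width in log2 units (default 0.25).
#' @return A tibble `offset_mid`, `value_mid`, `count`.
#' @export
profile_density <- function(profile, offset_bin = 250, value_bin = 0.25) {
  s <- profile$samples
  ob <- floor(s$offset / offset_bin)
  vb <- floor(s$log2_ratio / value_bin)
  out <- tibble(ob = ob, vb = vb) |>
    count(.data$ob, .data$vb, name = "count") |>
    mutate(
      offset_mid = (.data$ob + 0.5) * offset_bin,
      value_mid = (.data$vb + 0.5) * value_bin
    ) |>
    select("offset_mid", "value_mid", "count") |>
    arrange(.data$offset_mid, .data$value_mid)
  out
}

#' Correlate region enrichment between two tracks
#'
#' Scores each region on both tracks with [region_enrichment()] and reports
#' the Pearson product-moment correlation (two-sided test) together with a
#' lowess curve of y on x.
#'
#' @param track_x,track_y `probe_track`s.
#' @param regions Region tibble (>= 3 regions required).
#' @param k Probes per scoring window.
#' @param lowess_f Lowess span (default 2/3).
#' @return An `enrichment_cor`: list with `data` (per-region x/y), estimate,
#'   p-value, n and the lowess curve.
#' @export
correlate_domain_enrichment <- function(track_x, track_y, regions,
                                        k = 6L, lowess_f = 2 / 3) {
  if (nrow(regions) < 3) {
    abort("At least 3 regions are required for correlation.", class = "pcg_empty_input")
  }
  x <- score_regions(track_x, regions, k)
  y <- score_regions(track_y, regions, k)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    abort("Fewer than 3 regions have coverage on both tracks.", class = "pcg_no_coverage")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in region enrichment; correlation undefined.",
      class = "pcg_degenerate"
    )
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  lw <- lowess(x, y, f = lowess_f)
  res <- list(
    data = tibble(x = x, y = y),
    estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x),
    lowess = tibble(x = lw$x, y = lw$y)
  )
  class(res) <- "enrichment_cor"
  res
}

#' @export
print.enrichment_cor <- function(x, ...) {
  cat(sprintf(
    "enrichment correlation: r = %.3f, p = %s, n = %d regions\n",
    x$estimate, format(x$p_value, digits = 3), x$n
  ))
  invisible(x)
}
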