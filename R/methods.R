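# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @rdname rank_sum_test
#' @param x A `rank_sum_test`.
#' @param ... Unused.
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(
    statistic = x$U,
    p.value = x$p_two_sided,
    p.value.one.sided = x$p_one_sided,
    n_a = x$n_a, n_b = x$n_b,
    method = x$method
  )
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("intercept", "log10_amount"),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  sm <- summary(x$model)
  tibble(
    slope = x$slope, intercept = x$intercept, efficiency = x$efficiency,
    r.squared = sm$r.squared, sigma = sm$sigma,
    nobs = length(sm$residuals)
  )
}

#' @rdname correlate_domain_enrichment
#' @param x An `enrichment_cor`.
#' @param ... Unused.
#' @export
tidy.enrichment_cor <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p_value, n = x$n)
}

#' @rdname correlate_domain_enrichment
#' @export
glance.enrichment_cor <- tidy.enrichment_cor

#' @rdname knockdown_effect
#' @param x A `knockdown_report`.
#' @param ... Unused.
#' @export
glance.knockdown_report <- function(x, ...) {
  tibble(
    n_regions = nrow(x$regions),
    mean_region_ratio = x$mean_region_ratio,
    n_background = nrow(x$background),
    mean_background_ratio = x$mean_background_ratio,
    mean_treated = x$mean_treated,
    mean_control = x$mean_control,
    p.value = x$p_value,
    seed = x$seed
  )
}

#' @rdname knockdown_effect
#' @export
tidy.knockdown_report <- function(x, ...) {
  bind_rows(
    mutate(x$regions, group = "region"),
    mutate(x$background, group = "background")
  )
}

#' Plot a superposed anchor-centred profile
#'
#' Density-shaded scatter of the pooled (offset, log2 ratio) observations
#' with the fitted curve overlaid.
#'
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.profile_matrix <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$samples,
    ggplot2::aes(x = .data$offset, y = .data$log2_ratio)
  ) +
    ggplot2::geom_bin2d(bins = 80) +
    ggplot2::scale_fill_gradient(low = "red", high = "white") +
    ggplot2::labs(
      x = "offset from anchor (bp)", y = "log2 ChIP/Input",
      fill = "probes"
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$fit) > 0) {
    p <- p + ggplot2::geom_line(
      data = object$fit,
      ggplot2::aes(x = .data$offset, y = .data$fit),
      linewidth = 1
    )
  }
  p
}

#' Plot a knockdown report
#'
#' Per-region enrichment in control and treated tracks, with background
#' intervals alongside and group means marked.
#'
#' @param object A `knockdown_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.knockdown_report <- function(object, ...) {
  long <- tidy.knockdown_report(object) |>
    tidyr::pivot_longer(c("score_control", "score_treated"),
      names_to = "arm", values_to = "enrichment"
    ) |>
    mutate(arm = sub("score_", "", .data$arm))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = interaction(.data$group, .data$arm), y = .data$enrichment)
  ) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = "region enrichment (IP/Input)") +
    ggplot2::theme_minimal()
}

#' Plot a track region with called regions
#'
#' @param track A `probe_track`.
#' @param chrom,start,end Window to draw.
#' @param regions Optional region tibble highlighted under the signal.
#' @param fold_cutoff Horizontal reference line (default 2).
#' @return A ggplot.
#' @export
plot_track <- function(track, chrom, start, end, regions = NULL,
                       fold_cutoff = 2) {
  sel <- track$chrom == chrom & track$pos >= start & track$pos < end
  df <- as_tibble(track[sel, ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = fold_cutoff, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%s position (bp)", chrom), y = "ChIP/Input ratio",
      title = attr(track, "antibody") %||% NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    rg <- regions[regions$chrom == chrom & regions$end > start & regions$start < end, ]
    if (nrow(rg) > 0) {
      p <- p + ggplot2::annotate("rect",
        xmin = rg$start, xmax = rg$end,
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
      )
    }
  }
  p
}
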