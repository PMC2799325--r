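# qRT-PCR-style quantification and the nonparametric two-group comparison.

#' Fit a qPCR standard curve
#'
#' Least-squares line of quantification cycle (Cq) on log10 template amount,
#' fitted from a serial-dilution series. Amplification efficiency is derived
#' from the slope as `10^(-1/slope) - 1` (1.0 for a perfect doubling,
#' slope -3.3219). The slope must be negative: more template means fewer
#' cycles.
#'
#' @param amount Template amounts of the dilution points (> 0, >= 3 points).
#' @param cq Measured Cq per dilution point.
#' @return A `standard_curve`: list with `slope`, `intercept`, `efficiency`,
#'   the underlying `lm` fit and the calibrated Cq range.
#' @export
fit_standard_curve <- function(amount, cq) {
  if (length(amount) < 3 || length(cq) != length(amount)) {
    abort("A standard curve needs >= 3 dilution points.", class = "pcg_bad_params")
  }
  if (any(amount <= 0)) abort("Amounts must be positive.", class = "pcg_bad_params")
  fit <- lm(cq ~ log10(amount))
  slope <- unname(coef(fit)[2])
  if (is.na(slope) || slope >= 0) {
    abort("Standard-curve slope must be negative (Cq decreases with template).",
      class = "pcg_bad_curve"
    )
  }
  res <- list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    efficiency = 10^(-1 / slope) - 1,
    model = fit,
    cq_range = range(cq)
  )
  class(res) <- "standard_curve"
  res
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve: Cq = %.3f %+.4f * log10(amount); efficiency = %.3f\n",
    x$intercept, x$slope, x$efficiency
  ))
  invisible(x)
}

#' Invert a standard curve: template amount from Cq
#'
#' @param curve A `standard_curve`.
#' @param cq Cq values.
#' @return Template amounts on the curve's scale.
#' @export
amount_from_cq <- function(curve, cq) {
  10^((cq - curve$intercept) / curve$slope)
}

#' Relative template quantity of a gene versus a reference
#'
#' The quantity is `amount(gene) / amount(reference)` via standard-curve
#' inversion, i.e. `10^((gene_cq - ref_cq) / slope)`. With a negative slope,
#' a gene needing more cycles than the reference has a quantity below 1.
#' Quantities are scale-free: shifting both Cq by a constant leaves them
#' unchanged. Cq values outside the calibrated range are flagged, not
#' clamped.
#'
#' @param gene_cq,ref_cq Paired Cq vectors (e.g. one entry per replicate).
#' @param curve A `standard_curve`.
#' @return A tibble: `quantity`, `out_of_range`.
#' @export
relative_quantity <- function(gene_cq, ref_cq, curve) {
  tibble(
    quantity = 10^((gene_cq - ref_cq) / curve$slope),
    out_of_range = gene_cq < curve$cq_range[1] | gene_cq > curve$cq_range[2] |
      ref_cq < curve$cq_range[1] | ref_cq > curve$cq_range[2]
  )
}

#' Relative expression from a plate-style Cq table
#'
#' Takes a delimited-plate layout (`gene`, `condition`, `replicate`, `cq`)
#' and expresses each gene as a fraction of the reference gene's quantity
#' within the same condition and replicate, then summarises replicates by
#' their mean and scatter (half-range, matching error bars that indicate the
#' scatter of two independent experiments).
#'
#' @param plate A data frame with columns `gene`, `condition`, `replicate`,
#'   `cq`.
#' @param curve A `standard_curve`.
#' @param reference Reference gene label (default `"RpL32"`).
#' @return A tibble: `gene`, `condition`, `quantity` (replicate mean),
#'   `scatter`, `n_replicates`, plus a `replicates` list-column of per-
#'   replicate quantities.
#' @export
relative_expression <- function(plate, curve, reference = "RpL32") {
  needed <- c("gene", "condition", "replicate", "cq")
  if (!all(needed %in% names(plate))) {
    abort(paste(
      "Plate table must have columns:",
      paste(needed, collapse = ", ")
    ), class = "pcg_bad_params")
  }
  ref <- plate |>
    filter(.data$gene == reference) |>
    select("condition", "replicate", ref_cq = "cq")
  if (nrow(ref) == 0) {
    abort(sprintf("Reference gene '%s' not found in plate.", reference),
      class = "pcg_bad_params"
    )
  }
  per_rep <- plate |>
    filter(.data$gene != reference) |>
    left_join(ref, by = c("condition", "replicate")) |>
    mutate(quantity = relative_quantity(.data$cq, .data$ref_cq, curve)$quantity)
  per_rep |>
    group_by(.data$gene, .data$condition) |>
    summarise(
      quantity = mean(.data$quantity),
      scatter = (max(.data$quantity) - min(.data$quantity)) / 2,
      n_replicates = n(),
      replicates = list(.data$quantity),
      .groups = "drop"
    )
}

#' Mann-Whitney/Wilcoxon rank-sum test with exact enumeration
#'
#' The statistic follows the Mann-Whitney U convention with
#' `U = U_a = (rank sum of group a) - n_a (n_a + 1) / 2`, so that complete
#' separation of a above b gives `U = n_a * n_b` (e.g. 64 for two groups of
#' 8). The exact p-value is computed by full enumeration of all
#' `choose(n_a + n_b, n_a)` group assignments when the pooled sample has at
#' most 20 observations and no ties; otherwise the normal approximation with
#' tie correction is used. One-sided (a greater) and two-sided p-values are
#' both reported; under complete separation of 8 vs 8 the one-sided exact p
#' is 1 / choose(16, 8) = 7.77e-05.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return A `rank_sum_test`: list with `U`, `n_a`, `n_b`, `p_one_sided`,
#'   `p_two_sided`, `method`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("Both groups must be non-empty.", class = "pcg_empty_input")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled) # midranks under ties
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(pooled))
  mu <- n_a * n_b / 2
  if (n_a + n_b <= 20 && !ties) {
    sets <- combn(n_a + n_b, n_a)
    u_all <- colSums(matrix(r[sets], nrow = n_a)) - n_a * (n_a + 1) / 2
    p_one <- mean(u_all >= u_obs)
    p_two <- mean(abs(u_all - mu) >= abs(u_obs - mu))
    method <- "exact enumeration"
  } else {
    n <- n_a + n_b
    tie_tab <- table(pooled)
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) { # fully tied data carry no ordering information
      p_one <- p_two <- 1
    } else {
      z_one <- (u_obs - mu - 0.5) / sqrt(sigma2)
      p_one <- pnorm(z_one, lower.tail = FALSE)
      z_two <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p_two <- min(1, 2 * pnorm(z_two, lower.tail = FALSE))
    }
    method <- "normal approximation (tie-corrected)"
  }
  res <- list(
    U = u_obs, n_a = n_a, n_b = n_b,
    p_one_sided = p_one, p_two_sided = p_two, method = method
  )
  class(res) <- "rank_sum_test"
  res
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf(
    "rank-sum test: U = %g (n = %d vs %d), one-sided p = %s, two-sided p = %s [%s]\n",
    x$U, x$n_a, x$n_b,
    format(x$p_one_sided, digits = 3), format(x$p_two_sided, digits = 3),
    x$method
  ))
  invisible(x)
}
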