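# Programmatic fixtures: random tracks, random region sets, small planted
# simulations. All randomness is seeded by the caller.

rand_track <- function(n = 200, seed = 1, p_enriched = 0.3, fold = 4,
                       sd_log2 = 0.3, chrom = "chrT", smoothed = TRUE,
                       step_range = 20:60) {
  withr::with_seed(seed, {
    pos <- cumsum(sample(step_range, n, replace = TRUE))
    base <- ifelse(stats::runif(n) < p_enriched, fold, 1)
    value <- base * 2^stats::rnorm(n, 0, sd_log2)
    probe_track(chrom, pos, value, antibody = "TEST", smoothed = smoothed)
  })
}

rand_regions <- function(n = 20, seed = 1, chrom = "chrT", span = 100000,
                         min_w = 200, max_w = 5000) {
  withr::with_seed(seed, {
    start <- sort(sample.int(span, n))
    width <- sample(min_w:max_w, n, replace = TRUE)
    raw <- tibble::tibble(chrom = chrom, start = start, end = start + width)
    # collapse overlaps so each set is internally disjoint
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      raw$chrom, IRanges::IRanges(raw$start + 1, raw$end)
    ))
    tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = as.numeric(GenomicRanges::end(gr))
    )
  })
}

small_sim <- function(n_genes = 60, seed = 1, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
  truth <- simulate_genome(cfg)
  list(cfg = cfg, truth = truth)
}

recovery_rate <- function(truth, states) {
  planted <- stats::setNames(truth$genes$state, truth$genes$gene_id)
  four <- planted[states$gene_id] %in% c("repressed", "active", "balanced", "void")
  mean(states$state[four] == planted[states$gene_id][four])
}
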