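# Cross-condition comparison: matching, changes, Venn, saturation,
# knockdown quantification, profiles, correlation.

test_that("match_regions: identity, disjoint, and greedy-scan oracle", {
  a <- rand_regions(20, seed = 71)
  m <- match_regions(a, a)
  expect_equal(nrow(m$pairs), nrow(a))
  expect_equal(nrow(m$a_only) + nrow(m$b_only), 0)

  far <- dplyr::mutate(a, chrom = "other")
  m2 <- match_regions(a, far)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(nrow(m2$a_only), nrow(a))

  for (seed in 1:20) {
    x <- rand_regions(sample(5:40, 1), seed = seed, span = 60000)
    y <- rand_regions(sample(5:40, 1), seed = seed + 1000, span = 60000)
    got <- match_regions(x, y)$pairs
    want <- oracle_match(x, y)
    expect_equal(got$a_idx, want$a_idx, info = paste("seed", seed))
    expect_equal(got$b_idx, want$b_idx, info = paste("seed", seed))
    expect_equal(got$overlap_bp, want$overlap_bp, info = paste("seed", seed))
  }
})

test_that("detect_changes: identity, planted switch, antisymmetry", {
  sa <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    state = c(rep("repressed", 5), rep("active", 5))
  )
  expect_equal(nrow(detect_changes(list(a = sa, b = sa))), 0)

  sb <- sa
  sb$state[3] <- "balanced"
  ch <- detect_changes(list(a = sa, b = sb))
  expect_equal(ch$gene_id, "g03")
  expect_equal(ch$state_from, "repressed")
  expect_equal(ch$state_to, "balanced")

  # antisymmetry: swapping the directions mirrors every transition
  rev <- detect_changes(list(b = sb, a = sa), from = "b", to = "a")
  expect_equal(rev$state_from, ch$state_to)
  expect_equal(rev$state_to, ch$state_from)

  disjoint <- dplyr::mutate(sb, gene_id = paste0("x", gene_id))
  expect_error(detect_changes(list(a = sa, b = disjoint)),
    class = "pcg_annotation_mismatch"
  )
})

test_that("detect_changes recovers a known transition table", {
  states <- c("repressed", "active", "balanced", "void", "other")
  withr::with_seed(81, {
    from <- sample(states, 100, replace = TRUE)
    to <- sample(states, 100, replace = TRUE)
  })
  sa <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), state = from)
  sb <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), state = to)
  ch <- detect_changes(list(a = sa, b = sb))
  got <- attr(ch, "summary")
  want <- table(from, to)
  for (i in seq_len(nrow(got))) {
    expect_equal(
      got$n[i],
      unname(want[got$state_from[i], got$state_to[i]])
    )
  }
  expect_equal(sum(got$n), sum(from != to))
})

test_that("venn_counts equals membership enumeration and sums to the union", {
  sets0 <- list(A = rand_regions(10, seed = 91), B = rand_regions(10, seed = 91), C = rand_regions(10, seed = 91))
  v0 <- venn_counts(sets0)
  expect_equal(v0$count[v0$pattern == "A&B&C"], attr(v0, "total"))
  expect_equal(sum(v0$count), attr(v0, "total"))

  for (seed in 1:15) {
    sets <- list(
      A = rand_regions(sample(4:20, 1), seed = seed, span = 50000),
      B = rand_regions(sample(4:20, 1), seed = seed + 300, span = 50000),
      C = rand_regions(sample(4:20, 1), seed = seed + 600, span = 50000)
    )
    got <- venn_counts(sets)
    want <- oracle_venn(sets)
    expect_equal(stats::setNames(got$count, got$pattern), want, info = paste("seed", seed))
    expect_equal(sum(got$count), attr(got, "total"))
  }
})

test_that("saturation_curve is a set-union under every ordering", {
  cats <- list(
    Sg4 = sprintf("g%03d", 1:60),
    BG3 = sprintf("g%03d", 30:80),
    D23 = sprintf("g%03d", c(1:10, 70:100))
  )
  sat <- saturation_curve(cats)
  expect_equal(length(unique(sat$ordering)), 6)
  for (ord in unique(sat$ordering)) {
    sub <- sat[sat$ordering == ord, ]
    acc <- character(0)
    for (i in seq_len(nrow(sub))) {
      acc <- union(acc, cats[[sub$condition[i]]])
      expect_equal(sub$cumulative[i], length(acc))
    }
  }
  # identical catalogues: flat after step 1; disjoint: linear growth
  flat <- saturation_curve(list(a = cats$Sg4, b = cats$Sg4, c = cats$Sg4),
    orderings = list(c("a", "b", "c"))
  )
  expect_equal(flat$cumulative, rep(60, 3))
  lin <- saturation_curve(list(a = c("x1", "x2"), b = c("y1", "y2")),
    orderings = list(c("a", "b"))
  )
  expect_equal(lin$cumulative, c(2, 4))
  expect_equal(lin$pct_increase[2], 100)
})

test_that("knockdown_effect on identical tracks gives ratios of exactly 1", {
  sim <- small_sim(n_genes = 40, seed = 15)
  tr <- simulate_tracks(sim$truth, seed = 16, antibodies = "ASH1")[["ASH1"]]
  sm <- smooth_track(average_replicates(tr))
  regions <- call_bound_regions(sm, max_distance_bp = 1000)
  expect_gt(nrow(regions), 0)
  rep <- knockdown_effect(regions, sm, sm, sim$truth$genes,
    n_background = 20, seed = 4
  )
  expect_true(all(rep$regions$ratio == 1))
  expect_true(all(rep$background$ratio == 1))
  # empty region set: background-only report
  rep0 <- knockdown_effect(regions[0, ], sm, sm, sim$truth$genes,
    n_background = 10, seed = 4
  )
  expect_equal(nrow(rep0$regions), 0)
  expect_equal(nrow(rep0$background), 10)
  expect_true(is.na(rep0$p_value))
})

test_that("background sampling is seeded, intergenic and non-overlapping", {
  sim <- small_sim(n_genes = 40, seed = 17)
  tr <- simulate_tracks(sim$truth, seed = 18, antibodies = "PC")[["PC"]]
  sm <- smooth_track(average_replicates(tr))
  regions <- tibble::tibble(chrom = sm$chrom[1], start = 0, end = 2000)
  r1 <- knockdown_effect(regions, sm, sm, sim$truth$genes, n_background = 30, seed = 9)
  r2 <- knockdown_effect(regions, sm, sm, sim$truth$genes, n_background = 30, seed = 9)
  expect_equal(r1$background, r2$background)
  bg <- r1$background
  genes <- sim$truth$genes
  for (i in seq_len(nrow(bg))) {
    expect_false(any(genes$chrom == bg$chrom[i] &
      genes$start - 1000 < bg$end[i] & bg$start[i] < genes$end + 1000))
  }
  expect_true(all(bg$start[-1] >= head(bg$end, -1) | bg$chrom[-1] != head(bg$chrom, -1)))
})

test_that("superposed_profile recovers planted peak geometry", {
  # flat track: flat fit at the constant
  pos <- seq(0, 200000, 36)
  flat <- probe_track("c", pos, rep(2, length(pos)), smoothed = TRUE)
  anchors <- tibble::tibble(chrom = "c", pos = c(50000, 100000), strand = "+")
  pm <- superposed_profile(flat, anchors)
  expect_true(all(abs(pm$fit$fit - 1) < 1e-6)) # log2(2) = 1

  # symmetric planted peak at the anchors: maximum within +/-100 of 0
  withr::with_seed(21, {
    val <- rep(1, length(pos)) * 2^rnorm(length(pos), 0, 0.2)
  })
  anchors4 <- tibble::tibble(
    chrom = "c", pos = c(50000, 100000, 150000, 180000), strand = "+"
  )
  for (a in anchors4$pos) {
    d <- abs(pos - a)
    bump <- pmax(0, 1 - d / 600) * log2(6) # triangular peak, apex at the anchor
    val <- val * 2^bump
  }
  peaked <- probe_track("c", pos, val, smoothed = TRUE)
  pm2 <- superposed_profile(peaked, anchors4)
  expect_lt(abs(profile_peak(pm2)), 100)

  # strand-randomised anchors of an asymmetric signal give a symmetric fit
  val3 <- rep(1, length(pos))
  shifted <- c(30000, 70000, 110000, 150000)
  for (a in shifted) val3[pos >= a + 1000 & pos <= a + 2000] <- 8
  asym <- probe_track("c", pos, val3, smoothed = TRUE)
  anch3 <- tibble::tibble(chrom = "c", pos = shifted, strand = c("+", "-", "+", "-"))
  pm3 <- superposed_profile(asym, anch3, fit = "none")
  up <- sum(pm3$samples$log2_ratio[pm3$samples$offset < 0] > 1)
  down <- sum(pm3$samples$log2_ratio[pm3$samples$offset > 0] > 1)
  # peak mass mirrored evenly (to within probe-grid phase)
  expect_lt(abs(up - down), 3)
  expect_gt(up, 0.4 * (up + down))
})

test_that("anchors without coverage are dropped and counted", {
  tr <- probe_track("c", seq(0, 1000, 36), rep(2, 28), smoothed = TRUE)
  anchors <- tibble::tibble(chrom = c("c", "nowhere"), pos = c(500, 500), strand = "+")
  pm <- superposed_profile(tr, anchors, window_bp = 600)
  expect_equal(attr(pm, "n_dropped"), 1L)
  expect_equal(pm$n_anchors, 1L)
})

test_that("profile_density bins observations reproducibly", {
  tr <- rand_track(300, seed = 31)
  pm <- superposed_profile(tr, tibble::tibble(chrom = "chrT", pos = 5000, strand = "+"),
    window_bp = 4000, fit = "none"
  )
  d <- profile_density(pm, offset_bin = 500, value_bin = 0.5)
  expect_equal(sum(d$count), nrow(pm$samples))
  expect_identical(d, profile_density(pm, offset_bin = 500, value_bin = 0.5))
})

test_that("correlate_domain_enrichment: exact, null and limiting behaviour", {
  tr <- rand_track(2000, seed = 41, p_enriched = 0.5)
  regions <- tibble::tibble(
    chrom = "chrT",
    start = seq(0, 70000, 4000),
    end = seq(0, 70000, 4000) + 3000
  )
  same <- correlate_domain_enrichment(tr, tr, regions)
  expect_equal(same$estimate, 1.0)

  # y = 2x + vanishing noise: r -> 1
  tr2 <- tr
  withr::with_seed(42, {
    tr2$value <- 2 * tr$value * 2^rnorm(nrow(tr), 0, 1e-6)
  })
  expect_gt(correlate_domain_enrichment(tr, tr2, regions)$estimate, 0.9999)

  # independent tracks, many regions: |r| small
  withr::with_seed(43, {
    pos <- seq(0, 36 * 39999, 36)
    x <- probe_track("c", pos, 2^rnorm(40000, 0, 0.5), smoothed = TRUE)
    y <- probe_track("c", pos, 2^rnorm(40000, 0, 0.5), smoothed = TRUE)
  })
  big <- tibble::tibble(
    chrom = "c", start = seq(0, 999000, 1000),
    end = seq(0, 999000, 1000) + 900
  )
  expect_lt(abs(correlate_domain_enrichment(x, y, big)$estimate), 0.1)

  expect_error(correlate_domain_enrichment(tr, tr, regions[1:2, ]),
    class = "pcg_empty_input"
  )
  const <- probe_track("chrT", tr$pos, rep(2, nrow(tr)), smoothed = TRUE)
  expect_error(correlate_domain_enrichment(const, tr, regions),
    class = "pcg_degenerate"
  )
})
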