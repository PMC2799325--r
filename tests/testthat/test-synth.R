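# The synthetic generator: determinism, planted landscapes, noise model,
# knockdown and expression simulation.

test_that("simulation is deterministic under the seed", {
  cfg <- sim_config(n_genes = 30, seed = 123)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(t1$genes, t2$genes)
  expect_identical(t1$marks, t2$marks)
  tr1 <- simulate_tracks(t1, seed = 5, antibodies = c("PC", "ASH1"))
  tr2 <- simulate_tracks(t2, seed = 5, antibodies = c("PC", "ASH1"))
  expect_identical(tr1$PC$rep1$value, tr2$PC$rep1$value)
  # different noise seed, same truth: different values
  tr3 <- simulate_tracks(t1, seed = 6, antibodies = "PC")
  expect_false(identical(tr1$PC$rep1$value, tr3$PC$rep1$value))
})

test_that("an all-void genome has no marks and no bound regions", {
  cfg <- sim_config(
    n_genes = 20,
    state_fractions = c(
      repressed = 0, active = 0, balanced = 0,
      void = 1, non_target = 0
    ),
    seed = 2
  )
  truth <- simulate_genome(cfg)
  expect_equal(nrow(truth$marks), 0)
  tracks <- simulate_tracks(truth, antibodies = "PC")
  sm <- smooth_track(average_replicates(tracks$PC))
  expect_equal(nrow(call_bound_regions(sm)), 0)
  expect_true(all(truth$genes$pcg_target))
})

test_that("zero noise reproduces the planted folds exactly", {
  cfg <- sim_config(n_genes = 15, noise_sd_log2 = 0, seed = 3)
  truth <- simulate_genome(cfg)
  tracks <- simulate_tracks(truth, antibodies = "H3K27me3")
  tr <- tracks$H3K27me3$rep1
  k27 <- truth$marks[truth$marks$antibody == "H3K27me3", ]
  for (i in seq_len(nrow(k27))) {
    inside <- tr$pos >= k27$start[i] & tr$pos < k27$end[i]
    expect_true(all(tr$value[inside] == cfg$domain_fold))
  }
  outside <- !Reduce(`|`, lapply(seq_len(nrow(k27)), function(i) {
    tr$pos >= k27$start[i] & tr$pos < k27$end[i]
  }))
  expect_true(all(tr$value[outside] == 1))
})

test_that("replicate averaging halves the noise variance", {
  cfg <- sim_config(n_genes = 10, seed = 4)
  truth <- simulate_genome(cfg)
  devs <- sapply(1:12, function(s) {
    tracks <- simulate_tracks(truth, seed = 100 + s, antibodies = "PC")
    avg <- average_replicates(tracks$PC)
    bg <- truth$probes$pos < truth$genes$start[1] - 2000
    c(
      single = stats::var(log2(tracks$PC$rep1$value[bg])),
      averaged = stats::var(log2(avg$value[bg]))
    )
  })
  expect_equal(mean(devs["averaged", ]) / mean(devs["single", ]), 0.5,
    tolerance = 0.15
  )
})

test_that("planted states follow the drawn fractions and the Fig-8 layouts", {
  cfg <- sim_config(n_genes = 500, seed = 6)
  truth <- simulate_genome(cfg)
  counts <- table(truth$genes$state)
  expect_equal(sum(counts), 500)
  # multinomial draw: each fraction within 5 sd of its expectation
  for (st in names(cfg$state_fractions)) {
    p <- cfg$state_fractions[[st]]
    expect_lt(abs(counts[[st]] - 500 * p), 5 * sqrt(500 * p * (1 - p)))
  }
  # repressed genes lie inside their H3K27me3 domain, with a fully loaded PRE
  g <- truth$genes[truth$genes$state == "repressed", ][1, ]
  mk <- truth$marks[truth$marks$gene_id == g$gene_id, ]
  dom <- mk[mk$antibody == "H3K27me3", ]
  expect_true(dom$start <= g$start && dom$end >= g$end)
  expect_setequal(
    mk$antibody[mk$role == "pre"],
    c("PC", "E(Z)", "TRX-C", "TRX-N")
  )
  # active genes have no PcG marks but broad ASH1/TRX-N/H3K27ac
  ga <- truth$genes[truth$genes$state == "active", ][1, ]
  mka <- truth$marks[truth$marks$gene_id == ga$gene_id, ]
  expect_false(any(mka$antibody %in% c("PC", "E(Z)", "H3K27me3")))
  expect_setequal(
    mka$antibody[mka$role == "domain"],
    c("ASH1", "TRX-N", "H3K27ac")
  )
  # neighbouring genes' planted domains never touch (unambiguous truth)
  for (ab in unique(truth$marks$antibody[truth$marks$role == "domain"])) {
    doms <- truth$marks[truth$marks$role == "domain" & truth$marks$antibody == ab, ]
    doms <- doms[order(doms$start), ]
    expect_true(all(doms$start[-1] >= head(doms$end, -1)), info = ab)
  }
})

test_that("planted PRE summits are recovered within two probes", {
  cfg <- sim_config(n_genes = 80, seed = 8)
  truth <- simulate_genome(cfg)
  tracks <- simulate_tracks(truth, seed = 80, antibodies = c("PC", "E(Z)"))
  pc_sm <- smooth_track(average_replicates(tracks$PC))
  ez_sm <- smooth_track(average_replicates(tracks$`E(Z)`))
  pc <- call_bound_regions(pc_sm, max_distance_bp = 500)
  ez <- call_bound_regions(ez_sm, max_distance_bp = 500)
  pres <- define_computational_pres(pc, ez, pc_track = pc_sm, ez_track = ez_sm)
  planted <- truth$marks[truth$marks$antibody == "PC" & truth$marks$role == "pre", ]
  planted$summit <- (planted$start + planted$end) / 2
  m <- match_regions(pres, planted[, c("chrom", "start", "end", "summit")])
  expect_equal(nrow(m$pairs), nrow(planted))
  err <- abs(pres$summit[m$pairs$a_idx] - planted$summit[m$pairs$b_idx])
  expect_true(all(err <= 2 * cfg$probe_step_bp))
})

test_that("knockdown with residual 1 and no switching is the identity", {
  cfg <- sim_config(n_genes = 20, seed = 10)
  truth <- simulate_genome(cfg)
  kd <- simulate_knockdown(truth, target = "ASH1", residual = 1, switch_fraction = 0)
  expect_identical(kd$truth$marks, truth$marks)
  expect_identical(kd$truth$genes, truth$genes)
  expect_error(simulate_knockdown(truth, "ASH1", residual = 0),
    class = "pcg_bad_params"
  )
  expect_error(simulate_knockdown(truth, "NOPE"), class = "pcg_bad_params")
})

test_that("knockdown depletion scales the target and its linked partner", {
  cfg <- sim_config(n_genes = 40, seed = 11)
  truth <- simulate_genome(cfg)
  kd <- simulate_knockdown(truth, target = "ASH1", residual = 0.2)
  m0 <- truth$marks
  m1 <- kd$truth$marks
  ash1 <- m0$antibody == "ASH1"
  expect_equal(m1$fold[ash1], 0.2 * m0$fold[ash1])
  # TRX-N leaves domains with ASH1 but stays at PREs
  trxn_dom <- m0$antibody == "TRX-N" & m0$role != "pre"
  trxn_pre <- m0$antibody == "TRX-N" & m0$role == "pre"
  expect_equal(m1$fold[trxn_dom], 0.2 * m0$fold[trxn_dom])
  expect_equal(m1$fold[trxn_pre], m0$fold[trxn_pre])
})

test_that("switching sends sensitive repressed genes to balanced", {
  cfg <- sim_config(
    n_genes = 100,
    state_fractions = c(
      repressed = 1, active = 0, balanced = 0,
      void = 0, non_target = 0
    ),
    seed = 12
  )
  truth <- simulate_genome(cfg)
  kd <- simulate_knockdown(truth,
    target = "PC", residual = 0.2,
    switch_fraction = 0.1, deplete_signal = FALSE, seed = 99
  )
  expect_gt(length(kd$switched), 0)
  sw <- kd$truth$genes[kd$truth$genes$gene_id %in% kd$switched, ]
  expect_true(all(sw$state == "balanced"))
  # switched genes keep a (weakened) H3K27me3 domain and gain TSS-proximal ASH1
  mk <- kd$truth$marks[kd$truth$marks$gene_id %in% kd$switched, ]
  k27 <- mk[mk$antibody == "H3K27me3", ]
  expect_true(all(k27$fold < cfg$domain_fold & k27$fold > 2))
  expect_true(all(kd$switched %in% mk$gene_id[mk$antibody == "ASH1"]))
  # switching count is binomial around switch_fraction
  draws <- vapply(1:20, function(s) {
    length(simulate_knockdown(truth,
      target = "PC", switch_fraction = 0.1,
      deplete_signal = FALSE, seed = s
    )$switched)
  }, numeric(1))
  expect_gt(mean(draws), 5)
  expect_lt(mean(draws), 15)
})

test_that("simulated expression separates states at the planted ratios", {
  cfg <- sim_config(n_genes = 200, seed = 13)
  truth <- simulate_genome(cfg)
  ex <- simulate_expression(truth)
  med <- tapply(ex$quantity, ex$state, stats::median)
  expect_equal(unname(med["active"] / med["balanced"]), 10, tolerance = 0.5)
  expect_equal(unname(med["balanced"] / med["repressed"]), 10, tolerance = 0.5)
  # all-void genome: everything at the silent level
  cfg0 <- sim_config(
    n_genes = 30,
    state_fractions = c(
      repressed = 0, active = 0, balanced = 0,
      void = 1, non_target = 0
    ), seed = 14
  )
  ex0 <- simulate_expression(simulate_genome(cfg0))
  expect_lt(max(ex0$quantity), 10) # no gene anywhere near the active level
})

test_that("8 active vs 8 silent genes give complete separation over seeds", {
  cfg <- sim_config(n_genes = 40, seed = 20)
  truth <- simulate_genome(cfg)
  u_vals <- vapply(1:100, function(s) {
    ex <- simulate_expression(truth, seed = s)
    r1 <- ex[ex$replicate == "rep1", ]
    act <- r1$quantity[r1$state == "active"][1:8]
    rep_ <- r1$quantity[r1$state %in% c("repressed", "void")][1:8]
    rank_sum_test(act, rep_)$U
  }, numeric(1))
  expect_true(all(u_vals == 64))
})

test_that("class II layouts are planted only on request", {
  cfg <- sim_config(n_genes = 60, seed = 15, plant_class2 = TRUE)
  truth <- simulate_genome(cfg)
  c2 <- truth$genes$gene_id[truth$genes$class2]
  expect_gt(length(c2), 0)
  mk <- truth$marks[truth$marks$gene_id %in% c2, ]
  expect_false(any(mk$antibody == "E(Z)"))
  expect_true(any(mk$antibody == "PC"))
  cfg0 <- sim_config(n_genes = 60, seed = 15)
  expect_false(any(simulate_genome(cfg0)$genes$class2))
})

test_that("infeasible packing is an error", {
  cfg <- sim_config(n_genes = 50, chrom_length_bp = 10000, seed = 16)
  expect_error(simulate_genome(cfg), class = "pcg_no_space")
})
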