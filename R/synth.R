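# Synthetic genome, planted chromatin states, probe tracks, knockdown
# perturbations and matched expression — the pipeline's test bed.

#' Simulation configuration
#'
#' Defaults describe a tiling-array experiment: a 36 bp probe grid, two
#' replicates, multiplicative log-normal noise (sd 0.35 on the log2 scale),
#' broad domains at 3-fold enrichment, PRE/promoter peaks at 6-/4-fold.
#' State fractions cover the four chromatin states of PcG target genes plus
#' non-target genes.
#'
#' @param n_genes Number of transcription units (default 500).
#' @param probe_step_bp Probe spacing in bp (default 36).
#' @param n_replicates Replicates per antibody (default 2).
#' @param state_fractions Named fractions over repressed, active, balanced,
#'   void, non_target; must sum to 1.
#' @param domain_fold Enrichment of broad domains (H3K27me3; ASH1/TRX N-ter/
#'   H3K27ac over active units), default 3.
#' @param peak_fold Enrichment of PRE peaks (PC, E(Z), TRX), default 6.
#' @param promoter_fold Enrichment of promoter peaks (Pol II, H3K4me3,
#'   promoter-proximal H3K27ac and ASH1/TRX N-ter), default 4.
#' @param noise_sd_log2 Log2-scale sd of the multiplicative noise, default
#'   0.35.
#' @param pre_width_bp Width of planted PREs (default 1000; PREs are narrow
#'   elements).
#' @param chrom_length_bp Chromosome length; `NULL` (default) sizes the
#'   chromosome to fit the packed genes.
#' @param chrom Chromosome name.
#' @param expr_levels Relative expression by state class
#'   (active : balanced : silent = 100 : 10 : 1).
#' @param plant_class2 Also plant PC-without-E(Z) (Class II) layouts on a
#'   subset of repressed genes.
#' @param seed Base seed; all generator randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500,
                       probe_step_bp = 36,
                       n_replicates = 2,
                       state_fractions = c(
                         repressed = 0.25, active = 0.25,
                         balanced = 0.20, void = 0.10, non_target = 0.20
                       ),
                       domain_fold = 3.0,
                       peak_fold = 6.0,
                       promoter_fold = 4.0,
                       noise_sd_log2 = 0.35,
                       pre_width_bp = 1000,
                       chrom_length_bp = NULL,
                       chrom = "chrS",
                       expr_levels = c(active = 100, balanced = 10, silent = 1),
                       plant_class2 = FALSE,
                       seed = 1L) {
  states <- c("repressed", "active", "balanced", "void", "non_target")
  if (!setequal(names(state_fractions), states)) {
    abort("`state_fractions` must name repressed, active, balanced, void, non_target.",
      class = "pcg_bad_params"
    )
  }
  if (abs(sum(state_fractions) - 1) > 1e-8) {
    abort("`state_fractions` must sum to 1.", class = "pcg_bad_params")
  }
  if (any(c(domain_fold, peak_fold, promoter_fold) <= 1)) {
    abort("All planted folds must be > 1.", class = "pcg_bad_params")
  }
  if (probe_step_bp < 1) abort("`probe_step_bp` must be >= 1.", class = "pcg_bad_params")
  structure(
    list(
      n_genes = n_genes, probe_step_bp = probe_step_bp,
      n_replicates = n_replicates,
      state_fractions = state_fractions[states],
      domain_fold = domain_fold, peak_fold = peak_fold,
      promoter_fold = promoter_fold, noise_sd_log2 = noise_sd_log2,
      pre_width_bp = pre_width_bp, chrom_length_bp = chrom_length_bp,
      chrom = chrom, expr_levels = expr_levels,
      plant_class2 = plant_class2, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# strand-oriented half-open interval [tss + s*lo, tss + s*hi) of width hi-lo
oriented_ivl <- function(tss, lo, hi, strand) {
  s <- ifelse(strand == "-", -1, 1)
  a <- tss + s * lo
  b <- tss + s * hi
  tibble(start = pmin(a, b), end = pmax(a, b))
}

#' Simulate a toy genome with planted chromatin states
#'
#' Lays out non-overlapping transcription units (log-normal lengths, clamped
#' to 2-50 kb) on one chromosome, draws a state per gene from the configured
#' fractions, and plants the mark landscape of each state:
#' \describe{
#'   \item{repressed}{a broad H3K27me3 domain spanning the unit +/- 20%, and
#'     a PRE at the TSS binding PC, E(Z), TRX C-ter and TRX N-ter.}
#'   \item{active}{broad ASH1, TRX N-ter and H3K27ac domains over the unit
#'     (+/- 10%), TRX C-ter at the PRE and the TSS, Pol II and H3K4me3
#'     promoter peaks, and an H3K27ac promoter peak centred +450 bp
#'     downstream of the TSS.}
#'   \item{balanced}{the repressed landscape plus promoter-confined
#'     ASH1/TRX N-ter (TSS +/- 1 kb), Pol II, H3K4me3 and H3K27ac peaks.}
#'   \item{void}{no marks at all (the gene remains a catalogued PcG
#'     target).}
#'   \item{non_target}{no PcG/TrxG marks; half of these genes are plain
#'     active (Pol II, H3K4me3, promoter H3K27ac), half silent.}
#' }
#' Intergenic gaps are sized so that planted domains never touch the
#' neighbouring unit, keeping the ground truth unambiguous. Deterministic
#' under the config seed (R's Mersenne-Twister generator).
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `genes` (annotation + planted state,
#'   expression level, target/sensitivity flags), `marks` (planted intervals
#'   per gene x antibody with fold and role), `probes` (the probe grid),
#'   `chrom_length_bp`, `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    len <- round(pmin(50000, pmax(2000, exp(rnorm(n, log(8000), 0.6)))))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    state <- sample(names(config$state_fractions), n,
      replace = TRUE, prob = config$state_fractions
    )
    # pack genes left to right; the gap before gene i leaves room for the
    # +/-20% domain extensions of both neighbours, and intergenic space is
    # kept a realistic fraction (~half) of the chromosome
    prev_len <- c(0, len[-n])
    gap <- 3000 + 0.2 * prev_len + 0.2 * len + round(runif(n, 0, 12000))
    start <- cumsum(gap) + c(0, cumsum(len))[seq_len(n)]
    end <- start + len
    needed <- end[n] + 0.2 * len[n] + 2000
    chrom_length <- config$chrom_length_bp %||% needed
    if (chrom_length < needed) {
      abort(sprintf(
        "Genes do not fit: need %d bp, chromosome is %d bp.",
        ceiling(needed), ceiling(chrom_length)
      ), class = "pcg_no_space")
    }
    tss <- ifelse(strand == "+", start, end - 1)
    nt_active <- state == "non_target" & rbinom(n, 1, 0.5) == 1
    class2 <- rep(FALSE, n)
    if (isTRUE(config$plant_class2)) {
      idx <- which(state == "repressed")
      class2[idx[seq_along(idx) %% 2 == 0]] <- TRUE
    }
    genes <- tibble(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = config$chrom, start = start, end = end,
      strand = strand, tss = tss, state = state,
      nt_active = nt_active, class2 = class2,
      pcg_target = state %in% c("repressed", "active", "balanced", "void"),
      kd_sensitive = state == "repressed",
      expr_level = dplyr::case_when(
        state == "active" ~ config$expr_levels[["active"]],
        state == "balanced" ~ config$expr_levels[["balanced"]],
        state == "non_target" & nt_active ~ config$expr_levels[["active"]],
        TRUE ~ config$expr_levels[["silent"]]
      )
    )
    marks <- plant_marks(genes, config)
    probes <- tibble(
      chrom = config$chrom,
      pos = seq(0, chrom_length - 1, by = config$probe_step_bp)
    )
    structure(
      list(
        genes = genes, marks = marks, probes = probes,
        chrom_length_bp = chrom_length, config = config
      ),
      class = "sim_truth"
    )
  })
}

# Planted mark intervals for one gene table; deterministic (no RNG).
plant_marks <- function(genes, config) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    plant_gene_marks(g, config)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      gene_id = character(), antibody = character(), chrom = character(),
      start = numeric(), end = numeric(), fold = numeric(), role = character()
    ))
  }
  out
}

plant_gene_marks <- function(g, config) {
  len <- g$end - g$start
  half_pre <- config$pre_width_bp / 2
  pre <- tibble(start = g$tss - half_pre, end = g$tss + half_pre)
  mk <- function(antibody, start, end, fold, role) {
    tibble(
      gene_id = g$gene_id, antibody = antibody, chrom = g$chrom,
      start = pmax(0, start), end = end, fold = fold, role = role
    )
  }
  promoter_peaks <- function(k27ac_fold) {
    polII <- mk("PolII", g$tss - 500, g$tss + 500, config$promoter_fold, "promoter")
    k4 <- oriented_ivl(g$tss, 0, 1000, g$strand)
    k4me3 <- mk("H3K4me3", k4$start, k4$end, config$promoter_fold, "promoter")
    ac <- oriented_ivl(g$tss, -50, 950, g$strand) # centred +450 downstream
    k27ac <- mk("H3K27ac", ac$start, ac$end, k27ac_fold, "promoter")
    bind_rows(polII, k4me3, k27ac)
  }
  pre_peaks <- function(antibodies) {
    bind_rows(lapply(antibodies, function(ab) {
      mk(ab, pre$start, pre$end, config$peak_fold, "pre")
    }))
  }
  switch(g$state,
    repressed = bind_rows(
      mk("H3K27me3", g$start - 0.2 * len, g$end + 0.2 * len, config$domain_fold, "domain"),
      pre_peaks(if (g$class2) c("PC", "TRX-C") else c("PC", "E(Z)", "TRX-C", "TRX-N"))
    ),
    balanced = bind_rows(
      mk("H3K27me3", g$start - 0.2 * len, g$end + 0.2 * len, config$domain_fold, "domain"),
      pre_peaks(c("PC", "E(Z)", "TRX-C", "TRX-N")),
      mk("ASH1", g$tss - 1000, g$tss + 1000, config$promoter_fold, "promoter"),
      mk("TRX-N", g$tss - 1000, g$tss + 1000, config$promoter_fold, "promoter"),
      promoter_peaks(config$promoter_fold)
    ),
    active = bind_rows(
      mk("ASH1", g$start - 0.1 * len, g$end + 0.1 * len, config$domain_fold, "domain"),
      mk("TRX-N", g$start - 0.1 * len, g$end + 0.1 * len, config$domain_fold, "domain"),
      mk("H3K27ac", g$start - 0.1 * len, g$end + 0.1 * len, config$domain_fold, "domain"),
      pre_peaks("TRX-C"),
      mk("TRX-C", g$tss - 500, g$tss + 500, config$promoter_fold, "promoter"),
      promoter_peaks(config$peak_fold)
    ),
    void = NULL,
    non_target = if (g$nt_active) promoter_peaks(config$promoter_fold) else NULL
  )
}

#' Simulate probe tracks from planted truth
#'
#' The planted fold at a probe is the maximum fold of any mark interval
#' covering it (background 1.0 elsewhere); each replicate observes
#' `fold * 2^N(0, noise_sd_log2)` with independent noise. Deterministic
#' under `seed`.
#'
#' @param truth A `sim_truth` from [simulate_genome()] (or the `truth`
#'   element of [simulate_knockdown()]).
#' @param condition Condition label stamped on the tracks.
#' @param seed Noise seed (default `config$seed + 1`).
#' @param antibodies Antibody subset to simulate (default all of
#'   [chip_antibodies]).
#' @return A named list: antibody -> list of replicate `probe_track`s.
#' @export
simulate_tracks <- function(truth, condition = "control", seed = NULL,
                            antibodies = chip_antibodies) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  seed <- seed %||% (config$seed + 1L)
  pos <- truth$probes$pos
  chrom <- truth$probes$chrom
  withr::with_seed(seed, {
    out <- list()
    for (ab in antibodies) {
      fold <- planted_fold(truth, ab)
      reps <- lapply(seq_len(config$n_replicates), function(r) {
        value <- fold * 2^rnorm(length(pos), 0, config$noise_sd_log2)
        new_probe_track(
          tibble(chrom = chrom, pos = pos, value = value),
          antibody = ab, condition = condition,
          replicate = paste0("rep", r), smoothed = FALSE
        )
      })
      names(reps) <- paste0("rep", seq_len(config$n_replicates))
      out[[ab]] <- reps
    }
    out
  })
}

# Planted (noise-free) fold level per probe for one antibody. Overlapping
# enrichment marks combine by max; knockdown-depleted marks (fold < 1)
# combine by min and take precedence over background.
planted_fold <- function(truth, antibody) {
  pos <- truth$probes$pos
  fold <- rep(1, length(pos))
  down <- rep(NA_real_, length(pos))
  m <- truth$marks[truth$marks$antibody == antibody, , drop = FALSE]
  if (nrow(m) > 0) {
    for (i in seq_len(nrow(m))) {
      idx <- probes_in_interval(pos, m$start[i], m$end[i])
      if (length(idx) == 0) next
      if (m$fold[i] >= 1) {
        fold[idx] <- pmax(fold[idx], m$fold[i])
      } else {
        down[idx] <- pmin(down[idx], m$fold[i], na.rm = TRUE)
      }
    }
  }
  ifelse(is.na(down), fold, down)
}

#' Perturb planted truth with an RNAi knockdown
#'
#' Signal depletion scales the target antibody's planted enrichment by
#' `residual` (the residual protein level; `residual = 1` leaves the truth
#' unchanged, and the measured region-enrichment ratio recovers `residual`).
#' Interdependent binding is modelled: knocking down ASH1 also depletes TRX
#' N-ter within broad domains but not at PREs, and vice versa. A
#' `switch_fraction` of knockdown-sensitive repressed genes switches state
#' from repressed to balanced — gaining promoter-proximal ASH1/TRX N-ter,
#' Pol II, H3K4me3 and H3K27ac while their H3K27me3 domain weakens — and the
#' switched genes' new landscape (which retains PcG binding, as the balanced
#' state does) is exempt from depletion.
#'
#' @param truth A `sim_truth`.
#' @param target Antibody to knock down (one of [chip_antibodies]).
#' @param residual Residual signal fraction in (0, 1] (default 0.2).
#' @param switch_fraction Probability that a sensitive repressed gene
#'   switches to balanced (default 0).
#' @param deplete_signal Scale the target's tracks by `residual`? Set to
#'   `FALSE` to model a knockdown whose chromatin-level binding persists at
#'   unswitched loci (as observed for PC).
#' @param seed Seed for the switching draw (default `config$seed + 2`).
#' @return A list: `truth` (perturbed `sim_truth`), `switched` (gene ids),
#'   `target`, `residual`.
#' @export
simulate_knockdown <- function(truth, target, residual = 0.2,
                               switch_fraction = 0, deplete_signal = TRUE,
                               seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!target %in% chip_antibodies) {
    abort(sprintf("Unknown antibody '%s'.", target), class = "pcg_bad_params")
  }
  if (residual <= 0 || residual > 1) {
    abort("`residual` must be in (0, 1].", class = "pcg_bad_params")
  }
  config <- truth$config
  seed <- seed %||% (config$seed + 2L)
  genes <- truth$genes
  marks <- truth$marks
  switched <- character(0)
  withr::with_seed(seed, {
    sensitive <- which(genes$state == "repressed" & genes$kd_sensitive)
    if (switch_fraction > 0 && length(sensitive) > 0) {
      hit <- sensitive[rbinom(length(sensitive), 1, switch_fraction) == 1]
      switched <- genes$gene_id[hit]
    }
  })
  if (length(switched) > 0) {
    genes$state[genes$gene_id %in% switched] <- "balanced"
    genes$expr_level[genes$gene_id %in% switched] <- config$expr_levels[["balanced"]]
    marks <- marks[!marks$gene_id %in% switched, , drop = FALSE]
    new_marks <- plant_marks(genes[genes$gene_id %in% switched, , drop = FALSE], config)
    # the switched genes' H3K27me3 domain weakens but persists
    k27 <- new_marks$antibody == "H3K27me3"
    new_marks$fold[k27] <- 1 + 0.75 * (new_marks$fold[k27] - 1)
    marks <- bind_rows(marks, new_marks)
  }
  if (isTRUE(deplete_signal) && residual < 1) {
    exempt <- marks$gene_id %in% switched
    hit <- marks$antibody == target & !exempt
    marks$fold[hit] <- residual * marks$fold[hit]
    linked <- switch(target,
      "ASH1" = "TRX-N",
      "TRX-N" = "ASH1",
      NULL
    )
    if (!is.null(linked)) {
      # interdependent broad binding: the partner leaves domains, not PREs
      hit2 <- marks$antibody == linked & marks$role != "pre" & !exempt
      marks$fold[hit2] <- residual * marks$fold[hit2]
    }
  }
  new_truth <- truth
  new_truth$genes <- genes
  new_truth$marks <- marks
  list(truth = new_truth, switched = switched, target = target, residual = residual)
}

#' Simulate qRT-PCR-style expression values
#'
#' Relative quantities (fractions of a reference transcript) follow the
#' planted state: active 100, balanced 10, repressed/void/silent 1 by
#' default, with log-normal replicate scatter. Genes that switched state
#' inherit their new state's level.
#'
#' @param truth A `sim_truth`.
#' @param seed Scatter seed (default `config$seed + 3`).
#' @param scatter_sd_log2 Replicate scatter on the log2 scale (default: the
#'   config's `noise_sd_log2`).
#' @return A tibble: `gene_id`, `state`, `replicate`, `quantity`.
#' @export
simulate_expression <- function(truth, seed = NULL, scatter_sd_log2 = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  seed <- seed %||% (config$seed + 3L)
  sdl <- scatter_sd_log2 %||% config$noise_sd_log2
  genes <- truth$genes
  withr::with_seed(seed, {
    bind_rows(lapply(seq_len(config$n_replicates), function(r) {
      tibble(
        gene_id = genes$gene_id,
        state = genes$state,
        replicate = paste0("rep", r),
        quantity = genes$expr_level * 2^rnorm(nrow(genes), 0, sdl)
      )
    })) |> arrange(.data$gene_id, .data$replicate)
  })
}
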