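# Independent brute-force oracles. Each recomputes a statistic by the most
# literal route available (explicit loops, pairwise scans, full enumeration)
# and is kept free of the package's own code paths.

oracle_geom_mean <- function(value_matrix) {
  apply(value_matrix, 1, function(v) exp(mean(log(v))))
}

# O(n^2) windowed mean of log2 ratios
oracle_smooth <- function(pos, value, window_bp) {
  vapply(seq_along(pos), function(i) {
    w <- value[abs(pos - pos[i]) <= window_bp]
    w <- w[!is.na(w)]
    if (length(w) == 0) NA_real_ else 2^mean(log2(w))
  }, numeric(1))
}

# scan of every k-window of in-region probe values
oracle_enrichment <- function(values, k) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < k) {
    return(mean(values))
  }
  max(vapply(seq_len(n - k + 1), function(i) mean(values[i:(i + k - 1)]), numeric(1)))
}

# quadratic grouping: qualifying probes i < j share a region iff every
# successive gap between qualifying probes in [i, j] is <= max_distance
oracle_bound_regions <- function(pos, value, fold_cutoff, max_distance_bp,
                                 min_probes, step) {
  q <- which(!is.na(value) & value >= fold_cutoff)
  if (length(q) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0), n_probes = integer(0)))
  }
  nq <- length(q)
  same <- diag(TRUE, nq)
  for (i in seq_len(nq)) {
    for (j in seq_len(nq)) {
      if (i < j) {
        gaps <- diff(pos[q[i:j]])
        same[i, j] <- same[j, i] <- all(gaps <= max_distance_bp)
      }
    }
  }
  label <- integer(nq)
  next_label <- 0
  for (i in seq_len(nq)) {
    if (label[i] == 0) {
      next_label <- next_label + 1
      label[same[i, ]] <- next_label
    }
  }
  out <- do.call(rbind, lapply(unique(label), function(l) {
    members <- q[label == l]
    if (length(members) < min_probes) {
      return(NULL)
    }
    data.frame(
      start = pos[members[1]],
      end = pos[members[length(members)]] + step,
      n_probes = length(members)
    )
  }))
  if (is.null(out)) {
    return(data.frame(start = numeric(0), end = numeric(0), n_probes = integer(0)))
  }
  out[order(out$start), , drop = FALSE]
}

# all-pairs overlap test on half-open intervals
oracle_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i])
  }, logical(1))
}

# greedy maximum-overlap pairing by repeated global scan of the full
# overlap matrix (ties: leftmost a, then leftmost b)
oracle_match <- function(a, b) {
  ov <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        ov[i, j] <- max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
      }
    }
  }
  pairs <- NULL
  while (any(ov >= 1)) {
    best <- which(ov == max(ov), arr.ind = TRUE)
    best <- best[order(
      a$chrom[best[, 1]], a$start[best[, 1]],
      b$start[best[, 2]]
    ), , drop = FALSE][1, ]
    pairs <- rbind(pairs, data.frame(
      a_idx = best[1], b_idx = best[2],
      overlap_bp = ov[best[1], best[2]]
    ))
    ov[best[1], ] <- 0
    ov[, best[2]] <- 0
  }
  if (is.null(pairs)) {
    return(data.frame(a_idx = integer(0), b_idx = integer(0), overlap_bp = numeric(0)))
  }
  pairs[order(pairs$a_idx), , drop = FALSE]
}

# membership enumeration for three sets: pool intervals, form transitive
# overlap clusters by repeated sweeps, count membership patterns
oracle_venn <- function(sets) {
  pooled <- do.call(rbind, lapply(names(sets), function(nm) {
    df <- sets[[nm]]
    if (nrow(df) == 0) {
      return(NULL)
    }
    data.frame(chrom = df$chrom, start = df$start, end = df$end, set = nm)
  }))
  nms <- names(sets)
  patterns <- unlist(lapply(1:3, function(k) {
    apply(combn(nms, k), 2, paste, collapse = "&")
  }))
  if (is.null(pooled)) {
    return(stats::setNames(rep(0L, 7), patterns))
  }
  n <- nrow(pooled)
  label <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (pooled$chrom[i] == pooled$chrom[j] &&
          pooled$start[i] < pooled$end[j] && pooled$start[j] < pooled$end[i] &&
          label[i] != label[j]) {
          label[label == max(label[i], label[j])] <- min(label[i], label[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  pat <- vapply(unique(label), function(l) {
    members <- sort(unique(pooled$set[label == l]))
    paste(nms[nms %in% members], collapse = "&")
  }, character(1))
  counts <- table(factor(pat, levels = patterns))
  stats::setNames(as.integer(counts), patterns)
}

# exact one-sided rank-sum p by enumerating group assignments and counting
# (a > b) pairs directly (no rank arithmetic)
oracle_rank_sum <- function(a, b) {
  u_of <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
  }
  pooled <- c(a, b)
  n_a <- length(a)
  u_obs <- u_of(a, b)
  sets <- combn(length(pooled), n_a)
  u_all <- apply(sets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  list(
    U = u_obs,
    p_one = mean(u_all >= u_obs),
    p_two = mean(abs(u_all - n_a * length(b) / 2) >= abs(u_obs - n_a * length(b) / 2))
  )
}

# per-gene activity by explicit window scans
oracle_activity <- function(polII_regions, k4_track, genes, tss_window = 250,
                            k4_center = 500, k4_half = 250, cutoff = 2) {
  vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    lo <- g$tss - tss_window
    hi <- g$tss + tss_window
    pol <- any(polII_regions$chrom == g$chrom &
      polII_regions$start <= hi & polII_regions$end > lo)
    s <- if (g$strand == "-") -1 else 1
    wlo <- g$tss + s * k4_center - k4_half
    whi <- g$tss + s * k4_center + k4_half
    v <- k4_track$value[k4_track$chrom == g$chrom &
      k4_track$pos >= wlo & k4_track$pos <= whi]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(NA)
    }
    pol && mean(v) >= cutoff
  }, logical(1))
}
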