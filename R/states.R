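# Gene activity and the four-way chromatin-state classification.

#' Call transcriptional activity per gene
#'
#' A gene is called active when RNA Pol II binds at its TSS (a Pol II bound
#' region overlaps TSS +/- `tss_window_bp`) and H3K4me3 is enriched at
#' position +500 bp: the mean smoothed H3K4me3 ratio over the strand-oriented
#' window `[TSS + k4_center_bp - k4_halfwidth_bp, TSS + k4_center_bp +
#' k4_halfwidth_bp]` is at or above `fold_cutoff`. Genes with no covered
#' probe in the +500 window get `active = NA` ("unknown") and are excluded
#' downstream with a logged count (attribute `n_unknown`).
#'
#' @param polII_regions Pol II bound regions (tibble).
#' @param k4me3_track Smoothed H3K4me3 `probe_track`.
#' @param genes Gene annotation tibble with `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss` (see [read_annotation()]).
#' @param tss_window_bp Half-width of the Pol II window around the TSS
#'   (default 250).
#' @param k4_center_bp Offset of the H3K4me3 window centre downstream of the
#'   TSS (default +500).
#' @param k4_halfwidth_bp Half-width of the H3K4me3 window (default 250).
#' @param fold_cutoff Enrichment cutoff for the H3K4me3 window mean.
#' @return A tibble: `gene_id`, `polII_at_tss`, `k4me3_at_plus500`, `active`.
#' @export
call_gene_activity <- function(polII_regions, k4me3_track, genes,
                               tss_window_bp = 250, k4_center_bp = 500,
                               k4_halfwidth_bp = 250, fold_cutoff = 2) {
  stop_if_not_track(k4me3_track)
  if (!is_smoothed(k4me3_track)) {
    abort("call_gene_activity() requires a smoothed H3K4me3 track.",
      class = "pcg_precondition"
    )
  }
  strand_sign <- ifelse(genes$strand == "-", -1, 1)
  tss_win <- tibble(
    chrom = genes$chrom,
    start = genes$tss - tss_window_bp,
    end = genes$tss + tss_window_bp + 1
  )
  polII_at_tss <- overlaps_any(tss_win, polII_regions)
  k4_lo <- genes$tss + strand_sign * k4_center_bp - k4_halfwidth_bp
  k4_hi <- genes$tss + strand_sign * k4_center_bp + k4_halfwidth_bp
  k4mean <- rep(NA_real_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    sel <- which(k4me3_track$chrom == ch)
    pos <- k4me3_track$pos[sel]
    val <- k4me3_track$value[sel]
    for (i in which(genes$chrom == ch)) {
      idx <- probes_in_interval(pos, k4_lo[i], k4_hi[i] + 1)
      v <- val[idx]
      v <- v[!is.na(v)]
      if (length(v) > 0) k4mean[i] <- mean(v)
    }
  }
  k4me3_at_plus500 <- ifelse(is.na(k4mean), NA, k4mean >= fold_cutoff)
  out <- tibble(
    gene_id = genes$gene_id,
    polII_at_tss = polII_at_tss,
    k4me3_at_plus500 = k4me3_at_plus500,
    active = ifelse(is.na(k4me3_at_plus500), NA, polII_at_tss & k4me3_at_plus500)
  )
  attr(out, "n_unknown") <- sum(is.na(out$active))
  out
}

#' Flag joint ASH1/TRX N-ter domains
#'
#' Each ASH1 region (typically the dual-antibody consensus) is flagged
#' `joint` when it overlaps a TRX N-ter bound region, and `broad` when its
#' span is at least `broad_min_bp` (default 10 kb, the lower bound of the
#' broad-domain length range).
#'
#' @param ash1_consensus ASH1 bound regions.
#' @param trxN TRX N-ter bound regions from the same condition.
#' @param broad_min_bp Minimum span of a "broad" domain.
#' @return `ash1_consensus` with logical `joint` and `broad` columns; the
#'   joint fraction is attached as attribute `fraction_joint`.
#' @export
ash1_trxN_domain_call <- function(ash1_consensus, trxN, broad_min_bp = 10000) {
  out <- ash1_consensus
  out$joint <- overlaps_any(out, trxN)
  out$broad <- (out$end - out$start) >= broad_min_bp
  attr(out, "fraction_joint") <- if (nrow(out) == 0) NA_real_ else mean(out$joint)
  out
}

#' Assemble the per-gene evidence vector
#'
#' Each boolean is an overlap test between the gene (its transcription unit,
#' its TSS window, or its catalogued PREs, as appropriate) and the
#' corresponding region set:
#' \describe{
#'   \item{in_h3k27me3_domain, pc_bound, ez_bound, h3k27ac_domain_overlap}{
#'     transcription unit overlaps the H3K27me3 / PC / E(Z) / H3K27ac
#'     bound-region set.}
#'   \item{trxC_at_pre, trxN_at_pre}{some catalogued PRE overlapping the unit
#'     carries TRX C-ter / TRX N-ter occupancy (see [pre_occupancy()]).}
#'   \item{ash1_trxN_domain_overlap}{unit overlaps a joint ASH1/TRX N-ter
#'     region (see [ash1_trxN_domain_call()]).}
#'   \item{ash1_trxN_at_tss}{a joint region overlaps TSS +/- `tss_window_bp`.}
#'   \item{active}{the activity call of [call_gene_activity()].}
#' }
#' `pcg_target` records whether the gene is a catalogued PcG target in at
#' least one condition (`target_catalogue`); the "void" state is only
#' meaningful for such genes.
#'
#' @param genes Gene annotation tibble.
#' @param activity Output of [call_gene_activity()].
#' @param regions_by_antibody Named list of bound-region tibbles (needs
#'   "H3K27me3", "PC", "E(Z)", "H3K27ac"; missing sets count as no overlap).
#' @param pres PRE catalogue with occupancy columns (may be `NULL`).
#' @param ash1_trxN Output of [ash1_trxN_domain_call()] (may be `NULL`).
#' @param target_catalogue Character vector of gene ids that are PcG targets
#'   in at least one condition.
#' @param tss_window_bp TSS half-window (default 250).
#' @return A tibble: `gene_id`, the nine evidence booleans, `pcg_target`.
#' @export
build_evidence <- function(genes, activity, regions_by_antibody,
                           pres = NULL, ash1_trxN = NULL,
                           target_catalogue = character(0),
                           tss_window_bp = 250) {
  units <- genes[, c("chrom", "start", "end")]
  tss_win <- tibble(
    chrom = genes$chrom,
    start = genes$tss - tss_window_bp,
    end = genes$tss + tss_window_bp + 1
  )
  rset <- function(ab) regions_by_antibody[[ab]] %||% empty_regions()
  joint <- if (!is.null(ash1_trxN) && nrow(ash1_trxN) > 0) {
    ash1_trxN[ash1_trxN$joint, , drop = FALSE]
  } else {
    empty_regions()
  }
  ev <- tibble(
    gene_id = genes$gene_id,
    in_h3k27me3_domain = overlaps_any(units, rset("H3K27me3")),
    pc_bound = overlaps_any(units, rset("PC")),
    ez_bound = overlaps_any(units, rset("E(Z)")),
    trxC_at_pre = pre_flag_per_gene(units, pres, "occ_trx_c"),
    trxN_at_pre = pre_flag_per_gene(units, pres, "occ_trx_n"),
    ash1_trxN_domain_overlap = overlaps_any(units, joint),
    ash1_trxN_at_tss = overlaps_any(tss_win, joint),
    h3k27ac_domain_overlap = overlaps_any(units, rset("H3K27ac"))
  )
  act <- activity[match(ev$gene_id, activity$gene_id), ]
  ev$active <- act$active
  ev$pcg_target <- ev$gene_id %in% target_catalogue
  ev
}

pre_flag_per_gene <- function(units, pres, occ_col) {
  if (is.null(pres) || nrow(pres) == 0 || !occ_col %in% names(pres)) {
    return(rep(FALSE, nrow(units)))
  }
  occupied <- pres[pres[[occ_col]], , drop = FALSE]
  overlaps_any(units, occupied)
}

#' Classify chromatin states from evidence vectors
#'
#' Pure decision table over the evidence booleans, evaluated in order
#' (first match wins):
#' \describe{
#'   \item{repressed}{H3K27me3 domain and PC bound, not active, and no
#'     ASH1/TRX N-ter domain overlap — the canonical PcG-silenced state.}
#'   \item{balanced}{H3K27me3 domain and PC bound, together with either
#'     promoter-proximal ASH1/TRX N-ter or transcriptional activity —
#'     repressive and anti-repressive machineries coexisting.}
#'   \item{active}{no PC, no H3K27me3 domain, a broad ASH1/TRX N-ter domain
#'     overlap, and transcriptionally active — the fully derepressed state.}
#'   \item{void}{a catalogued PcG target (in some condition) with none of
#'     PC, H3K27me3, ASH1/TRX N-ter or TRX C-ter at a PRE, and not active —
#'     regulation lost, yet silent.}
#'   \item{other}{anything else.}
#' }
#' Genes with unknown activity (`active` is `NA`) are refused: they are
#' dropped from the result and counted in attribute `n_unclassified`.
#'
#' @param evidence Output of [build_evidence()].
#' @return A tibble `gene_id`, `state` plus the evidence columns; `state` is
#'   a character in `c("repressed", "active", "balanced", "void", "other")`.
#' @export
classify_state <- function(evidence) {
  unknown <- is.na(evidence$active)
  ev <- evidence[!unknown, , drop = FALSE]
  state <- with(ev, case_when(
    in_h3k27me3_domain & pc_bound & !active & !ash1_trxN_domain_overlap ~ "repressed",
    in_h3k27me3_domain & pc_bound & (ash1_trxN_at_tss | active) ~ "balanced",
    !pc_bound & !in_h3k27me3_domain & ash1_trxN_domain_overlap & active ~ "active",
    pcg_target &
      !(pc_bound | in_h3k27me3_domain | ash1_trxN_domain_overlap | trxC_at_pre) &
      !active ~ "void",
    TRUE ~ "other"
  ))
  out <- tibble(gene_id = ev$gene_id, state = state)
  out <- bind_cols(out, ev[, setdiff(names(ev), "gene_id"), drop = FALSE])
  attr(out, "n_unclassified") <- sum(unknown)
  out
}
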