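# Differential methylation: per-probe DMC calling, subtype-specific probe
# sets, promoter/distal mapping, and distal TFBS hypergeometric enrichment.

#' Call differentially methylated cytosines
#'
#' Per-probe Welch two-sample t-test on M-values (log2(beta / (1 - beta))
#' after clipping), with the effect size reported as the group-mean beta
#' difference (case minus control). A probe is a DMC when
#' \code{|delta_beta| >= min_delta} and the unadjusted p-value is below
#' \code{alpha} — the beta-difference filter carries the burden of
#' multiplicity control in this rule; BH-adjusted q-values are reported
#' alongside for transparency. Probes with fewer than two unmasked values
#' in either group are untestable and excluded from the testable universe.
#'
#' @param beta probes x samples beta matrix.
#' @param case_samples,control_samples sample id vectors.
#' @param min_delta beta-difference threshold, default 0.2.
#' @param alpha p-value cutoff, default 0.05.
#' @param eps clipping margin for the M-value transform.
#' @return data.frame (class \code{"dmc_table"}): probe_id, delta_beta, p, q,
#'   direction (hyper/hypo), is_dmc, testable.
#' @export
call_dmcs <- function(beta, case_samples, control_samples,
                      min_delta = 0.2, alpha = 0.05, eps = 1e-3) {
  validate_beta_matrix(beta)
  idx1 <- match(case_samples, colnames(beta))
  idx2 <- match(control_samples, colnames(beta))
  if (anyNA(idx1) || anyNA(idx2)) {
    stop("case/control sample(s) absent from beta matrix")
  }
  if (length(idx1) < 2 || length(idx2) < 2) {
    stop("need at least 2 samples per group")
  }
  m <- beta_to_m(beta, eps)
  wt <- row_welch(m, idx1, idx2)
  delta <- rowMeans(beta[, idx1, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, idx2, drop = FALSE], na.rm = TRUE)
  testable <- !is.na(wt$p)
  q <- rep(NA_real_, nrow(beta))
  q[testable] <- stats::p.adjust(wt$p[testable], method = "BH")
  out <- data.frame(
    probe_id = rownames(beta),
    delta_beta = delta,
    p = wt$p,
    q = q,
    direction = ifelse(delta >= 0, "hyper", "hypo"),
    is_dmc = testable & abs(delta) >= min_delta & wt$p < alpha,
    testable = testable,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("dmc_table", "data.frame")
  out
}

#' Fibroid-specific methylated probes
#'
#' Probes unmethylated in every normal sample (beta <= \code{normal_max})
#' but methylated (beta >= \code{meth_min}) in at least one subtype sample.
#'
#' @param beta probes x samples beta matrix.
#' @param normal_samples,subtype_samples sample id vectors.
#' @param meth_min methylated threshold, default 0.3.
#' @param normal_max unmethylated-in-normal threshold, default 0.2.
#' @return character vector of probe ids.
#' @export
subtype_specific_probes <- function(beta, normal_samples, subtype_samples,
                                    meth_min = 0.3, normal_max = 0.2) {
  validate_beta_matrix(beta)
  if (!length(normal_samples) || !length(subtype_samples)) {
    stop("both sample groups must be non-empty")
  }
  bn <- beta[, normal_samples, drop = FALSE]
  bs <- beta[, subtype_samples, drop = FALSE]
  normal_unmeth <- rowSums(bn > normal_max, na.rm = TRUE) == 0 &
    rowSums(!is.na(bn)) > 0
  subtype_meth <- rowSums(bs >= meth_min, na.rm = TRUE) >= 1
  rownames(beta)[normal_unmeth & subtype_meth]
}

#' Map probes to promoters or distal space
#'
#' A probe within \code{window} bp of its assigned TSS is a promoter probe
#' of that gene; anything else is distal. Distal probes carrying at least
#' one TFBS label form the enrichment universe ("probes located within
#' TFBSs but not within gene promoters").
#'
#' @param annotation probe annotation table.
#' @param window promoter half-width in bp, default 2000.
#' @return data.frame: probe_id, region (promoter/distal), gene (NA for
#'   distal), in_tfbs_universe (logical).
#' @export
map_probes_to_promoters <- function(annotation, window = 2000) {
  validate_probe_annotation(annotation)
  is_prom <- !is.na(annotation$tss_distance) &
    abs(annotation$tss_distance) <= window
  has_tfbs <- !is.na(annotation$tfbs) & annotation$tfbs != ""
  data.frame(
    probe_id = annotation$probe_id,
    region = ifelse(is_prom, "promoter", "distal"),
    gene = ifelse(is_prom, annotation$gene, NA_character_),
    in_tfbs_universe = !is_prom & has_tfbs,
    stringsAsFactors = FALSE
  )
}

# expand "A;B;C" labels into a probe -> TF long table
split_tfbs <- function(annotation, probe_ids) {
  ann <- annotation[annotation$probe_id %in% probe_ids, ]
  labs <- strsplit(ann$tfbs, ";", fixed = TRUE)
  data.frame(
    probe_id = rep(ann$probe_id, lengths(labs)),
    tf = unlist(labs),
    stringsAsFactors = FALSE
  )
}

#' TFBS enrichment of DMCs among distal probes
#'
#' For each transcription factor, tests whether DMCs are over- or
#' under-represented in its binding-site probe set by hypergeometric tail
#' probabilities over the distal TFBS universe: with universe size N, TF set
#' size K, n DMCs in the universe and overlap k, the enrichment p-value is
#' P(X >= k) and the depletion p-value P(X <= k). BH correction is applied
#' separately within the enrichment family and within the depletion family
#' across TFs; calls use the (stringent) FDR cutoff of 1e-6.
#'
#' @param dmc_probes probe ids called as DMC (intersected with the universe;
#'   the intersection size is reported).
#' @param annotation probe annotation carrying \code{tfbs} labels.
#' @param universe probe ids forming the distal TFBS universe; default is
#'   computed via [map_probes_to_promoters()].
#' @param fdr_cut FDR cutoff for the enriched/depleted call, default 1e-6.
#' @param promoter_window passed to the default universe computation.
#' @return data.frame (class \code{"enrichment_table"}): tf, universe_size,
#'   tf_set_size, dmc_count, overlap, p_enrich, p_deplete, q_enrich,
#'   q_deplete, call.
#' @export
tfbs_enrichment <- function(dmc_probes, annotation, universe = NULL,
                            fdr_cut = 1e-6, promoter_window = 2000) {
  if (is.null(universe)) {
    pm <- map_probes_to_promoters(annotation, promoter_window)
    universe <- pm$probe_id[pm$in_tfbs_universe]
  }
  if (!length(universe)) stop("TFBS universe is empty")
  dmc_in <- intersect(dmc_probes, universe)
  long <- split_tfbs(annotation, universe)
  N <- length(universe)
  n <- length(dmc_in)
  tfs <- sort(unique(long$tf))
  rows <- lapply(tfs, function(tf) {
    members <- long$probe_id[long$tf == tf]
    K <- length(members)
    if (K == 0) return(NULL)   # no binding sites in universe: skipped
    k <- length(intersect(members, dmc_in))
    data.frame(
      tf = tf, universe_size = N, tf_set_size = K,
      dmc_count = n, overlap = k,
      p_enrich = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      p_deplete = stats::phyper(k, K, N - K, n),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_enrich <- stats::p.adjust(out$p_enrich, method = "BH")
  out$q_deplete <- stats::p.adjust(out$p_deplete, method = "BH")
  out$call <- ifelse(out$q_enrich <= fdr_cut, "enriched",
                     ifelse(out$q_deplete <= fdr_cut, "depleted", "neither"))
  class(out) <- c("enrichment_table", "data.frame")
  out
}
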