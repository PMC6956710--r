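# Expression integration: simplified differential expression on log2-CPM,
# promoter-methylation/expression starburst categories, the directional
# DEG-overlap chi-square test, and gene-gene correlation.

#' Counts per million
#' @param counts genes x samples count matrix.
#' @return CPM matrix; errors on a zero library size.
#' @export
cpm <- function(counts) {
  lib <- colSums(counts)
  zero <- names(lib)[lib == 0]
  if (length(zero)) {
    stop("sample(s) with zero library size: ", paste(zero, collapse = ", "))
  }
  sweep(counts, 2, lib, "/") * 1e6
}

#' Simplified differential expression on log2-CPM
#'
#' Genes are kept when CPM >= \code{cpm_min} in at least \code{min_samples}
#' of the samples in the contrast; kept genes are tested by Welch t on
#' log2(CPM + 0.5) and BH-corrected. The log2 fold change is the mean
#' difference of log2(CPM + 0.5), case minus control. This is a defined
#' stand-in procedure with the canonical count filter and FDR rule, not a
#' moderated-dispersion model.
#'
#' @param counts genes x samples count matrix.
#' @param case_samples,control_samples sample id vectors (>= 2 each).
#' @param cpm_min CPM filter threshold, default 1.
#' @param min_samples samples required to pass the filter, default 3.
#' @param fdr FDR cutoff for the DEG call, default 0.05.
#' @return data.frame (class \code{"deg_table"}): gene_id, log2fc, p, q,
#'   passed_filter, is_deg.
#' @export
call_degs <- function(counts, case_samples, control_samples,
                      cpm_min = 1, min_samples = 3, fdr = 0.05) {
  validate_count_matrix(counts)
  all_s <- c(case_samples, control_samples)
  missing <- setdiff(all_s, colnames(counts))
  if (length(missing)) {
    stop("sample(s) absent from count matrix: ", paste(missing, collapse = ", "))
  }
  if (length(case_samples) < 2 || length(control_samples) < 2) {
    stop("need at least 2 samples per group")
  }
  sub <- counts[, all_s, drop = FALSE]
  cp <- cpm(sub)
  passed <- rowSums(cp >= cpm_min) >= min_samples
  lcpm <- log2(cp + 0.5)
  idx1 <- match(case_samples, colnames(lcpm))
  idx2 <- match(control_samples, colnames(lcpm))
  wt <- row_welch(lcpm, idx1, idx2)
  p <- ifelse(passed, wt$p, NA_real_)
  q <- rep(NA_real_, nrow(sub))
  q[passed] <- stats::p.adjust(p[passed], method = "BH")
  out <- data.frame(
    gene_id = rownames(sub),
    log2fc = wt$diff,
    p = p,
    q = q,
    passed_filter = passed,
    is_deg = passed & !is.na(q) & q < fdr,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Starburst integration of promoter methylation and expression
#'
#' Joins a DMC table (restricted to promoter probes via the probe-to-gene
#' map) with a DEG table. Each gene's promoter methylation change is
#' summarised by the probe with the largest |delta beta| (a mean summary is
#' available via \code{summary_fn}). Categories: \code{hyper_down} when
#' delta beta > \code{delta_cut}, methylation p < \code{p_cut}, expression
#' log2FC < 0 and expression q < 0.05; \code{hypo_up} symmetric; otherwise
#' \code{other}. Genes without a promoter probe are excluded and counted.
#'
#' @param dmc a \code{dmc_table} from [call_dmcs()].
#' @param degs a \code{deg_table} from [call_degs()].
#' @param probe_map output of [map_probes_to_promoters()].
#' @param delta_cut promoter beta-difference threshold, default 0.25.
#' @param p_cut methylation p threshold, default 0.05.
#' @param expr_fdr expression q threshold, default 0.05.
#' @param summary_fn \code{"max_abs"} (default) or \code{"mean"}.
#' @return data.frame (class \code{"starburst_table"}): gene_id,
#'   promoter_delta_beta, promoter_p, expr_log2fc, expr_q, category; the
#'   number of DEG genes without promoter probes is in
#'   \code{attr(, "n_unmapped")}.
#' @export
starburst <- function(dmc, degs, probe_map, delta_cut = 0.25, p_cut = 0.05,
                      expr_fdr = 0.05, summary_fn = c("max_abs", "mean")) {
  summary_fn <- match.arg(summary_fn)
  prom <- probe_map[probe_map$region == "promoter" & !is.na(probe_map$gene), ]
  d <- merge(dmc, prom[, c("probe_id", "gene")], by = "probe_id")
  d <- d[!is.na(d$p), ]
  per_gene <- lapply(split(d, d$gene), function(g) {
    i <- if (summary_fn == "max_abs") which.max(abs(g$delta_beta)) else NA
    if (summary_fn == "max_abs") {
      data.frame(gene_id = g$gene[1], promoter_delta_beta = g$delta_beta[i],
                 promoter_p = g$p[i], stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = g$gene[1],
                 promoter_delta_beta = mean(g$delta_beta),
                 promoter_p = min(g$p), stringsAsFactors = FALSE)
    }
  })
  meth <- do.call(rbind, per_gene)
  joined <- merge(meth, degs[, c("gene_id", "log2fc", "q")], by = "gene_id")
  n_unmapped <- sum(!degs$gene_id %in% meth$gene_id)
  names(joined)[names(joined) == "log2fc"] <- "expr_log2fc"
  names(joined)[names(joined) == "q"] <- "expr_q"
  sig_meth <- abs(joined$promoter_delta_beta) > delta_cut &
    joined$promoter_p < p_cut
  sig_expr <- !is.na(joined$expr_q) & joined$expr_q < expr_fdr
  joined$category <- "other"
  joined$category[sig_meth & sig_expr &
                    joined$promoter_delta_beta > 0 &
                    joined$expr_log2fc < 0] <- "hyper_down"
  joined$category[sig_meth & sig_expr &
                    joined$promoter_delta_beta < 0 &
                    joined$expr_log2fc > 0] <- "hypo_up"
  attr(joined, "n_unmapped") <- n_unmapped
  class(joined) <- c("starburst_table", "data.frame")
  joined
}

#' Directional DEG-overlap chi-square test
#'
#' Compares two DEG tables over their shared tested universe (genes passing
#' the filter in both contrasts), separately for up- and downregulated DEG
#' sets. Each direction is a 2x2 contingency table \{in A, not in A\} x
#' \{in B, not in B\} tested by Pearson chi-square with 1 df and no
#' continuity correction (expected counts in intended use are large).
#'
#' @param degs_a,degs_b \code{deg_table}s sharing gene ids.
#' @return list with one entry per direction (\code{up}, \code{down}), each
#'   holding \code{table} (2x2), \code{chisq}, \code{p}, \code{overlap_genes},
#'   plus \code{universe_size}.
#' @export
overlap_test <- function(degs_a, degs_b) {
  universe <- intersect(degs_a$gene_id[degs_a$passed_filter],
                        degs_b$gene_id[degs_b$passed_filter])
  if (!length(universe)) stop("empty shared gene universe")
  one_direction <- function(sign) {
    in_a <- universe %in% degs_a$gene_id[degs_a$is_deg &
                                           sign * degs_a$log2fc > 0]
    in_b <- universe %in% degs_b$gene_id[degs_b$is_deg &
                                           sign * degs_b$log2fc > 0]
    tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
    ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(table = tab,
         chisq = unname(ch$statistic),
         p = unname(ch$p.value),
         overlap_genes = universe[in_a & in_b])
  }
  list(up = one_direction(1), down = one_direction(-1),
       universe_size = length(universe))
}

#' Gene-gene expression correlation
#'
#' Pearson product-moment or Kendall tau-b correlation between two genes'
#' log2-CPM profiles (or two supplied vectors), with the p-value from
#' [stats::cor.test()] (exact where the sample size permits, asymptotic
#' otherwise).
#'
#' @param expr log2-CPM matrix (genes x samples), or NULL when \code{x} and
#'   \code{y} are given directly.
#' @param gene_x,gene_y gene ids (rows of \code{expr}), or numeric vectors
#'   when \code{expr} is NULL.
#' @param method \code{"pearson"} or \code{"kendall"}.
#' @return list with \code{estimate}, \code{p}, \code{n}, \code{method}.
#' @export
correlate_genes <- function(expr, gene_x, gene_y,
                            method = c("pearson", "kendall")) {
  method <- match.arg(method)
  if (is.null(expr)) {
    x <- gene_x
    y <- gene_y
  } else {
    missing <- setdiff(c(gene_x, gene_y), rownames(expr))
    if (length(missing)) {
      stop("gene(s) absent from expression matrix: ",
           paste(missing, collapse = ", "))
    }
    x <- expr[gene_x, ]
    y <- expr[gene_y, ]
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero-variance vector")
  }
  ct <- stats::cor.test(x, y, method = method)
  list(estimate = unname(ct$estimate), p = ct$p.value,
       n = length(x), method = method)
}
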