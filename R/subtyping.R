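# Subtype discovery: variable-probe selection, hierarchical clustering,
# consensus clustering with stability scores, and the rule-based subtype
# classifier.

#' Select the most variable probes
#'
#' Returns the top fraction (default 1\%) of probes of a class (default CpG)
#' ranked by per-probe standard deviation across all samples, masked cells
#' excluded. Exactly \code{ceiling(fraction * P)} probes are returned; an
#' absolute count can be given instead of a fraction. Ties are broken
#' lexicographically by probe id; an all-tied (constant) input triggers a
#' warning.
#'
#' @param beta probes x samples beta matrix.
#' @param annotation probe annotation (used to restrict by probe class);
#'   omit to rank all rows.
#' @param fraction fraction of probes to keep, in (0, 1].
#' @param n_probes absolute count overriding \code{fraction} when given.
#' @param probe_class class to rank within, default \code{"CpG"}.
#' @return character vector of probe ids, ordered by decreasing SD.
#' @export
select_variable_probes <- function(beta, annotation = NULL, fraction = 0.01,
                                   n_probes = NULL, probe_class = "CpG") {
  validate_beta_matrix(beta)
  if (!is.null(annotation)) {
    keep <- annotation$probe_id[annotation$probe_class == probe_class]
    beta <- beta[intersect(rownames(beta), keep), , drop = FALSE]
  }
  p <- nrow(beta)
  if (p < 100) stop("need at least 100 probes of class ", probe_class)
  if (is.null(n_probes)) {
    if (fraction <= 0 || fraction > 1) {
      stop("configuration error: fraction must be in (0, 1]")
    }
    n_probes <- ceiling(fraction * p)
  }
  n <- rowSums(!is.na(beta))
  m <- rowMeans(beta, na.rm = TRUE)
  sds <- sqrt(rowSums((beta - m)^2, na.rm = TRUE) / pmax(n - 1, 1))
  sds[n < 2] <- 0
  ord <- order(-sds, rownames(beta))
  top <- rownames(beta)[ord[seq_len(n_probes)]]
  if (sds[ord[1]] == sds[ord[n_probes]]) {
    warning("variable-probe selection is tie-dominated (constant variance); ",
            "order is lexicographic")
  }
  top
}

#' Hierarchical clustering of samples
#'
#' Ward linkage on Euclidean distance over beta values (columns = samples),
#' the compact-cluster convention used for methylation heatmaps. Masked
#' cells are dropped pairwise by the distance computation.
#'
#' @param beta_subset probes x samples matrix (typically the variable-probe
#'   subset).
#' @param k optional number of flat clusters to cut.
#' @param linkage \code{hclust} method, default \code{"ward.D2"}.
#' @return list with \code{hclust} (the dendrogram) and, when \code{k} is
#'   given, \code{assignments} (named integer vector).
#' @export
hier_cluster <- function(beta_subset, k = NULL, linkage = "ward.D2") {
  if (ncol(beta_subset) < 2) stop("need at least 2 samples to cluster")
  d <- stats::dist(t(beta_subset))
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc)
  if (!is.null(k)) {
    if (k > ncol(beta_subset)) {
      stop("configuration error: k exceeds the number of samples")
    }
    out$assignments <- stats::cutree(hc, k = k)
  }
  out
}

#' Consensus clustering by sample subsampling
#'
#' Repeatedly subsamples \code{floor(subsample * n)} samples without
#' replacement, clusters each subsample with [hier_cluster()] at \code{k},
#' and tallies how often each sample pair lands in the same cluster. The
#' consensus value for a pair is its co-clustering count divided by its
#' co-sampling count; final assignments come from clustering
#' \code{1 - consensus} at the same \code{k}. Reproducible under a fixed
#' seed. Pairs never co-sampled (vanishingly rare at the default 1000
#' iterations) are flagged with a warning and treated as consensus 0.5 for
#' the final cut.
#'
#' @param beta_subset probes x samples matrix.
#' @param k number of clusters, >= 2.
#' @param iterations number of perturbation iterations, default 1000.
#' @param subsample fraction of samples drawn each iteration, default 0.8.
#' @param seed RNG seed.
#' @param linkage passed to [hier_cluster()].
#' @return object of class \code{"consensus_result"}: list with
#'   \code{consensus} (samples x samples matrix, symmetric, unit diagonal),
#'   \code{k}, \code{assignments}, \code{sample_stability},
#'   \code{cluster_stability}, \code{iterations}, \code{subsample},
#'   \code{seed}, \code{hclust}.
#' @export
consensus_cluster <- function(beta_subset, k, iterations = 1000,
                              subsample = 0.8, seed = 1L,
                              linkage = "ward.D2") {
  if (k < 2) stop("configuration error: k must be >= 2")
  if (iterations < 1) stop("configuration error: iterations must be >= 1")
  n <- ncol(beta_subset)
  ids <- colnames(beta_subset)
  m <- max(2L, floor(subsample * n))
  set.seed(as.integer(seed))
  co_cluster <- matrix(0, n, n, dimnames = list(ids, ids))
  co_sampled <- matrix(0, n, n, dimnames = list(ids, ids))
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, m)
    cl <- hier_cluster(beta_subset[, idx, drop = FALSE],
                       k = min(k, m), linkage = linkage)$assignments
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    same <- outer(cl, cl, "==")
    co_cluster[idx, idx] <- co_cluster[idx, idx] + same
  }
  consensus <- co_cluster / co_sampled
  never <- co_sampled == 0
  diag(never) <- FALSE
  if (any(never)) {
    warning(sum(never) / 2, " sample pair(s) were never co-sampled; ",
            "their consensus entries are missing")
    consensus[never] <- NA_real_
  }
  diag(consensus) <- 1
  cons_for_cut <- consensus
  cons_for_cut[is.na(cons_for_cut)] <- 0.5
  hc <- stats::hclust(stats::as.dist(1 - cons_for_cut), method = linkage)
  assignments <- stats::cutree(hc, k = k)
  res <- structure(
    list(consensus = consensus, k = k, assignments = assignments,
         iterations = iterations, subsample = subsample,
         seed = as.integer(seed), hclust = hc),
    class = "consensus_result"
  )
  stab <- stability_scores(res)
  res$sample_stability <- stab$sample_stability
  res$cluster_stability <- stab$cluster_stability
  res
}

#' Sample- and cluster-level stability scores
#'
#' The stability of sample \code{s} with respect to cluster \code{C} is the
#' mean consensus value between \code{s} and the members of \code{C},
#' excluding \code{s} itself when it belongs to \code{C} (self-inclusion
#' would inflate the score). A cluster's stability is the mean of its
#' members' scores with respect to it. A singleton cluster has no pairs; its
#' member's score is defined as 1 and flagged.
#'
#' @param consensus a \code{consensus_result}, or a list with elements
#'   \code{consensus} (matrix) and \code{assignments}.
#' @return list with \code{sample_stability} (samples x clusters matrix),
#'   \code{cluster_stability} (named numeric) and \code{singleton_flags}.
#' @export
stability_scores <- function(consensus) {
  cm <- consensus$consensus
  cl <- consensus$assignments
  if (is.null(cl)) stop("consensus result has no assignments")
  ids <- rownames(cm)
  ks <- sort(unique(cl))
  sample_stability <- matrix(
    NA_real_, length(ids), length(ks),
    dimnames = list(ids, paste0("cluster", ks))
  )
  singleton <- logical(length(ks))
  names(singleton) <- paste0("cluster", ks)
  for (ci in seq_along(ks)) {
    members <- ids[cl == ks[ci]]
    for (s in ids) {
      others <- setdiff(members, s)
      sample_stability[s, ci] <- if (length(others)) {
        mean(cm[s, others], na.rm = TRUE)
      } else {
        1   # singleton cluster: defined as 1, flagged below
      }
    }
    if (length(members) == 1) singleton[ci] <- TRUE
  }
  cluster_stability <- vapply(seq_along(ks), function(ci) {
    members <- ids[cl == ks[ci]]
    mean(sample_stability[members, ci])
  }, numeric(1))
  names(cluster_stability) <- paste0("cluster", ks)
  list(sample_stability = sample_stability,
       cluster_stability = cluster_stability,
       singleton_flags = singleton)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus clustering: k = %d, %d iterations, subsample %.2f, seed %d\n",
              x$k, x$iterations, x$subsample, x$seed))
  cat("cluster stability:\n")
  print(round(x$cluster_stability, 3))
  invisible(x)
}

#' Rule-based fibroid subtype classification
#'
#' A fibroid with a MED12 exon 1/2 mutation is \code{MED12mt} regardless of
#' expression. Otherwise HMGA2 fold change > 5 vs the matched normal calls
#' \code{HMGA2hi}; otherwise HMGA1 fold change > 2 calls \code{HMGA1hi};
#' otherwise \code{unclassified}. HMGA2 is checked before HMGA1 so a sample
#' exceeding both thresholds is called by the stronger criterion.
#'
#' @param med12_mutation logical: MED12 exon 1/2 mutation present.
#' @param fold_changes named numeric vector of linear fold changes versus
#'   the matched normal; must contain \code{HMGA1} and \code{HMGA2} when
#'   \code{med12_mutation} is \code{FALSE}.
#' @param hmga2_fc,hmga1_fc thresholds, defaults 5 and 2.
#' @return one of \code{"MED12mt"}, \code{"HMGA2hi"}, \code{"HMGA1hi"},
#'   \code{"unclassified"}.
#' @export
classify_subtype <- function(med12_mutation, fold_changes = NULL,
                             hmga2_fc = 5, hmga1_fc = 2) {
  if (isTRUE(med12_mutation)) return("MED12mt")
  if (is.null(fold_changes) ||
      any(is.na(fold_changes[c("HMGA1", "HMGA2")]))) {
    stop("classification error: HMGA1/HMGA2 fold changes vs matched normal ",
         "are required for MED12 wild-type samples")
  }
  if (fold_changes[["HMGA2"]] > hmga2_fc) return("HMGA2hi")
  if (fold_changes[["HMGA1"]] > hmga1_fc) return("HMGA1hi")
  "unclassified"
}
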