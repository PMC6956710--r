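# Sample-level quality control: marker-promoter cell-composition estimates
# and SNP-probe genotype calling / sample identity matching.

#' Build a marker set definition
#'
#' A marker set names the probes within +/- 500 bp of a lineage marker's TSS
#' and whether promoter methylation marks the target lineage
#' (\code{"methylated_in_target"}, e.g. MIR200C/141 for mesenchymal cells)
#' or its complement (\code{"unmethylated_in_target"}, e.g. the smooth
#' muscle actin promoter, unmethylated in myofibroblasts).
#'
#' @param name marker name.
#' @param probe_ids non-empty character vector of probe ids.
#' @param polarity one of \code{"methylated_in_target"},
#'   \code{"unmethylated_in_target"}.
#' @return a list of class \code{"marker_set"}.
#' @export
marker_set <- function(name, probe_ids,
                       polarity = c("methylated_in_target",
                                    "unmethylated_in_target")) {
  polarity <- match.arg(polarity)
  if (!length(probe_ids)) stop("marker set '", name, "' has no probes")
  structure(list(name = name, probe_ids = probe_ids, polarity = polarity),
            class = "marker_set")
}

#' Read marker sets from TSV
#'
#' Columns: \code{name}, \code{probe_id}, \code{polarity}; one row per probe.
#'
#' @param path file path.
#' @return list of \code{marker_set} objects.
#' @export
read_marker_sets <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(split(df, df$name), function(d) {
    marker_set(d$name[1], d$probe_id, d$polarity[1])
  })
}

#' Estimate cell-composition fractions from marker-promoter methylation
#'
#' Two-component linear mixture read-out: for a marker methylated in the
#' target lineage the target fraction is the mean beta over the marker
#' probes; for a marker unmethylated in the target it is one minus that
#' mean. Fractions are clipped to \code{[0, 1]}. Estimates are invariant to
#' probe order and monotone in marker methylation.
#'
#' @param beta probes x samples beta matrix.
#' @param markers list of \code{marker_set} objects.
#' @return data.frame sample_id x one column per marker, values in [0, 1].
#' @export
estimate_composition <- function(beta, markers) {
  validate_beta_matrix(beta)
  if (inherits(markers, "marker_set")) markers <- list(markers)
  est <- lapply(markers, function(m) {
    missing <- setdiff(m$probe_ids, rownames(beta))
    if (length(missing)) {
      stop("marker set '", m$name, "' references probe(s) absent from the ",
           "beta matrix: ", paste(missing, collapse = ", "))
    }
    mb <- colMeans(beta[m$probe_ids, , drop = FALSE], na.rm = TRUE)
    frac <- if (m$polarity == "methylated_in_target") mb else 1 - mb
    pmin(pmax(frac, 0), 1)
  })
  out <- data.frame(sample_id = colnames(beta), stringsAsFactors = FALSE)
  for (i in seq_along(markers)) out[[markers[[i]]$name]] <- est[[i]]
  out
}

#' Call SNP-probe genotypes from beta values
#'
#' Tri-modal thresholding of SNP-probe betas: beta < 0.25 is AA,
#' 0.25 <= beta <= 0.75 is AB, beta > 0.75 is BB; masked cells are
#' \code{missing}.
#'
#' @param beta beta matrix restricted to (or containing) SNP probes.
#' @param snp_probes optional probe ids to restrict to; default all rows.
#' @param lower,upper genotype thresholds, defaults 0.25 and 0.75.
#' @return character matrix of calls in \{AA, AB, BB, missing\}.
#' @export
call_snp_genotypes <- function(beta, snp_probes = rownames(beta),
                               lower = 0.25, upper = 0.75) {
  validate_beta_matrix(beta)
  b <- beta[intersect(snp_probes, rownames(beta)), , drop = FALSE]
  if (!nrow(b)) stop("no SNP probes present in beta matrix")
  g <- matrix("missing", nrow(b), ncol(b), dimnames = dimnames(b))
  g[!is.na(b) & b < lower] <- "AA"
  g[!is.na(b) & b >= lower & b <= upper] <- "AB"
  g[!is.na(b) & b > upper] <- "BB"
  g
}

#' Match samples by SNP-probe genotype identity
#'
#' Pairwise identity is the fraction of matching genotype calls over shared
#' non-missing loci; pairs sharing fewer than \code{min_shared} callable loci
#' are unevaluable. Samples are grouped by single linkage at identity >=
#' \code{min_identity} (connected components of the threshold graph) and the
#' recovered groups are compared with declared patient ids when supplied.
#'
#' @param genotypes call matrix from [call_snp_genotypes()].
#' @param min_identity grouping threshold, default 0.9.
#' @param min_shared minimum shared non-missing calls per pair, default 10.
#' @param patient_ids optional named vector (sample -> declared patient).
#' @return list with \code{identity} (symmetric matrix, unit diagonal, NA =
#'   unevaluable), \code{groups} (integer group per sample),
#'   \code{unevaluable} (samples with no callable genotypes) and, when
#'   declared ids are given, \code{mismatches} (pairs grouped together but
#'   declared different, or vice versa).
#' @export
match_samples <- function(genotypes, min_identity = 0.9, min_shared = 10,
                          patient_ids = NULL) {
  n <- ncol(genotypes)
  if (n < 2) stop("need at least two samples to match")
  ids <- colnames(genotypes)
  unevaluable <- ids[colSums(genotypes != "missing") == 0]
  identity <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(identity) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- genotypes[, i] != "missing" & genotypes[, j] != "missing"
      if (sum(ok) >= min_shared) {
        identity[i, j] <- identity[j, i] <-
          mean(genotypes[ok, i] == genotypes[ok, j])
      }
    }
  }
  pairs <- which(upper.tri(identity) & !is.na(identity) &
                   identity >= min_identity, arr.ind = TRUE)
  groups <- components_from_edges(n, pairs[, 1], pairs[, 2])
  names(groups) <- ids
  out <- list(identity = identity, groups = groups, unevaluable = unevaluable)
  if (!is.null(patient_ids)) {
    declared <- patient_ids[ids]
    mm <- list()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        same_grp <- groups[i] == groups[j]
        same_pat <- declared[i] == declared[j]
        if (!is.na(identity[i, j]) && same_grp != same_pat) {
          mm[[length(mm) + 1]] <- data.frame(
            sample_a = ids[i], sample_b = ids[j],
            identity = identity[i, j],
            declared_same = same_pat, genotype_same = same_grp
          )
        }
      }
    }
    out$mismatches <- if (length(mm)) do.call(rbind, mm) else NULL
  }
  out
}
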