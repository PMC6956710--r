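# X-inactivation-based clonality inference for tumour pairs, plus small
# variant-interpretation utilities (in-frame deletion effect, mutation
# burden per megabase).
#
# One X chromosome is silenced at random early in development, so two
# tumours arising from the same founding cell express the same allele at
# every heterozygous chromosome-X locus, while independently arising tumours
# will disagree wherever their inactive X differs.

#' Informative chromosome-X loci for a tumour pair
#'
#' A locus is informative when, in BOTH tumours, DNA depth is at least
#' \code{min_depth} and the DNA alternate-allele fraction falls inside the
#' heterozygous band (i.e. the locus remains heterozygous in both tumours).
#'
#' @param allelic allelic count table.
#' @param tumor1,tumor2 sample ids.
#' @param min_depth minimum DNA depth, default 10.
#' @param het_band inclusive alt-fraction band, default \code{c(0.2, 0.8)}.
#' @return character vector of locus ids.
#' @export
informative_x_loci <- function(allelic, tumor1, tumor2, min_depth = 10,
                               het_band = c(0.2, 0.8)) {
  validate_allelic_counts(allelic)
  het_ok <- function(sample) {
    a <- allelic[allelic$sample_id == sample, ]
    depth <- a$dna_ref + a$dna_alt
    frac <- ifelse(depth > 0, a$dna_alt / depth, NA)
    a$locus_id[depth >= min_depth & !is.na(frac) &
                 frac >= het_band[1] & frac <= het_band[2]]
  }
  intersect(het_ok(tumor1), het_ok(tumor2))
}

#' Call the expressed allele at a locus
#'
#' Below \code{min_depth} RNA reads the locus is uncallable; otherwise the
#' major allele is called when its fraction reaches \code{mono_frac}, else
#' the locus is biallelic.
#'
#' @param rna_ref,rna_alt RNA read counts.
#' @param min_depth minimum RNA depth, default 10.
#' @param mono_frac monoallelic-call fraction, default 0.9.
#' @return one of \code{"REF"}, \code{"ALT"}, \code{"biallelic"},
#'   \code{"uncallable"} (vectorised).
#' @export
expressed_allele <- function(rna_ref, rna_alt, min_depth = 10,
                             mono_frac = 0.9) {
  depth <- rna_ref + rna_alt
  major <- pmax(rna_ref, rna_alt) / ifelse(depth > 0, depth, 1)
  out <- rep("biallelic", length(depth))
  out[major >= mono_frac & rna_ref >= rna_alt] <- "REF"
  out[major >= mono_frac & rna_alt > rna_ref] <- "ALT"
  out[depth < min_depth] <- "uncallable"
  out
}

#' Clonality call for a tumour pair from X-inactivation
#'
#' Informative loci are those heterozygous in DNA in both tumours
#' ([informative_x_loci()]) at which the expressed allele is monoallelic in
#' both tumours. Concordance is the fraction of informative loci at which
#' both tumours express the same allele. The verdict is
#' \code{shared_origin} at concordance >= \code{shared_min},
#' \code{independent_origins} at concordance <= \code{independent_max}, and
#' \code{indeterminate} otherwise or when fewer than \code{min_informative}
#' loci are available. The methylation-profile Pearson correlation between
#' the two tumours is reported as corroborating evidence only; it never
#' overrides the allelic verdict. The call is symmetric in tumour order.
#'
#' @param allelic allelic count table.
#' @param tumor1,tumor2 sample ids, both from \code{patient_id}.
#' @param samples sample sheet (used to verify the tumours share a patient).
#' @param beta optional beta matrix for the corroborating methylation
#'   correlation, computed over \code{meth_probes} (default: top 1\% most
#'   variable rows of \code{beta}).
#' @param meth_probes optional probe ids for the methylation correlation.
#' @param min_depth,het_band,mono_frac per-locus thresholds.
#' @param min_informative minimum informative loci, default 5.
#' @param shared_min,independent_max concordance decision thresholds.
#' @return list of class \code{"clonality_call"}: patient_id, tumor_pair,
#'   n_informative, n_concordant, concordance, meth_correlation, verdict.
#' @export
clonality_call <- function(allelic, tumor1, tumor2, samples = NULL,
                           beta = NULL, meth_probes = NULL,
                           min_depth = 10, het_band = c(0.2, 0.8),
                           mono_frac = 0.9, min_informative = 5,
                           shared_min = 0.9, independent_max = 0.1) {
  patient <- NA_character_
  if (!is.null(samples)) {
    p1 <- samples$patient_id[samples$sample_id == tumor1]
    p2 <- samples$patient_id[samples$sample_id == tumor2]
    if (!length(p1) || !length(p2) || p1 != p2) {
      stop("clonality_call compares tumours from one patient; '", tumor1,
           "' and '", tumor2, "' have different (or missing) patient ids")
    }
    patient <- p1
  }
  het <- informative_x_loci(allelic, tumor1, tumor2, min_depth, het_band)
  calls <- lapply(c(tumor1, tumor2), function(s) {
    a <- allelic[allelic$sample_id == s & allelic$locus_id %in% het, ]
    a <- a[match(het, a$locus_id), ]
    expressed_allele(a$rna_ref, a$rna_alt, min_depth, mono_frac)
  })
  mono <- calls[[1]] %in% c("REF", "ALT") & calls[[2]] %in% c("REF", "ALT")
  n_informative <- sum(mono)
  n_concordant <- sum(mono & calls[[1]] == calls[[2]])
  concordance <- if (n_informative > 0) n_concordant / n_informative else NA_real_
  verdict <- if (n_informative < min_informative) {
    "indeterminate"
  } else if (concordance >= shared_min) {
    "shared_origin"
  } else if (concordance <= independent_max) {
    "independent_origins"
  } else {
    "indeterminate"
  }
  meth_correlation <- NA_real_
  if (!is.null(beta)) {
    if (is.null(meth_probes)) {
      meth_probes <- select_variable_probes(beta, fraction = 0.01)
    }
    meth_correlation <- stats::cor(beta[meth_probes, tumor1],
                                   beta[meth_probes, tumor2],
                                   use = "pairwise.complete.obs")
  }
  structure(
    list(patient_id = patient, tumor_pair = c(tumor1, tumor2),
         n_informative = n_informative, n_concordant = n_concordant,
         concordance = concordance, meth_correlation = meth_correlation,
         verdict = verdict),
    class = "clonality_call"
  )
}

#' @export
print.clonality_call <- function(x, ...) {
  cat(sprintf("clonality: %s vs %s (patient %s)\n",
              x$tumor_pair[1], x$tumor_pair[2], x$patient_id))
  cat(sprintf("  informative X loci: %d, concordant: %d (%.2f)\n",
              x$n_informative, x$n_concordant, x$concordance))
  if (!is.na(x$meth_correlation)) {
    cat(sprintf("  methylation correlation (advisory): %.3f\n",
                x$meth_correlation))
  }
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Effect of a CDS deletion on the translated protein
#'
#' For a coding sequence and a half-open deletion interval (0-based, within
#' the CDS), reports whether the deletion is in frame (length divisible by
#' 3) and, if so, how many residues the translated mutant protein loses
#' relative to the original. Both sequences are translated with the standard
#' code up to the first stop codon, so an in-frame deletion that creates a
#' premature stop reports the full truncation, not just the deleted span.
#'
#' @param cds coding nucleotide sequence (character), length divisible by 3.
#' @param deletion_start,deletion_end half-open 0-based interval within the
#'   CDS.
#' @return list: in_frame (logical), residues_removed (integer, NA when out
#'   of frame), premature_stop (logical).
#' @export
deletion_effect <- function(cds, deletion_start, deletion_end) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3")
  if (deletion_start < 0 || deletion_end > n || deletion_start >= deletion_end) {
    stop("deletion interval must be half-open, non-empty and within the CDS")
  }
  del_len <- deletion_end - deletion_start
  if (del_len %% 3 != 0) {
    return(list(in_frame = FALSE, residues_removed = NA_integer_,
                premature_stop = NA))
  }
  mutant <- paste0(substr(cds, 1, deletion_start),
                   substr(cds, deletion_end + 1, n))
  translate_to_stop <- function(seq) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                             if.fuzzy.codon = "X"))
    sub("\\*.*$", "", aa)
  }
  p0 <- translate_to_stop(cds)
  p1 <- translate_to_stop(mutant)
  removed <- nchar(p0) - nchar(p1)
  list(in_frame = TRUE,
       residues_removed = as.integer(removed),
       premature_stop = removed > del_len / 3)
}

#' Somatic mutation burden per megabase
#'
#' Quotient of somatic variant count over the captured target size,
#' reported to two decimals; values above \code{outlier_cut} (default 0.5
#' per Mb, the cohort-typical ceiling) are flagged.
#'
#' @param n_somatic non-negative integer variant count.
#' @param target_size_mb captured target size in megabases, > 0.
#' @param outlier_cut flag threshold in variants/Mb, default 0.5.
#' @return list: burden (numeric, 2 dp), outlier (logical).
#' @export
mutation_burden <- function(n_somatic, target_size_mb, outlier_cut = 0.5) {
  if (!is.numeric(target_size_mb) || target_size_mb <= 0) {
    stop("configuration error: target_size_mb must be positive")
  }
  if (n_somatic < 0) stop("n_somatic must be >= 0")
  burden <- round(n_somatic / target_size_mb, 2)
  list(burden = burden, outlier = burden > outlier_cut)
}
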