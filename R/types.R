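# Domain containers.
#
# The pipeline works on plain base-R structures, in the style of expression
# analysis packages: a beta matrix is a numeric matrix (probes x samples,
# NA = masked non-detection), counts are an integer-valued matrix
# (genes x samples), and annotation tables are data.frames. The validators
# below define and enforce the contracts; every reader and the simulator
# run them before returning.

#' Validate a beta-value matrix
#'
#' A beta matrix is a numeric matrix of methylation fractions in
#' \code{[0, 1]} with unique probe rownames and sample colnames. Masked
#' (non-detected) cells are \code{NA}; masking, not imputation, is how
#' missingness is represented throughout.
#'
#' @param beta numeric matrix, probes x samples.
#' @return the matrix, invisibly; errors name the offending cell.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("beta matrix must be a numeric matrix")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) stop("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids in beta matrix")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "beta value out of [0, 1] at probe '%s', sample '%s' (value %g)",
      rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
      beta[bad[1, 1], bad[1, 2]]
    ))
  }
  invisible(beta)
}

#' Validate a probe annotation table
#'
#' Required columns: \code{probe_id}, \code{chrom}, \code{pos} (0-based),
#' \code{probe_class} in \{CpG, CpH, SNP\}, \code{gene} (NA when unassigned),
#' \code{tss_distance} (signed bp to the assigned TSS, NA when unassigned)
#' and \code{tfbs} (semicolon-joined transcription-factor labels, empty
#' string when none).
#'
#' @param ann data.frame of probe annotation.
#' @return the table, invisibly.
#' @export
validate_probe_annotation <- function(ann) {
  need <- c("probe_id", "chrom", "pos", "probe_class", "gene",
            "tss_distance", "tfbs")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    stop("probe annotation missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe ids in annotation")
  if (any(ann$pos < 0)) stop("probe positions must be >= 0")
  bad <- setdiff(unique(ann$probe_class), c("CpG", "CpH", "SNP"))
  if (length(bad)) {
    stop("unknown probe_class value(s): ", paste(bad, collapse = ", "))
  }
  invisible(ann)
}

#' Validate a read-count matrix
#'
#' Non-negative integer-valued matrix, genes x samples, unique ids.
#'
#' @param counts numeric matrix of read counts.
#' @return the matrix, invisibly.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("count matrix must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in count matrix")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in count matrix")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  invisible(counts)
}

#' Validate a sample sheet
#'
#' Required columns: \code{sample_id}, \code{patient_id}, \code{tissue} in
#' \{normal_myometrium, fibroid, cervical_stroma\}, \code{med12_mutation}
#' (logical) and optionally \code{med12_descriptor} and \code{race_label}.
#'
#' @param samples data.frame sample sheet.
#' @return the table, invisibly.
#' @export
validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "patient_id", "tissue", "med12_mutation")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(samples$tissue),
                 c("normal_myometrium", "fibroid", "cervical_stroma"))
  if (length(bad)) stop("unknown tissue value(s): ", paste(bad, collapse = ", "))
  if (!is.logical(samples$med12_mutation)) {
    stop("med12_mutation must be logical")
  }
  invisible(samples)
}

#' Validate an allelic count table
#'
#' Per chromosome-X locus and sample: DNA and RNA reference/alternate read
#' counts. Required columns: \code{locus_id}, \code{chrom}, \code{pos},
#' \code{sample_id}, \code{dna_ref}, \code{dna_alt}, \code{rna_ref},
#' \code{rna_alt}. (locus_id, sample_id) pairs must be unique and counts
#' non-negative.
#'
#' @param allelic data.frame of allelic counts.
#' @return the table, invisibly.
#' @export
validate_allelic_counts <- function(allelic) {
  need <- c("locus_id", "chrom", "pos", "sample_id",
            "dna_ref", "dna_alt", "rna_ref", "rna_alt")
  miss <- setdiff(need, names(allelic))
  if (length(miss)) {
    stop("allelic count table missing column(s): ", paste(miss, collapse = ", "))
  }
  cnt <- as.matrix(allelic[, c("dna_ref", "dna_alt", "rna_ref", "rna_alt")])
  if (any(cnt < 0)) stop("allelic counts must be >= 0")
  if (anyDuplicated(allelic[, c("locus_id", "sample_id")])) {
    stop("duplicate (locus_id, sample_id) pairs in allelic count table")
  }
  invisible(allelic)
}
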