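# Readers and writers.
#
# On-disk formats are plain text: tab-delimited matrices/tables with a header
# row, and a BED-style probe annotation (0-based, half-open coordinates on
# disk; positions are kept 0-based in memory). Result writers prepend
# provenance comment lines ('# key=value') that the paired readers skip.

#' Read a beta-value matrix from TSV
#'
#' First column \code{probe_id}, remaining columns one per sample. Values
#' are validated to \code{[0, 1]} (NA = masked).
#'
#' @param path file path.
#' @return numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "probe_id") {
    stop("beta matrix file must start with a 'probe_id' column, found '",
         names(df)[1], "'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  storage.mode(m) <- "double"
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix to TSV
#' @param beta probes x samples matrix.
#' @param path file path.
#' @param config optional \code{fibro_config}; its seed is echoed in a header
#'   comment.
#' @return the path, invisibly.
#' @export
write_beta_matrix <- function(beta, path, config = NULL) {
  validate_beta_matrix(beta)
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  write_result(df, path, config)
}

#' Read a BED-style probe annotation
#'
#' Columns (no header, BED convention): chrom, start, end, probe_id,
#' probe_class, gene, tss_distance, semicolon-joined TFBS labels. Start is
#' 0-based, half-open; the in-memory \code{pos} is the start coordinate.
#'
#' @param path file path.
#' @return data.frame passing [validate_probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          na.strings = c("NA", "."))
  if (ncol(df) != 8) {
    stop("probe annotation must have 8 BED-style columns, found ", ncol(df))
  }
  names(df) <- c("chrom", "start", "end", "probe_id", "probe_class",
                 "gene", "tss_distance", "tfbs")
  ann <- data.frame(
    probe_id = as.character(df$probe_id),
    chrom = as.character(df$chrom),
    pos = as.integer(df$start),
    probe_class = as.character(df$probe_class),
    gene = as.character(df$gene),
    tss_distance = as.integer(df$tss_distance),
    tfbs = ifelse(is.na(df$tfbs), "", as.character(df$tfbs)),
    stringsAsFactors = FALSE
  )
  validate_probe_annotation(ann)
  ann
}

#' Write a probe annotation as BED
#' @param ann annotation data.frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_probe_annotation <- function(ann, path) {
  validate_probe_annotation(ann)
  out <- data.frame(
    chrom = ann$chrom,
    start = ann$pos,
    end = ann$pos + 1L,
    probe_id = ann$probe_id,
    probe_class = ann$probe_class,
    gene = ifelse(is.na(ann$gene), ".", ann$gene),
    tss_distance = ifelse(is.na(ann$tss_distance), ".",
                          as.character(ann$tss_distance)),
    tfbs = ifelse(ann$tfbs == "", ".", ann$tfbs)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene count matrix from TSV
#' @param path file path; first column \code{gene_id}.
#' @return integer-valued matrix, genes x samples.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "gene_id") {
    stop("count matrix file must start with a 'gene_id' column, found '",
         names(df)[1], "'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  validate_count_matrix(m)
  m
}

#' Write a gene count matrix to TSV
#' @inheritParams write_beta_matrix
#' @param counts genes x samples matrix.
#' @return the path, invisibly.
#' @export
write_count_matrix <- function(counts, path, config = NULL) {
  validate_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write_result(df, path, config)
}

#' Read a sample sheet from TSV
#' @param path file path.
#' @return data.frame passing [validate_sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("med12_mutation" %in% names(df)) {
    df$med12_mutation <- as.logical(df$med12_mutation)
  }
  validate_sample_sheet(df)
  df
}

#' Read an allelic count table from TSV
#' @param path file path with columns locus_id, chrom, pos, sample_id,
#'   dna_ref, dna_alt, rna_ref, rna_alt.
#' @return data.frame passing [validate_allelic_counts()].
#' @export
read_allelic_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_allelic_counts(df)
  df
}

#' Build an allelic count table from paired DNA/RNA VCFs
#'
#' Reads the AD (allelic depth) FORMAT field from a DNA VCF and an RNA VCF
#' covering the same loci and samples and merges them into the allelic count
#' table used by the clonality module. Requires the \pkg{vcfR} package.
#'
#' @param dna_vcf,rna_vcf paths to VCF files with AD fields.
#' @return data.frame passing [validate_allelic_counts()].
#' @export
read_allelic_vcf <- function(dna_vcf, rna_vcf) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_allelic_vcf requires the 'vcfR' package")
  }
  parse_one <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(v, element = "AD")
    fix <- vcfR::getFIX(v)
    ref <- apply(ad, 2, function(x) as.integer(sub(",.*", "", x)))
    alt <- apply(ad, 2, function(x) as.integer(sub(".*,", "", x)))
    list(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]) - 1L,
         id = fix[, "ID"], ref = ref, alt = alt,
         samples = colnames(ad))
  }
  d <- parse_one(dna_vcf)
  r <- parse_one(rna_vcf)
  if (!identical(d$id, r$id) || !identical(d$samples, r$samples)) {
    stop("DNA and RNA VCFs must cover identical loci and samples")
  }
  out <- do.call(rbind, lapply(seq_along(d$samples), function(j) {
    data.frame(
      locus_id = d$id, chrom = d$chrom, pos = d$pos,
      sample_id = d$samples[j],
      dna_ref = d$ref[, j], dna_alt = d$alt[, j],
      rna_ref = r$ref[, j], rna_alt = r$alt[, j],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  validate_allelic_counts(out)
  out
}

#' Load and cross-validate a full dataset
#'
#' Reads the five standard files and checks referential integrity: every
#' sample id appearing in the beta matrix, count matrix or allelic table must
#' be declared in the sample sheet, and every beta probe must be annotated.
#' Beta values are clipped to \code{[eps, 1 - eps]} after range validation,
#' so downstream logit transforms are finite; the clip margin is recorded in
#' the returned config.
#'
#' @param paths named list/vector with entries \code{beta},
#'   \code{annotation}, \code{counts}, \code{samples}, \code{allelic}
#'   (\code{allelic} may be omitted).
#' @param config a \code{fibro_config}, default [default_config()].
#' @return list of class \code{"fibro_cohort"} with elements \code{beta},
#'   \code{annotation}, \code{counts}, \code{samples}, \code{allelic},
#'   \code{config}.
#' @export
load_dataset <- function(paths, config = default_config()) {
  validate_config(config)
  need <- c("beta", "annotation", "counts", "samples")
  miss <- setdiff(need, names(paths))
  if (length(miss)) {
    stop("load_dataset needs path(s): ", paste(miss, collapse = ", "))
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  beta <- read_beta_matrix(paths[["beta"]])
  ann <- read_probe_annotation(paths[["annotation"]])
  counts <- read_count_matrix(paths[["counts"]])
  samples <- read_sample_sheet(paths[["samples"]])
  allelic <- if (!is.null(paths[["allelic"]])) {
    read_allelic_counts(paths[["allelic"]])
  } else {
    NULL
  }

  check_samples <- function(ids, where) {
    unknown <- setdiff(ids, samples$sample_id)
    if (length(unknown)) {
      stop(sprintf("sample(s) in %s absent from sample sheet: %s",
                   where, paste(unknown, collapse = ", ")))
    }
  }
  check_samples(colnames(beta), "beta matrix")
  check_samples(colnames(counts), "count matrix")
  if (!is.null(allelic)) check_samples(unique(allelic$sample_id), "allelic table")
  unann <- setdiff(rownames(beta), ann$probe_id)
  if (length(unann)) {
    stop("probe(s) in beta matrix without annotation: ",
         paste(utils::head(unann, 5), collapse = ", "),
         if (length(unann) > 5) sprintf(" (and %d more)", length(unann) - 5) else "")
  }

  beta <- clip_beta(beta, config$eps)
  structure(
    list(beta = beta, annotation = ann, counts = counts,
         samples = samples, allelic = allelic, config = config),
    class = "fibro_cohort"
  )
}

#' Write a result table with provenance header
#'
#' Writes a data.frame as TSV with deterministic column order and
#' \code{# key=value} comment lines carrying the package version and, when a
#' config is supplied, the RNG seed. [read_result()] reproduces the table.
#'
#' @param result a data.frame.
#' @param path file path.
#' @param config optional \code{fibro_config} whose seed is echoed.
#' @return the path, invisibly.
#' @export
write_result <- function(result, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("fibrointegra"))
  writeLines(sprintf("# fibrointegra=%s", ver), con)
  if (!is.null(config)) {
    writeLines(sprintf("# seed=%d", as.integer(config$seed)), con)
  }
  utils::write.table(result, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result()]
#' @param path file path.
#' @return data.frame.
#' @export
read_result <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a compartment track as bedGraph
#'
#' Four columns (chrom, start, end, eigenvector loading); masked bins are
#' skipped. A companion \code{.bed} of merged A/B segments can be derived
#' from the same track object.
#'
#' @param track a \code{CompartmentTrack} data.frame from
#'   [compartment_eigenvector()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_compartment_track <- function(track, path) {
  ok <- track$compartment != "masked"
  out <- data.frame(track$chrom[ok], track$bin_start[ok], track$bin_end[ok],
                    signif(track$loading[ok], 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a dendrogram in Newick format
#' @param hc an \code{hclust} object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
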