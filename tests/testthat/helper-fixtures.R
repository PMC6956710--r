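# Shared fixtures, built in code.

# memoised study-profile cohort so several test files can share one draw
.cohort_cache <- new.env(parent = emptyenv())
get_cohort <- function(seed = 11L) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(paper_profile(), seed = seed)
  }
  .cohort_cache[[key]]
}

group_samples <- function(cohort, grp) {
  names(cohort$truth$group)[cohort$truth$group == grp]
}

# tiny beta matrix with named probes/samples
toy_beta <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(probes)) probes <- sprintf("p%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(probes, samples)
  m
}

# minimal annotation for toy probes
toy_annotation <- function(probe_ids, chrom = "chr1", pos = NULL,
                           probe_class = "CpG", gene = NA_character_,
                           tss_distance = NA_integer_, tfbs = "") {
  n <- length(probe_ids)
  data.frame(
    probe_id = probe_ids,
    chrom = rep_len(chrom, n),
    pos = if (is.null(pos)) 1000L * seq_len(n) else pos,
    probe_class = rep_len(probe_class, n),
    gene = rep_len(gene, n),
    tss_distance = rep_len(tss_distance, n),
    tfbs = rep_len(tfbs, n),
    stringsAsFactors = FALSE
  )
}

# allelic-count row builder
allelic_row <- function(locus, sample, dna_ref, dna_alt, rna_ref, rna_alt,
                        pos = 1000L) {
  data.frame(locus_id = locus, chrom = "chrX", pos = pos, sample_id = sample,
             dna_ref = dna_ref, dna_alt = dna_alt,
             rna_ref = rna_ref, rna_alt = rna_alt,
             stringsAsFactors = FALSE)
}

# independent codon-table translation used as an oracle against the
# Biostrings-based path
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16),
                   rep(rep(bases, each = 4), times = 4),
                   rep(bases, times = 16))
  # standard genetic code in TCAG order
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  stats::setNames(aas, codons)
})

oracle_translate <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  aa <- .codon_table[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1)]
  paste(aa, collapse = "")
}

random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  non_stop <- function() {
    repeat {
      c3 <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!c3 %in% c("TAA", "TAG", "TGA")) return(c3)
    }
  }
  paste0("ATG", paste(replicate(n_codons - 2, non_stop()), collapse = ""), "TAA")
}
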