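# Synthetic cohort generator.
#
# Emulates the statistical structure of a fibroid methylation/expression
# cohort: group-structured beta values for normal myometrium plus three
# fibroid subtypes, subtype marker expression, promoter-methylation-coupled
# silencing, purity-driven marker-promoter methylation, patient-consistent
# SNP-probe genotypes, chromosome-X allelic counts under planted
# X-inactivation patterns, and block-correlated compartment structure along
# one chromosome. Every planted quantity is recorded in a truth bundle so
# recovery can be tested.

.fibro_groups <- c("normal", "MED12mt", "HMGA2hi", "HMGA1hi")

#' Study-profile generator configuration
#'
#' Preset matching the discovery cohort design: 10 normal myometria and 24
#' fibroids split 16/4/4 into MED12-mutant, HMGA2-high and HMGA1-high
#' subtypes; 20,000 CpG probes plus 200 CpH and 59 SNP probes; planted
#' marker effects of log2 fold change 11.6 (HMGA2, HMGA2hi group) and 3.2
#' (HMGA2, MED12mt), 4.4 and 3 for HOXA13, and 3 for HMGA1 in HMGA1hi
#' (the subtype rule only requires > 2-fold); two patients carrying two
#' fibroids each, one pair sharing the inactive X and one pair with
#' independent inactive X; tumour purity drawn from \code{[0.7, 0.9]}.
#'
#' @param ... overrides passed to [default_config()] for the analysis
#'   thresholds; generator entries live under \code{$generator}.
#' @return a \code{fibro_config} with a \code{generator} entry.
#' @examples
#' prof <- paper_profile()
#' prof$generator$group_sizes
#' @export
paper_profile <- function(...) {
  cfg <- default_config(...)
  cfg$generator <- list(
    group_sizes = c(normal = 10L, MED12mt = 16L, HMGA2hi = 4L, HMGA1hi = 4L),
    n_cpg = 20000L,
    n_cph = 200L,
    n_snp = 59L,
    n_informative = 150L,
    # per-set informative design: sizes and group means
    informative_sets = list(
      shared_hyper   = list(n = 50L, means = c(0.15, 0.75, 0.70, 0.20)),
      med12_hyper    = list(n = 40L, means = c(0.20, 0.70, 0.25, 0.25)),
      hmga2_hypo     = list(n = 40L, means = c(0.85, 0.80, 0.15, 0.85)),
      hmga1_hyper    = list(n = 20L, means = c(0.10, 0.10, 0.10, 0.80))
    ),
    kappa = 50,
    kappa_snp = 200,
    n_genes = 2000L,
    nb_dispersion = 0.1,
    marker_genes = data.frame(
      gene = c("HMGA2", "HMGA2", "HOXA13", "HOXA13", "HMGA1"),
      group = c("HMGA2hi", "MED12mt", "HMGA2hi", "MED12mt", "HMGA1hi"),
      log2fc = c(11.6, 3.2, 4.4, 3, 3),
      stringsAsFactors = FALSE
    ),
    marker_base_cpm = c(HMGA2 = 0.5, HOXA13 = 20, HMGA1 = 30),
    n_coupled = 30L,
    coupled_delta = 0.4,
    coupled_log2fc = -2,
    n_silent = 50L,
    n_dmc_distal = 300L,
    dmc_distal_delta = 0.35,
    n_distal_background = 1700L,
    n_tf = 20L,
    planted_tf = "EZH2",
    tf_set_size = 300L,
    purity_range = c(0.7, 0.9),
    normal_purity_range = c(0.9, 0.98),
    n_x_loci = 40L,
    het_rate = 0.6,
    dna_depth = 30,
    rna_depth = 30,
    rna_mono_frac = 0.98,
    seq_error = 0.01,
    compartment_chrom = "chr12",
    n_bins = 20L,
    block_len = 5L,
    probes_per_bin = c(A = 8L, B = 4L),
    compartment_base = c(A = 0.45, B = 0.55),
    compartment_amp = 0.15,
    lib_factor_range = c(0.5, 1.5)
  )
  cfg
}

# truncated standard normal draws on [-2, 2]
rtnorm2 <- function(n) {
  x <- stats::rnorm(n)
  while (any(bad <- abs(x) > 2)) x[bad] <- stats::rnorm(sum(bad))
  x
}

# beta-distributed noise around mean mu with concentration kappa,
# mu clipped into (0, 1) for valid shapes
rbeta_mu <- function(mu, kappa) {
  mu <- pmin(pmax(mu, 0.02), 0.98)
  stats::rbeta(length(mu), mu * kappa, (1 - mu) * kappa)
}

#' Simulate a cohort with planted truth
#'
#' Draws a full dataset (beta matrix, probe annotation, count matrix, sample
#' sheet, allelic count table) under the structure described in
#' [paper_profile()], together with a \code{truth} bundle recording every
#' planted parameter. Beta values are Beta-distributed around group means
#' (concentration \code{kappa}), counts are negative-binomial with a
#' per-sample library factor spanning the configured range, SNP-probe
#' genotypes are constant within a patient, DNA allelic counts are binomial
#' around 0.5 at heterozygous chromosome-X loci, RNA allelic counts are
#' near-monoallelic for the tumour's planted inactive X, and one chromosome
#' carries alternating blocks of correlated methylation for compartment
#' recovery. Identical seeds give bit-identical output.
#'
#' @param config a \code{fibro_config} carrying a \code{generator} entry,
#'   usually from [paper_profile()].
#' @param seed integer RNG seed.
#' @return list of class \code{"fibro_cohort"} with elements \code{beta},
#'   \code{annotation}, \code{counts}, \code{samples}, \code{allelic},
#'   \code{truth}, \code{config}.
#' @export
simulate_cohort <- function(config = paper_profile(), seed = 1L) {
  validate_config(config)
  gen <- config$generator
  if (is.null(gen)) stop("configuration error: config has no generator entry")
  n_inf_sets <- sum(vapply(gen$informative_sets, function(s) s$n, integer(1)))
  if (n_inf_sets != gen$n_informative) {
    stop("configuration error: informative set sizes do not sum to n_informative")
  }
  n_special <- gen$n_informative + gen$n_dmc_distal + gen$n_distal_background +
    2L * gen$n_coupled + 10L + sum(rep(gen$probes_per_bin, gen$n_bins / (2 * gen$block_len) * gen$block_len))
  if (n_special >= gen$n_cpg) {
    stop("configuration error: more planted probes than CpG probes")
  }
  set.seed(as.integer(seed))

  ## ---- samples ----------------------------------------------------------
  gs <- gen$group_sizes
  group <- rep(.fibro_groups, times = gs[.fibro_groups])
  sample_id <- c(sprintf("N%02d", seq_len(gs["normal"])),
                 sprintf("F%02d", seq_len(sum(gs) - gs["normal"])))
  n_samples <- length(sample_id)
  is_fibroid <- group != "normal"
  # patients: normals from PT01..PT10; first two MED12mt patients carry two
  # fibroids each (PT01 shared-XCI pair, PT02 independent-XCI pair)
  patient <- character(n_samples)
  patient[!is_fibroid] <- sprintf("PT%02d", seq_len(gs["normal"]))
  fib_idx <- which(is_fibroid)
  fib_patient <- c("PT01", "PT01", "PT02", "PT02",
                   sprintf("PT%02d", 2 + seq_len(length(fib_idx) - 4)))
  patient[fib_idx] <- fib_patient
  samples <- data.frame(
    sample_id = sample_id,
    patient_id = patient,
    tissue = ifelse(is_fibroid, "fibroid", "normal_myometrium"),
    med12_mutation = group == "MED12mt",
    med12_descriptor = ifelse(group == "MED12mt", "exon2_missense", ""),
    race_label = rep_len(c("AA", "C"), n_samples),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(samples)

  ## ---- purity -----------------------------------------------------------
  purity <- numeric(n_samples)
  purity[is_fibroid] <- stats::runif(sum(is_fibroid),
                                     gen$purity_range[1], gen$purity_range[2])
  purity[!is_fibroid] <- stats::runif(sum(!is_fibroid),
                                      gen$normal_purity_range[1],
                                      gen$normal_purity_range[2])
  names(purity) <- sample_id

  ## ---- probe layout -----------------------------------------------------
  sets <- gen$informative_sets
  inf_ids <- sprintf("cg_inf%04d", seq_len(gen$n_informative))
  inf_set <- rep(names(sets), vapply(sets, function(s) s$n, integer(1)))
  inf_means <- do.call(rbind, lapply(seq_along(inf_ids), function(i) {
    sets[[inf_set[i]]]$means
  }))
  colnames(inf_means) <- .fibro_groups

  dmc_ids <- sprintf("cg_dmc%04d", seq_len(gen$n_dmc_distal))
  distal_bg_ids <- sprintf("cg_dst%04d", seq_len(gen$n_distal_background))
  coupled_genes <- sprintf("CPLD%03d", seq_len(gen$n_coupled))
  coupled_ids <- sprintf("cg_cpl%04d", seq_len(2L * gen$n_coupled))
  marker_ids <- c(sprintf("cg_mir200c%02d", 1:5), sprintf("cg_acta2%02d", 1:5))

  n_half_blocks <- gen$n_bins / gen$block_len
  block_label <- rep(rep(c("A", "B"), length.out = n_half_blocks),
                     each = gen$block_len)
  bin_probes <- gen$probes_per_bin[block_label]
  comp_ids <- sprintf("cg_cmp%04d", seq_len(sum(bin_probes)))
  comp_bin <- rep(seq_len(gen$n_bins), times = bin_probes)

  n_bg <- gen$n_cpg - length(inf_ids) - length(dmc_ids) -
    length(distal_bg_ids) - length(coupled_ids) - length(marker_ids) -
    length(comp_ids)
  bg_ids <- sprintf("cg_bg%05d", seq_len(n_bg))
  cph_ids <- sprintf("ch_%04d", seq_len(gen$n_cph))
  snp_ids <- sprintf("rs_%04d", seq_len(gen$n_snp))

  probe_id <- c(inf_ids, dmc_ids, distal_bg_ids, coupled_ids, marker_ids,
                comp_ids, bg_ids, cph_ids, snp_ids)
  n_probes <- length(probe_id)

  ## ---- annotation -------------------------------------------------------
  autosomes <- paste0("chr", c(1:11, 13:22))
  ann <- data.frame(
    probe_id = probe_id,
    chrom = rep_len(autosomes, n_probes),
    pos = integer(n_probes),
    probe_class = rep(c("CpG", "CpH", "SNP"),
                      c(gen$n_cpg, gen$n_cph, gen$n_snp)),
    gene = NA_character_,
    tss_distance = NA_integer_,
    tfbs = "",
    stringsAsFactors = FALSE
  )
  rownames(ann) <- ann$probe_id
  ann$pos <- 10000L + 137L * seq_len(n_probes)   # arbitrary, strictly increasing

  # informative probes: promoter-adjacent, no TFBS (kept out of the distal
  # enrichment universe by construction)
  ann[inf_ids, "tss_distance"] <- 500L
  ann[inf_ids, "gene"] <- sprintf("INFG%03d", seq_along(inf_ids))
  # distal probes: beyond the 2 kb promoter window, carry TFBS labels
  ann[c(dmc_ids, distal_bg_ids), "tss_distance"] <- 50000L
  # coupled promoter probes: two per coupled gene, within the promoter window
  ann[coupled_ids, "gene"] <- rep(coupled_genes, each = 2L)
  ann[coupled_ids, "tss_distance"] <- rep(c(-350L, 420L), gen$n_coupled)
  # marker promoter probes: within +/- 500 bp of the marker TSS
  ann[marker_ids, "gene"] <- rep(c("MIR200C", "ACTA2"), each = 5L)
  ann[marker_ids, "tss_distance"] <- rep(c(-400L, -200L, 0L, 200L, 400L), 2L)
  # compartment probes: one chromosome, tiled into fixed 100-kb bins
  ann[comp_ids, "chrom"] <- gen$compartment_chrom
  bin_size <- as.integer(config$bin_size)
  within <- unlist(lapply(bin_probes, function(k) {
    as.integer(round(seq(0.1, 0.9, length.out = k) * bin_size))
  }))
  ann[comp_ids, "pos"] <- (comp_bin - 1L) * bin_size + within
  # background CpG: alternate promoter-assigned and distal-unannotated
  bg_gene <- sprintf("GENE%04d", rep_len(seq_len(gen$n_genes), n_bg))
  prom_bg <- seq_len(n_bg) %% 2L == 0L
  ann[bg_ids[prom_bg], "gene"] <- bg_gene[prom_bg]
  ann[bg_ids[prom_bg], "tss_distance"] <- 900L
  ann[bg_ids[!prom_bg], "tss_distance"] <- 30000L
  ann[snp_ids, "chrom"] <- "chr1"

  # TFBS memberships over the distal universe
  universe_ids <- c(dmc_ids, distal_bg_ids)
  tf_labels <- c(gen$planted_tf, "SUZ12", "CTCF", "ESR1", "NR3C1",
                 sprintf("TF%02d", seq_len(gen$n_tf - 5L)))
  tf_members <- vector("list", length(tf_labels))
  names(tf_members) <- tf_labels
  # planted TF: half of its binding sites sit on planted-DMC distal probes
  half <- gen$tf_set_size %/% 2L
  tf_members[[gen$planted_tf]] <- c(sample(dmc_ids, half),
                                    sample(distal_bg_ids, gen$tf_set_size - half))
  for (tf in setdiff(tf_labels, gen$planted_tf)) {
    tf_members[[tf]] <- sample(universe_ids, gen$tf_set_size)
  }
  tfbs_by_probe <- split(
    rep(tf_labels, lengths(tf_members)),
    factor(unlist(tf_members), levels = universe_ids)
  )
  ann[universe_ids, "tfbs"] <- vapply(
    tfbs_by_probe, function(x) paste(sort(x), collapse = ";"), character(1)
  )
  validate_probe_annotation(ann)

  ## ---- beta matrix ------------------------------------------------------
  grp_idx <- match(group, .fibro_groups)
  mu <- matrix(0, n_probes, n_samples, dimnames = list(probe_id, sample_id))
  mu[inf_ids, ] <- inf_means[, grp_idx]
  mu[dmc_ids, ] <- ifelse(rep(is_fibroid, each = length(dmc_ids)),
                          0.15 + gen$dmc_distal_delta, 0.15)
  bg_dst_mean <- stats::runif(length(distal_bg_ids), 0.1, 0.9)
  mu[distal_bg_ids, ] <- bg_dst_mean
  mu[coupled_ids, ] <- ifelse(rep(is_fibroid, each = length(coupled_ids)),
                              0.15 + gen$coupled_delta, 0.15)
  mu[marker_ids[1:5], ] <- rep(purity, each = 5)          # methylated in target
  mu[marker_ids[6:10], ] <- rep(1 - purity, each = 5)     # unmethylated in target
  u <- rtnorm2(n_samples)                                 # compartment latent
  amp <- gen$compartment_amp
  comp_sign <- ifelse(block_label[comp_bin] == "A", 1, -1)
  comp_base <- gen$compartment_base[block_label[comp_bin]]
  mu[comp_ids, ] <- comp_base + outer(comp_sign * amp, u)
  bg_mean <- ifelse(stats::runif(n_bg) < 0.5,
                    stats::runif(n_bg, 0.05, 0.15),
                    stats::runif(n_bg, 0.8, 0.92))
  mu[bg_ids, ] <- bg_mean
  mu[cph_ids, ] <- 0.04

  # patient-level SNP genotypes, shared by all samples from the patient
  patients <- unique(patient)
  gt_pat <- matrix(sample(c(0, 0.5, 1), gen$n_snp * length(patients),
                          replace = TRUE, prob = c(0.25, 0.5, 0.25)),
                   nrow = gen$n_snp,
                   dimnames = list(snp_ids, patients))
  snp_mu <- gt_pat[, patient, drop = FALSE]
  snp_mu <- 0.03 + snp_mu * 0.94                          # 0 -> .03, .5 -> .5, 1 -> .97
  mu[snp_ids, ] <- snp_mu

  beta <- mu
  non_snp <- setdiff(probe_id, snp_ids)
  beta[non_snp, ] <- rbeta_mu(mu[non_snp, ], gen$kappa)
  beta[snp_ids, ] <- rbeta_mu(mu[snp_ids, ], gen$kappa_snp)
  validate_beta_matrix(beta)

  ## ---- counts -----------------------------------------------------------
  gene_id <- sprintf("GENE%04d", seq_len(gen$n_genes))
  gene_id[1:3] <- c("HMGA2", "HMGA1", "HOXA13")
  silent_genes <- gene_id[4:(3 + gen$n_silent)]
  # coupled genes replace a slice of the background ids
  cpl_slice <- (4 + gen$n_silent):(3 + gen$n_silent + gen$n_coupled)
  gene_id[cpl_slice] <- coupled_genes
  ann$gene[!is.na(ann$gene) & ann$gene %in% sprintf("GENE%04d", c(1:3, 4:(3 + gen$n_silent), cpl_slice))] <- NA

  base_cpm <- exp(stats::rnorm(gen$n_genes, log(30), 1.2))
  names(base_cpm) <- gene_id
  base_cpm[names(gen$marker_base_cpm)] <- gen$marker_base_cpm
  base_cpm[silent_genes] <- 0.02
  scale_ids <- setdiff(gene_id, c(names(gen$marker_base_cpm), silent_genes))
  base_cpm[scale_ids] <- base_cpm[scale_ids] *
    (1e6 - sum(base_cpm[c(names(gen$marker_base_cpm), silent_genes)])) /
    sum(base_cpm[scale_ids])

  # planted effects on the CPM + 0.5 scale, so the estimator's pseudo-count
  # arithmetic recovers the planted log2 fold change
  cpm_group <- matrix(base_cpm, gen$n_genes, length(.fibro_groups),
                      dimnames = list(gene_id, .fibro_groups))
  for (i in seq_len(nrow(gen$marker_genes))) {
    g <- gen$marker_genes$gene[i]
    grp <- gen$marker_genes$group[i]
    cpm_group[g, grp] <- (base_cpm[g] + 0.5) * 2^gen$marker_genes$log2fc[i] - 0.5
  }
  for (grp in setdiff(.fibro_groups, "normal")) {
    cpm_group[coupled_genes, grp] <-
      pmax((base_cpm[coupled_genes] + 0.5) * 2^gen$coupled_log2fc - 0.5, 0.01)
  }

  lib_factor <- sample(seq(gen$lib_factor_range[1], gen$lib_factor_range[2],
                           length.out = n_samples))
  names(lib_factor) <- sample_id
  mu_counts <- cpm_group[, group, drop = FALSE] *
    rep(lib_factor, each = gen$n_genes)
  counts <- matrix(
    stats::rnbinom(length(mu_counts), mu = mu_counts,
                   size = 1 / gen$nb_dispersion),
    nrow = gen$n_genes, dimnames = list(gene_id, sample_id)
  )
  storage.mode(counts) <- "double"
  validate_count_matrix(counts)

  ## ---- chromosome-X allelic counts --------------------------------------
  loci <- sprintf("XL%03d", seq_len(gen$n_x_loci))
  locus_pos <- 100000L + 25000L * seq_len(gen$n_x_loci)
  gt_x <- matrix(sample(c("hom_ref", "het", "hom_alt"),
                        gen$n_x_loci * length(patients), replace = TRUE,
                        prob = c((1 - gen$het_rate) / 2, gen$het_rate,
                                 (1 - gen$het_rate) / 2)),
                 nrow = gen$n_x_loci, dimnames = list(loci, patients))
  phase <- matrix(sample(c(1L, 2L), gen$n_x_loci * length(patients),
                         replace = TRUE),
                  nrow = gen$n_x_loci,
                  dimnames = list(loci, patients))   # haplotype carrying ALT
  inactive_x <- integer(n_samples)
  names(inactive_x) <- sample_id
  inactive_x[is_fibroid] <- sample(c(1L, 2L), sum(is_fibroid), replace = TRUE)
  # planted pairs: PT01 fibroids share the inactive X, PT02 fibroids differ
  pt01 <- sample_id[patient == "PT01" & is_fibroid]
  pt02 <- sample_id[patient == "PT02" & is_fibroid]
  inactive_x[pt01] <- 2L
  inactive_x[pt02] <- c(1L, 2L)

  err <- gen$seq_error
  allelic <- do.call(rbind, lapply(seq_len(n_samples), function(s) {
    pat <- patient[s]
    gt <- gt_x[, pat]
    dna_depth <- stats::rpois(gen$n_x_loci, gen$dna_depth)
    rna_depth <- stats::rpois(gen$n_x_loci, gen$rna_depth)
    dna_p <- ifelse(gt == "het", 0.5, ifelse(gt == "hom_alt", 1 - err, err))
    if (is_fibroid[s]) {
      active <- 3L - inactive_x[s]
      alt_expressed <- phase[, pat] == active
      rna_p <- ifelse(gt == "het",
                      ifelse(alt_expressed, gen$rna_mono_frac,
                             1 - gen$rna_mono_frac),
                      ifelse(gt == "hom_alt", 1 - err, err))
    } else {
      rna_p <- ifelse(gt == "het", 0.5,
                      ifelse(gt == "hom_alt", 1 - err, err))
    }
    dna_alt <- stats::rbinom(gen$n_x_loci, dna_depth, dna_p)
    rna_alt <- stats::rbinom(gen$n_x_loci, rna_depth, rna_p)
    data.frame(
      locus_id = loci, chrom = "chrX", pos = locus_pos,
      sample_id = sample_id[s],
      dna_ref = dna_depth - dna_alt, dna_alt = dna_alt,
      rna_ref = rna_depth - rna_alt, rna_alt = rna_alt,
      stringsAsFactors = FALSE
    )
  }))
  rownames(allelic) <- NULL
  validate_allelic_counts(allelic)

  ## ---- truth bundle -----------------------------------------------------
  truth <- list(
    seed = as.integer(seed),
    group = stats::setNames(group, sample_id),
    informative_probes = data.frame(
      probe_id = inf_ids, set = inf_set, inf_means,
      stringsAsFactors = FALSE, row.names = NULL
    ),
    dmc_distal_probes = dmc_ids,
    dmc_fibroid_vs_normal = c(dmc_ids, coupled_ids),
    marker_log2fc = gen$marker_genes,
    coupled_genes = data.frame(
      gene = coupled_genes,
      delta_beta = gen$coupled_delta,
      log2fc = gen$coupled_log2fc,
      stringsAsFactors = FALSE
    ),
    coupled_probes = coupled_ids,
    silent_genes = silent_genes,
    planted_tf = gen$planted_tf,
    tf_members = tf_members,
    purity = purity,
    xci = data.frame(
      sample_id = sample_id[is_fibroid],
      patient_id = patient[is_fibroid],
      inactive_x = inactive_x[is_fibroid],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    compartments = data.frame(
      chrom = gen$compartment_chrom,
      bin_start = (seq_len(gen$n_bins) - 1L) * bin_size,
      bin_end = seq_len(gen$n_bins) * bin_size,
      label = block_label,
      n_probes = as.integer(bin_probes),
      stringsAsFactors = FALSE
    ),
    lib_factor = lib_factor
  )

  structure(
    list(beta = beta, annotation = ann, counts = counts, samples = samples,
         allelic = allelic, truth = truth, config = config),
    class = "fibro_cohort"
  )
}

#' Write a simulated cohort to a directory
#'
#' Writes the five standard files (beta.tsv, annotation.bed, counts.tsv,
#' samples.tsv, allelic.tsv) plus \code{truth.json} when a truth bundle is
#' present. [load_dataset()] on the same directory round-trips the data.
#'
#' @param cohort a \code{fibro_cohort}.
#' @param dir output directory (created if missing).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    beta = file.path(dir, "beta.tsv"),
    annotation = file.path(dir, "annotation.bed"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    allelic = file.path(dir, "allelic.tsv")
  )
  write_beta_matrix(cohort$beta, paths["beta"], cohort$config)
  write_probe_annotation(cohort$annotation, paths["annotation"])
  write_count_matrix(cohort$counts, paths["counts"], cohort$config)
  write_result(cohort$samples, paths["samples"], cohort$config)
  write_result(cohort$allelic, paths["allelic"], cohort$config)
  if (!is.null(cohort$truth)) {
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}

#' @export
print.fibro_cohort <- function(x, ...) {
  cat("fibrointegra cohort\n")
  cat(sprintf("  %d probes x %d samples (beta), %d genes (counts)\n",
              nrow(x$beta), ncol(x$beta), nrow(x$counts)))
  if (!is.null(x$truth)) {
    cat("  simulated cohort with truth bundle, seed", x$truth$seed, "\n")
  }
  invisible(x)
}
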