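#' Default pipeline configuration
#'
#' Named thresholds and seeds used throughout the pipeline. Every analysis
#' function takes the relevant values as arguments with these defaults, and
#' [load_dataset()] / [simulate_cohort()] record the configuration used.
#'
#' Thresholds taken from the study design: variable-probe fraction 0.01
#' (top 1\% of CpG probes by standard deviation), DMC rule |delta beta| >= 0.2
#' with p < 0.05, fibroid-specific probe rule beta >= 0.3 in at least one
#' tumour with all normals <= 0.2, promoter window +/- 2 kb of the TSS,
#' TFBS enrichment FDR cutoff 1e-6, expression filter CPM >= 1 in >= 3
#' samples with DEG FDR < 0.05, starburst rule |delta beta| > 0.25 with
#' p < 0.05, consensus clustering with 1000 subsampling iterations, and
#' compartment bins of 100 kb. Thresholds the study describes only
#' qualitatively (genotype-call bands, identity cutoff, XCI depth and
#' monoallelic fractions) are this package's documented defaults.
#'
#' @param ... named overrides for any configuration entry.
#' @return a list of class \code{"fibro_config"}.
#' @examples
#' cfg <- default_config(consensus_iterations = 200)
#' cfg$consensus_iterations
#' @export
default_config <- function(...) {
  cfg <- list(
    eps = 1e-3,
    # subtyping
    var_fraction = 0.01,
    consensus_iterations = 1000,
    consensus_subsample = 0.8,
    hmga1_fc = 2,
    hmga2_fc = 5,
    # differential methylation
    dmc_min_delta = 0.2,
    dmc_alpha = 0.05,
    subtype_meth_min = 0.3,
    subtype_normal_max = 0.2,
    promoter_window = 2000,
    tfbs_fdr = 1e-6,
    # expression / integration
    cpm_min = 1,
    cpm_min_samples = 3,
    deg_fdr = 0.05,
    starburst_delta = 0.25,
    starburst_p = 0.05,
    # sample QC
    genotype_lower = 0.25,
    genotype_upper = 0.75,
    min_identity = 0.9,
    min_shared_snps = 10,
    # clonality
    xci_min_depth = 10,
    xci_het_band = c(0.2, 0.8),
    xci_mono_frac = 0.9,
    xci_min_informative = 5,
    xci_shared_min = 0.9,
    xci_independent_max = 0.1,
    # compartments
    bin_size = 1e5,
    bin_min_probes = 3,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "fibro_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks that every threshold lies in its documented range. Called by
#' [default_config()] and by functions that accept a config object.
#'
#' @param cfg a \code{"fibro_config"} list.
#' @return the config, invisibly, or an error naming the offending entry.
#' @export
validate_config <- function(cfg) {
  chk <- function(cond, what) {
    if (!isTRUE(cond)) stop("configuration error: ", what, call. = FALSE)
  }
  chk(cfg$eps > 0 && cfg$eps < 0.5, "eps must be in (0, 0.5)")
  chk(cfg$var_fraction > 0 && cfg$var_fraction <= 1,
      "var_fraction must be in (0, 1]")
  chk(cfg$consensus_iterations >= 1, "consensus_iterations must be >= 1")
  chk(cfg$consensus_subsample > 0 && cfg$consensus_subsample <= 1,
      "consensus_subsample must be in (0, 1]")
  chk(cfg$dmc_min_delta >= 0 && cfg$dmc_min_delta <= 1,
      "dmc_min_delta must be in [0, 1]")
  chk(cfg$dmc_alpha > 0 && cfg$dmc_alpha <= 1, "dmc_alpha must be in (0, 1]")
  chk(cfg$tfbs_fdr > 0 && cfg$tfbs_fdr <= 1, "tfbs_fdr must be in (0, 1]")
  chk(cfg$promoter_window > 0, "promoter_window must be positive")
  chk(cfg$bin_size > 0, "bin_size must be positive")
  chk(cfg$bin_min_probes >= 1, "bin_min_probes must be >= 1")
  chk(length(cfg$xci_het_band) == 2 &&
        cfg$xci_het_band[1] < cfg$xci_het_band[2],
      "xci_het_band must be an increasing pair")
  chk(cfg$min_identity > 0 && cfg$min_identity <= 1,
      "min_identity must be in (0, 1]")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && cfg$seed == round(cfg$seed),
      "seed must be a single integer")
  invisible(cfg)
}

#' @export
print.fibro_config <- function(x, ...) {
  cat("fibrointegra pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
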