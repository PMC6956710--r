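# Methylation-derived A/B chromatin compartments at fixed (100 kb)
# resolution: bin CpG betas along a chromosome, correlate bins across
# samples, and read the compartment structure off the first eigenvector of
# the bin-bin correlation matrix.

#' Bin methylation along a chromosome
#'
#' Half-open bins \code{[i * binsize, (i + 1) * binsize)} tiling the probed
#' extent of the chromosome; each bin's value per sample is the mean beta of
#' its unmasked CpG probes. Bins with fewer than \code{min_probes} probes
#' are masked (all-NA row).
#'
#' @param beta probes x samples beta matrix.
#' @param annotation probe annotation table.
#' @param chrom chromosome name.
#' @param binsize bin width in bp, default 100000.
#' @param min_probes minimum probes per bin, default 3.
#' @return list: \code{means} (bins x samples matrix), \code{bins}
#'   (data.frame chrom/bin_start/bin_end/n_probes/masked).
#' @export
bin_methylation <- function(beta, annotation, chrom, binsize = 1e5,
                            min_probes = 3) {
  validate_probe_annotation(annotation)
  on_chrom <- annotation[annotation$chrom == chrom &
                           annotation$probe_class == "CpG" &
                           annotation$probe_id %in% rownames(beta), ]
  if (!nrow(on_chrom)) stop("no CpG probes on ", chrom)
  bin <- on_chrom$pos %/% binsize
  n_bins <- max(bin) + 1L
  bins <- data.frame(
    chrom = chrom,
    bin_start = (seq_len(n_bins) - 1L) * binsize,
    bin_end = seq_len(n_bins) * binsize,
    n_probes = as.integer(tabulate(bin + 1L, nbins = n_bins))
  )
  means <- matrix(NA_real_, n_bins, ncol(beta),
                  dimnames = list(NULL, colnames(beta)))
  for (b in unique(bin)) {
    probes <- on_chrom$probe_id[bin == b]
    if (length(probes) >= min_probes) {
      means[b + 1L, ] <- colMeans(beta[probes, , drop = FALSE], na.rm = TRUE)
    }
  }
  bins$masked <- bins$n_probes < min_probes
  list(means = means, bins = bins)
}

#' A/B compartment track from binned methylation
#'
#' Computes the Pearson correlation matrix between unmasked bins (across
#' samples) and takes its first eigenvector. The sign is oriented so that
#' the eigenvector correlates positively with per-bin probe density (open,
#' A-type chromatin is probe dense), then multiplied by -1 when \code{flip}
#' requests the plotting convention that shows open compartments in the
#' positive orientation. Bins are labelled A where the final loading is
#' positive and B where negative; masked bins propagate as \code{masked}.
#' Note the flip therefore swaps the A/B labels; recovery against a known
#' pattern should be read at \code{flip = FALSE}.
#'
#' @param binned output of [bin_methylation()].
#' @param flip apply the plotting sign convention, default TRUE.
#' @param min_bins minimum unmasked bins, default 10.
#' @return data.frame (class \code{"compartment_track"}): chrom, bin_start,
#'   bin_end, loading, compartment (A/B/masked), n_probes.
#' @export
compartment_eigenvector <- function(binned, flip = TRUE, min_bins = 10) {
  means <- binned$means
  bins <- binned$bins
  ok <- !bins$masked
  if (sum(ok) < min_bins) {
    stop("need at least ", min_bins, " unmasked bins")
  }
  if (ncol(means) < 3) stop("need at least 3 samples")
  m <- means[ok, , drop = FALSE]
  if (any(apply(m, 1, stats::sd) == 0)) {
    stop("degenerate binned matrix: constant bin(s)")
  }
  cc <- stats::cor(t(m))
  ev <- eigen(cc, symmetric = TRUE)
  v <- ev$vectors[, 1]
  dens <- bins$n_probes[ok]
  orient <- stats::cor(v, dens)
  if (!is.na(orient) && orient < 0) v <- -v
  if (flip) v <- -v
  loading <- rep(NA_real_, nrow(bins))
  loading[ok] <- v
  track <- data.frame(
    chrom = bins$chrom,
    bin_start = bins$bin_start,
    bin_end = bins$bin_end,
    loading = loading,
    compartment = ifelse(bins$masked, "masked",
                         ifelse(loading > 0, "A", "B")),
    n_probes = bins$n_probes,
    stringsAsFactors = FALSE
  )
  class(track) <- c("compartment_track", "data.frame")
  track
}
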