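# Internal numerical helpers shared across modules.

#' Clip beta values away from 0 and 1
#'
#' Beta values of exactly 0 or 1 have infinite M-values; before any logit
#' transform they are clipped into \code{[eps, 1 - eps]}. Clipping never moves
#' a value by more than \code{eps}.
#'
#' @param beta numeric vector or matrix of methylation fractions.
#' @param eps clipping margin, default \code{1e-3}.
#' @return object of the same shape with values in \code{[eps, 1 - eps]}.
#' @export
clip_beta <- function(beta, eps = 1e-3) {
  stopifnot(is.numeric(eps), eps > 0, eps < 0.5)
  beta[!is.na(beta) & beta < eps] <- eps
  beta[!is.na(beta) & beta > 1 - eps] <- 1 - eps
  beta
}

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)), the variance-stabilised scale used for
#' per-probe testing. Input is clipped first so the transform is finite.
#'
#' @inheritParams clip_beta
#' @return M-values, same shape as input.
#' @export
beta_to_m <- function(beta, eps = 1e-3) {
  b <- clip_beta(beta, eps)
  log2(b / (1 - b))
}

# Row-wise Welch two-sample t-test on a matrix, NA-aware.
# Returns mean difference (group1 - group2), t, df, p, and per-row group sizes.
# Rows with fewer than 2 non-missing values in either group get NA statistics.
row_welch <- function(x, idx1, idx2) {
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) + (v2 / n2)^2 / pmax(n2 - 1, 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  bad <- n1 < 2 | n2 < 2 | se2 == 0 | !is.finite(se2)
  tstat[bad] <- NA_real_
  df[bad] <- NA_real_
  p[bad] <- NA_real_
  list(diff = m1 - m2, t = tstat, df = df, p = p, n1 = n1, n2 = n2)
}

# Connected components of an undirected graph given as an edge list over
# integer vertex ids 1..n (union-find).
components_from_edges <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
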