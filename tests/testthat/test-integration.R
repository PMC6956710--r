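make_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

test_that("the CPM filter drops genes expressed in fewer than 3 samples", {
  # library size 1e6 per sample so counts are CPM directly
  base <- matrix(1e6 - 10, 1, 8)
  gene_lo <- c(5, 5, 0, 0, 0, 0, 0, 0)   # CPM >= 1 in exactly 2 samples
  gene_hi <- c(5, 5, 5, 0, 0, 0, 0, 0)   # in exactly 3
  counts <- make_counts(rbind(base, gene_lo, gene_hi),
                        genes = c("filler", "lo", "hi"))
  degs <- call_degs(counts, colnames(counts)[1:4], colnames(counts)[5:8])
  expect_false(degs$passed_filter[degs$gene_id == "lo"])
  expect_true(degs$passed_filter[degs$gene_id == "hi"])
  expect_false(degs$is_deg[degs$gene_id == "lo"])
})

test_that("zero library sizes are rejected", {
  counts <- make_counts(matrix(c(1, 2, 0, 0, 3, 1, 2, 2), 2, 4))
  expect_error(call_degs(counts, c("s01", "s02"), c("s03", "s04")),
               "zero library size.*s02")
})

test_that("DEG statistics agree with t-tests on log2 CPM and are antisymmetric", {
  set.seed(14)
  counts <- make_counts(matrix(rnbinom(50 * 8, mu = 200, size = 10), 50, 8))
  cases <- colnames(counts)[1:4]
  controls <- colnames(counts)[5:8]
  degs <- call_degs(counts, cases, controls)
  lcpm <- log2(cpm(counts) + 0.5)
  for (i in c(1, 25, 50)) {
    tt <- stats::t.test(lcpm[i, cases], lcpm[i, controls])
    expect_equal(degs$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(degs$log2fc[i],
                 mean(lcpm[i, cases]) - mean(lcpm[i, controls]))
  }
  rev <- call_degs(counts, controls, cases)
  expect_equal(degs$log2fc, -rev$log2fc)
  expect_equal(degs$p, rev$p, tolerance = 1e-12)
})

test_that("planted marker effects are recovered within tolerance", {
  co <- get_cohort()
  norm <- group_samples(co, "normal")
  degs <- call_degs(co$counts, group_samples(co, "HMGA2hi"), norm)
  expect_lt(abs(degs$log2fc[degs$gene_id == "HMGA2"] - 11.6), 1.0)
  expect_lt(abs(degs$log2fc[degs$gene_id == "HOXA13"] - 4.4), 0.5)
  expect_true(degs$is_deg[degs$gene_id == "HMGA2"])
  # silent planted genes mostly fail the CPM filter
  silent <- degs[degs$gene_id %in% co$truth$silent_genes, ]
  expect_gt(mean(!silent$passed_filter), 0.9)
})

test_that("false discovery proportion among null genes is controlled", {
  fdps <- vapply(1:6, function(s) {
    co <- simulate_cohort(paper_profile(), seed = 500 + s)
    tr <- co$truth
    non_null <- c(tr$marker_log2fc$gene, tr$coupled_genes$gene)
    degs <- call_degs(co$counts, group_samples(co, "MED12mt"),
                      group_samples(co, "normal"))
    hits <- degs$gene_id[degs$is_deg]
    if (!length(hits)) return(0)
    mean(!hits %in% non_null)
  }, numeric(1))
  expect_lte(mean(fdps), 0.075)   # BH target 0.05 plus simulation error
})

test_that("starburst categories follow the joint thresholds and partition genes", {
  dmc <- data.frame(
    probe_id = c("pA", "pB", "pC", "pD"),
    delta_beta = c(0.30, 0.20, -0.40, 0.30),
    p = c(0.01, 0.001, 0.001, 0.5),
    q = c(0.02, 0.01, 0.01, 0.6),
    direction = c("hyper", "hyper", "hypo", "hyper"),
    is_dmc = c(TRUE, FALSE, TRUE, FALSE),
    testable = TRUE, stringsAsFactors = FALSE
  )
  degs <- data.frame(
    gene_id = c("GA", "GB", "GC", "GD"),
    log2fc = c(-2, -2, 3, -2),
    p = 0.001, q = 0.001,
    passed_filter = TRUE, is_deg = TRUE, stringsAsFactors = FALSE
  )
  pm <- data.frame(
    probe_id = c("pA", "pB", "pC", "pD"),
    region = "promoter",
    gene = c("GA", "GB", "GC", "GD"),
    in_tfbs_universe = FALSE, stringsAsFactors = FALSE
  )
  sb <- starburst(dmc, degs, pm)
  got <- stats::setNames(sb$category, sb$gene_id)
  expect_identical(got[["GA"]], "hyper_down")
  expect_identical(got[["GB"]], "other")       # delta 0.20 below 0.25
  expect_identical(got[["GC"]], "hypo_up")
  expect_identical(got[["GD"]], "other")       # methylation p not significant
  expect_equal(anyDuplicated(sb$gene_id), 0)   # categories partition genes
})

test_that("planted promoter-silenced genes are recovered as hyper_down", {
  co <- get_cohort()
  norm <- group_samples(co, "normal")
  fib <- names(co$truth$group)[co$truth$group != "normal"]
  dmc <- call_dmcs(co$beta, fib, norm)
  degs <- call_degs(co$counts, fib, norm)
  pm <- map_probes_to_promoters(co$annotation)
  sb <- starburst(dmc, degs, pm)
  coupled <- sb[sb$gene_id %in% co$truth$coupled_genes$gene, ]
  expect_gte(nrow(coupled), 0.9 * nrow(co$truth$coupled_genes))
  expect_gte(mean(coupled$category == "hyper_down"), 0.9)
})

test_that("overlap chi-square matches the closed form and the identity case", {
  make_deg <- function(universe, deg_up) {
    data.frame(gene_id = universe,
               log2fc = ifelse(universe %in% deg_up, 2, 0.1),
               p = 0.001, q = ifelse(universe %in% deg_up, 0.001, 0.9),
               passed_filter = TRUE,
               is_deg = universe %in% deg_up, stringsAsFactors = FALSE)
  }
  # exact independence expectation: universe 100, |A| = 20, |B| = 50, overlap 10
  u <- sprintf("g%03d", 1:100)
  a <- make_deg(u, c(u[1:10], u[51:60]))
  b <- make_deg(u, u[1:50])
  res <- overlap_test(a, b)
  expect_equal(res$up$chisq, 0, tolerance = 1e-12)
  expect_length(res$up$overlap_genes, 10)
  # closed form: universe 1000, |A| = |B| = 100, overlap 50
  u2 <- sprintf("h%04d", 1:1000)
  a2 <- make_deg(u2, c(u2[1:50], u2[101:150]))
  b2 <- make_deg(u2, u2[1:100])
  res2 <- overlap_test(a2, b2)
  expect_equal(res2$up$chisq,
               1000 * (50 * 850 - 50 * 50)^2 / (100 * 900 * 100 * 900),
               tolerance = 1e-10)
})

test_that("chi-square equals the closed form on random 2x2 tables", {
  set.seed(15)
  for (rep in 1:25) {
    tab <- matrix(as.numeric(sample(5:200, 4, replace = TRUE)), 2, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    ch <- stats::chisq.test(tab, correct = FALSE)
    expect_equal(unname(ch$statistic), closed, tolerance = 1e-10)
  }
})

test_that("a planted shared expression program yields significant directional overlap", {
  co <- get_cohort()
  norm <- group_samples(co, "normal")
  deg_a <- call_degs(co$counts, group_samples(co, "MED12mt"), norm)
  deg_b <- call_degs(co$counts, group_samples(co, "HMGA2hi"), norm)
  res <- overlap_test(deg_a, deg_b)
  expect_lt(res$up$p, 0.001)
  expect_lt(res$down$p, 0.001)
  # the planted coupled genes drive the shared down-program
  expect_gt(length(intersect(res$down$overlap_genes,
                             co$truth$coupled_genes$gene)), 0)
})

test_that("correlation identities and a Monte-Carlo bivariate check hold", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_genes(NULL, x, 2 * x + 1, method = "pearson")$estimate, 1)
  expect_equal(correlate_genes(NULL, x, rev(x), method = "kendall")$estimate, -1)
  expect_error(correlate_genes(NULL, x, rep(1, 5)), "zero-variance")
  expect_error(correlate_genes(NULL, 1:2, 2:1), "at least 3")
  set.seed(16)
  rho <- 0.6
  ests <- vapply(1:200, function(i) {
    z <- rnorm(30)
    x <- z + rnorm(30, sd = sqrt(1 / rho^2 - 1))
    correlate_genes(NULL, x, z, method = "pearson")$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - rho), 0.1)
})
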