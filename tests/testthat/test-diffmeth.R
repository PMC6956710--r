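test_that("a forced 0.1-vs-0.7 contrast is called hyper-DMC and 0.15 delta is not", {
  set.seed(5)
  jitter <- function(mu) pmin(pmax(rnorm(4, mu, 0.01), 0), 1)
  beta <- toy_beta(rbind(
    c(jitter(0.70), jitter(0.10)),   # strong hyper in cases
    c(jitter(0.55), jitter(0.40))    # delta 0.15, below the 0.2 rule
  ), probes = c("strong", "weak"))
  cases <- colnames(beta)[1:4]
  controls <- colnames(beta)[5:8]
  dmc <- call_dmcs(beta, cases, controls)
  strong <- dmc[dmc$probe_id == "strong", ]
  expect_true(strong$is_dmc)
  expect_identical(strong$direction, "hyper")
  expect_equal(strong$delta_beta, 0.6, tolerance = 0.05)
  weak <- dmc[dmc$probe_id == "weak", ]
  expect_false(weak$is_dmc)   # |delta| < 0.2 regardless of p
})

test_that("DMC statistics agree with per-probe Welch t-tests on M-values", {
  set.seed(6)
  beta <- toy_beta(matrix(runif(30 * 10, 0.05, 0.95), 30, 10))
  beta[2, 3] <- NA
  cases <- colnames(beta)[1:5]
  controls <- colnames(beta)[6:10]
  dmc <- call_dmcs(beta, cases, controls)
  m <- beta_to_m(beta)
  for (i in c(1, 2, 15, 30)) {
    tt <- stats::t.test(m[i, cases], m[i, controls])
    expect_equal(dmc$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(dmc$delta_beta[i],
                 mean(beta[i, cases], na.rm = TRUE) -
                   mean(beta[i, controls], na.rm = TRUE))
  }
})

test_that("swapping case and control groups negates delta and preserves p", {
  set.seed(8)
  beta <- toy_beta(matrix(runif(20 * 8, 0.1, 0.9), 20, 8))
  a <- call_dmcs(beta, colnames(beta)[1:4], colnames(beta)[5:8])
  b <- call_dmcs(beta, colnames(beta)[5:8], colnames(beta)[1:4])
  expect_equal(a$delta_beta, -b$delta_beta)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("probes with fewer than two unmasked values per group are untestable", {
  beta <- toy_beta(matrix(runif(2 * 6, 0.2, 0.8), 2, 6))
  beta[1, 1:3] <- NA   # one unmasked case left
  dmc <- call_dmcs(beta, colnames(beta)[1:4], colnames(beta)[5:6])
  expect_false(dmc$testable[1])
  expect_true(is.na(dmc$p[1]))
  expect_false(dmc$is_dmc[1])
  expect_true(dmc$testable[2])
})

test_that("fibroid-specific probes require all-normal-unmethylated and one methylated tumour", {
  beta <- toy_beta(rbind(
    c(0.05, 0.05, 0.05, 0.35, 0.10, 0.10),   # in: one tumour at 0.35
    c(0.05, 0.05, 0.05, 0.29, 0.10, 0.10),   # out: tumour max 0.29 < 0.3
    c(0.05, 0.25, 0.05, 0.80, 0.80, 0.80)    # out: one normal above 0.2
  ), probes = c("in1", "out_low", "out_normal"))
  normals <- colnames(beta)[1:3]
  tumours <- colnames(beta)[4:6]
  got <- subtype_specific_probes(beta, normals, tumours)
  expect_identical(got, "in1")
  # boundary: beta exactly 0.3 counts as methylated ("no less than 0.3")
  beta["out_low", 4] <- 0.3
  expect_setequal(subtype_specific_probes(beta, normals, tumours),
                  c("in1", "out_low"))
})

test_that("probes map to promoter or distal space by the 2 kb TSS window", {
  ann <- toy_annotation(c("a", "b", "c", "d"),
                        gene = c("G1", "G2", NA, NA),
                        tss_distance = c(1500L, -2500L, 50000L, NA),
                        tfbs = c("", "", "EZH2", ""))
  pm <- map_probes_to_promoters(ann)
  expect_identical(pm$region, c("promoter", "distal", "distal", "distal"))
  expect_identical(pm$gene[1], "G1")
  expect_identical(pm$in_tfbs_universe, c(FALSE, FALSE, TRUE, FALSE))
  # boundary: exactly 2000 bp is still promoter
  ann2 <- toy_annotation("e", tss_distance = 2000L)
  expect_identical(map_probes_to_promoters(ann2)$region, "promoter")
})

test_that("hypergeometric tails match the worked combinatorial examples", {
  ann <- toy_annotation(sprintf("u%03d", 1:100), tss_distance = 50000L,
                        tfbs = c(rep("TFX", 20), rep("TFOTHER", 80)))
  universe <- ann$probe_id
  # k = 0 of n = 10 drawn hit the K = 20 TF set
  res0 <- tfbs_enrichment(ann$probe_id[21:30], ann, universe = universe)
  tfx0 <- res0[res0$tf == "TFX", ]
  expect_equal(tfx0$p_enrich, 1)
  expect_equal(tfx0$p_deplete, choose(80, 10) / choose(100, 10))
  # k = 8 of n = 10
  res8 <- tfbs_enrichment(ann$probe_id[c(1:8, 21:22)], ann, universe = universe)
  tfx8 <- res8[res8$tf == "TFX", ]
  exact <- sum(sapply(8:10, function(i) {
    choose(20, i) * choose(80, 10 - i)
  })) / choose(100, 10)
  expect_equal(tfx8$p_enrich, exact, tolerance = 1e-12)
})

test_that("hypergeometric tails equal exhaustive enumeration for N <= 30", {
  set.seed(13)
  enum_tail <- function(N, K, n, k, upper) {
    is <- 0:min(K, n)
    probs <- choose(K, is) * choose(N - K, n - is) / choose(N, n)
    if (upper) sum(probs[is >= k]) else sum(probs[is <= k])
  }
  for (rep in 1:40) {
    N <- sample(5:30, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 enum_tail(N, K, n, k, upper = TRUE), tolerance = 1e-10)
    expect_equal(stats::phyper(k, K, N - K, n),
                 enum_tail(N, K, n, k, upper = FALSE), tolerance = 1e-10)
    # the two tails share the P(X = k) term
    expect_gte(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE) +
                 stats::phyper(k, K, N - K, n), 1)
  }
})

test_that("the planted TF is called enriched and unplanted TFs are neither", {
  co <- get_cohort()
  norm <- group_samples(co, "normal")
  fib <- names(co$truth$group)[co$truth$group != "normal"]
  dmc <- call_dmcs(co$beta, fib, norm)
  en <- tfbs_enrichment(dmc$probe_id[dmc$is_dmc], co$annotation)
  planted <- en[en$tf == co$truth$planted_tf, ]
  expect_identical(planted$call, "enriched")
  expect_lte(planted$q_enrich, 1e-6)
  expect_true(all(en$call[en$tf != co$truth$planted_tf] == "neither"))
  # invariant: k <= min(K, n)
  expect_true(all(en$overlap <= pmin(en$tf_set_size, en$dmc_count)))
})
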