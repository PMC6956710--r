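test_that("variable-probe selection returns ceiling(fraction * P) probes by SD", {
  co <- get_cohort()
  vp <- select_variable_probes(co$beta, co$annotation, fraction = 0.01)
  expect_length(vp, 200)   # ceiling(0.01 * 20000) CpG probes
  # independent SD ranking as oracle
  cpg <- co$annotation$probe_id[co$annotation$probe_class == "CpG"]
  sds <- apply(co$beta[cpg, ], 1, stats::sd)
  oracle <- names(sort(sds, decreasing = TRUE))[1:200]
  expect_gte(length(intersect(vp, oracle)), 198)  # ties may swap the tail
  # planted informative probes dominate the top 1%
  expect_gte(sum(co$truth$informative_probes$probe_id %in% vp), 140)
})

test_that("variable-probe ties fall back to lexicographic order with a warning", {
  beta <- toy_beta(matrix(0.5, 120, 4),
                   probes = sprintf("cg%03d", sample(120)))
  expect_warning(vp <- select_variable_probes(beta, fraction = 0.05),
                 "tie")
  expect_identical(vp, sort(rownames(beta))[1:6])
})

test_that("masked cells are excluded from the SD ranking", {
  set.seed(3)
  beta <- toy_beta(matrix(runif(120 * 6), 120, 6))
  beta[1, 1:3] <- NA
  vp <- select_variable_probes(beta, fraction = 0.1)
  sds <- apply(beta, 1, stats::sd, na.rm = TRUE)
  expect_identical(sort(vp), sort(names(sort(sds, decreasing = TRUE))[1:12]))
})

test_that("hierarchical clustering recovers well-separated groups", {
  set.seed(7)
  g1 <- matrix(rnorm(50 * 5, 0.2, 0.01), 50, 5)
  g2 <- matrix(rnorm(50 * 5, 0.8, 0.01), 50, 5)
  beta <- toy_beta(pmin(pmax(cbind(g1, g2), 0), 1))
  res <- hier_cluster(beta, k = 2)
  expect_identical(unname(res$assignments[1:5]), rep(res$assignments[[1]], 5))
  expect_true(all(res$assignments[6:10] != res$assignments[1]))
  # brute-force check: flat cut equals the partition minimising
  # between-group distance for two blobs
  expect_equal(length(unique(res$assignments)), 2L)
  # duplicated sample merges at height zero
  dup <- beta[, c(1, 1, 6)]
  colnames(dup) <- c("a", "a2", "b")
  hc <- hier_cluster(dup)$hclust
  expect_equal(min(hc$height), 0)
  expect_error(hier_cluster(beta, k = 11), "k exceeds")
})

test_that("fibroid samples split into three subtype clades", {
  co <- get_cohort()
  vp <- select_variable_probes(co$beta, co$annotation)
  res <- hier_cluster(co$beta[vp, ], k = 4)
  fib <- res$assignments[group_samples(co, "MED12mt") |>
                           c(group_samples(co, "HMGA2hi"),
                             group_samples(co, "HMGA1hi"))]
  clades <- table(fib)
  expect_length(clades, 3)
  expect_true(all(clades >= 2))
})

test_that("consensus separates two clean groups and is seed-deterministic", {
  set.seed(9)
  g1 <- matrix(rnorm(40 * 6, 0.2, 0.02), 40, 6)
  g2 <- matrix(rnorm(40 * 6, 0.8, 0.02), 40, 6)
  beta <- toy_beta(pmin(pmax(cbind(g1, g2), 0), 1))
  res <- consensus_cluster(beta, k = 2, iterations = 200, seed = 4)
  within <- c(res$consensus[1:6, 1:6][upper.tri(diag(6))],
              res$consensus[7:12, 7:12][upper.tri(diag(6))])
  between <- res$consensus[1:6, 7:12]
  expect_gte(min(within), 0.95)
  expect_lte(max(between), 0.05)
  # matrix is a valid co-clustering fraction table
  expect_identical(res$consensus, t(res$consensus))
  expect_true(all(res$consensus >= 0 & res$consensus <= 1, na.rm = TRUE))
  expect_equal(unname(diag(res$consensus)), rep(1, 12))
  res2 <- consensus_cluster(beta, k = 2, iterations = 200, seed = 4)
  expect_identical(res$consensus, res2$consensus)
})

test_that("stability scores match the stated averaging rule", {
  cm <- matrix(c(1, 0.8, 0.2,
                 0.8, 1, 0.4,
                 0.2, 0.4, 1), 3, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  cl <- c(s1 = 1, s2 = 1, s3 = 2)
  st <- stability_scores(list(consensus = cm, assignments = cl))
  expect_equal(st$sample_stability["s1", "cluster1"], 0.8)
  expect_equal(st$sample_stability["s3", "cluster1"], 0.3)
  expect_equal(unname(st$cluster_stability["cluster1"]), 0.8)
  # singleton cluster: defined as 1 and flagged
  expect_equal(st$sample_stability["s3", "cluster2"], 1)
  expect_true(st$singleton_flags[["cluster2"]])
  # all-ones consensus, one cluster
  ones <- matrix(1, 3, 3, dimnames = dimnames(cm))
  st1 <- stability_scores(list(consensus = ones,
                               assignments = c(s1 = 1, s2 = 1, s3 = 1)))
  expect_equal(unname(st1$cluster_stability), 1)
})

test_that("stability scores equal brute-force averaging on random matrices", {
  set.seed(12)
  for (rep in 1:20) {
    n <- 6
    cm <- matrix(runif(n * n), n, n)
    cm <- (cm + t(cm)) / 2
    diag(cm) <- 1
    dimnames(cm) <- list(letters[1:n], letters[1:n])
    cl <- stats::setNames(sample(1:3, n, replace = TRUE), letters[1:n])
    st <- stability_scores(list(consensus = cm, assignments = cl))
    for (s in letters[1:n]) {
      for (k in sort(unique(cl))) {
        members <- setdiff(names(cl)[cl == k], s)
        brute <- if (length(members)) mean(cm[s, members]) else 1
        expect_equal(st$sample_stability[s, paste0("cluster", k)], brute)
      }
    }
  }
})

test_that("consensus clustering recovers planted subtypes across generator seeds", {
  # moderate iteration count here; the full-protocol run lives in the
  # acceptance suite
  aris <- vapply(1:8, function(s) {
    co <- simulate_cohort(paper_profile(), seed = 300 + s)
    vp <- select_variable_probes(co$beta, co$annotation)
    res <- consensus_cluster(co$beta[vp, ], k = 4, iterations = 100,
                             seed = s)
    adjusted_rand_index(res$assignments, co$truth$group)
  }, numeric(1))
  expect_gte(stats::median(aris), 0.9)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (rep in 1:10) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 1, 4, 5, 3)), 1)
})

test_that("subtype rules apply with MED12 > HMGA2 > HMGA1 precedence", {
  expect_identical(classify_subtype(TRUE, c(HMGA1 = 100, HMGA2 = 100)),
                   "MED12mt")
  expect_identical(classify_subtype(TRUE), "MED12mt")
  expect_identical(classify_subtype(FALSE, c(HMGA1 = 3, HMGA2 = 6)),
                   "HMGA2hi")
  expect_identical(classify_subtype(FALSE, c(HMGA1 = 3, HMGA2 = 4)),
                   "HMGA1hi")
  expect_identical(classify_subtype(FALSE, c(HMGA1 = 1.5, HMGA2 = 1.2)),
                   "unclassified")
  # thresholds are strict inequalities
  expect_identical(classify_subtype(FALSE, c(HMGA1 = 2, HMGA2 = 5)),
                   "unclassified")
  expect_error(classify_subtype(FALSE, c(HMGA1 = 3)), "classification error")
  expect_error(classify_subtype(FALSE), "classification error")
})
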