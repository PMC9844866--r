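test_that("nmf recovers an exact rank-1 matrix and validates its inputs", {
  set.seed(1)
  X <- outer(runif(20, 0.5, 2), runif(10, 0.5, 2))
  fit <- nmf(X, k = 1, seed = 4)
  expect_lt(fit$reconstruction_error, 1e-8)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))

  expect_error(nmf(matrix(c(-1, 1, 2, 3), 2), k = 1), "negative")
  expect_error(nmf(abs(matrix(rnorm(40), 8, 5)), k = 5), "k must")
})

test_that("the nmf objective is monotone non-increasing", {
  set.seed(2)
  X <- matrix(runif(200, 0.1, 2), 20, 10)
  fit <- nmf(X, k = 3, seed = 7, max_iter = 200)
  expect_true(all(diff(fit$error_trace) <= 1e-10 * fit$error_trace[1]))
})

test_that("a rank-2 fit beats the rank-1 fit on 2-block data", {
  set.seed(3)
  W0 <- cbind(c(runif(10, 1, 2), runif(10, 0, 0.1)),
              c(runif(10, 0, 0.1), runif(10, 1, 2)))
  H0 <- cbind(matrix(runif(12, 1, 2), 2) * c(1, 0.05),
              matrix(runif(12, 1, 2), 2) * c(0.05, 1))
  X <- W0 %*% H0
  e2 <- nmf(X, k = 2, seed = 1)$reconstruction_error
  e1 <- nmf(X, k = 1, seed = 1)$reconstruction_error
  expect_lte(e2, e1)
})

test_that("consensus entries reflect co-clustering structure", {
  set.seed(4)
  X <- matrix(runif(60, 0.5, 1.5), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  X[, 2] <- X[, 1]  # identical columns must always co-cluster
  C <- consensus_matrix(X, k = 2, n_runs = 5, seed = 1)
  expect_equal(C[1, 2], 1)
  expect_equal(diag(C), rep(1, 10), ignore_attr = TRUE)
  expect_lt(max(abs(C - t(C))), 1e-12)
  expect_true(all(C >= 0 & C <= 1))

  expect_error(consensus_matrix(X, k = 2, n_runs = 1), "n_runs")
})

test_that("planted two-block structure is recovered from the consensus", {
  co <- generate_cohort(cohort_config(n_samples = 60, n_genes = 120,
                                      n_informative = 20, effect_size = 3,
                                      seed = 8))
  C <- consensus_matrix(co$expression, k = 2, n_runs = 30, seed = 2)
  within <- outer(co$true_subtype, co$true_subtype, "==")
  diag(within) <- NA
  expect_gt(mean(C[which(within)]), mean(C[which(!within)]))

  labels <- cluster_from_consensus(C, 2)
  expect_equal(adjusted_rand_index(labels, co$true_subtype), 1)

  # true labels score a higher silhouette than a random permutation
  set.seed(9)
  perm <- sample(labels)
  expect_gt(asw(C, labels), asw(C, perm))
})

test_that("consensus clustering handles block and degenerate inputs", {
  C <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  C[1:3, 1:3] <- 1
  C[4:6, 4:6] <- 1
  labels <- cluster_from_consensus(C, 2)
  expect_identical(unname(labels), rep(c(1L, 2L), each = 3))
  expect_equal(asw(C, labels), 1)
  expect_equal(cophenetic_correlation(C), 1, tolerance = 1e-12)

  ones <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_error(cluster_from_consensus(ones, 2), "distinct rows")
  expect_error(asw(C, rep(1, 6)), "single cluster")
  expect_error(cophenetic_correlation(ones), "constant")
})

test_that("deterministic relabelling assigns cluster 1 to the first sample", {
  C <- matrix(0, 5, 5, dimnames = list(paste0("s", 1:5), paste0("s", 1:5)))
  C[c(1, 4), c(1, 4)] <- 1  # first sample sits in the smaller block
  C[c(2, 3, 5), c(2, 3, 5)] <- 1
  labels <- cluster_from_consensus(C, 2)
  expect_identical(unname(labels), c(1L, 2L, 2L, 1L, 2L))
})

test_that("cophenetic correlation matches a hand-worked 3-sample linkage", {
  C <- matrix(c(1, 0.8, 0.4,
                0.8, 1, 0.2,
                0.4, 0.2, 1), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  # average linkage by hand: merge {1,2} at 0.2; {12}-{3} at mean(0.6, 0.8)
  d <- c(0.2, 0.6, 0.8)
  coph <- c(0.2, 0.7, 0.7)
  expect_equal(cophenetic_correlation(C), cor(d, coph), tolerance = 1e-12)

  # i.i.d. noise consensus scores below clean block structure
  set.seed(10)
  M <- matrix(runif(100, 0.2, 0.8), 10, 10)
  noise <- (M + t(M)) / 2
  diag(noise) <- 1
  dimnames(noise) <- list(paste0("s", 1:10), paste0("s", 1:10))
  block <- matrix(0, 10, 10, dimnames = dimnames(noise))
  block[1:5, 1:5] <- 1
  block[6:10, 6:10] <- 1
  expect_lt(cophenetic_correlation(noise), cophenetic_correlation(block))
})

test_that("adjusted Rand index agrees with the mclust implementation", {
  set.seed(11)
  for (i in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:2, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10 %% 2, (1:10 %% 2)[c(1:10)]), 1)
})
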