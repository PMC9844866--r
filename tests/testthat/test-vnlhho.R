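test_that("the sigmoid transfer gives the closed-form selection rates", {
  set.seed(1)
  draws <- replicate(10000, binarize(c(1, 0.8, 0.5), transfer_slope = 10))
  freq <- rowMeans(draws)
  probs <- plogis(10 * (c(1, 0.8, 0.5) - 0.5))  # 0.9933, 0.9526, 0.5
  se <- sqrt(probs * (1 - probs) / 10000)
  expect_true(all(abs(freq - probs) < 3 * pmax(se, 1e-4)))
})

test_that("fitness combines CV error and sparsity; empty masks are +Inf", {
  # one perfectly separating gene among 100
  fx <- make_two_group_matrix(n_genes = 100, n_per_group = 20, n_sep = 1,
                              delta = 10)
  cfg <- vnlhho_config(seed = 1)
  mask <- c(TRUE, rep(FALSE, 99))
  set.seed(5)
  f <- evaluate_fitness(mask, fx$X, fx$labels, cfg)
  expect_equal(f, 0.01 * 1 / 100, tolerance = 1e-12)

  expect_identical(evaluate_fitness(rep(FALSE, 100), fx$X, fx$labels, cfg),
                   Inf)

  # planted-informative mask beats the all-genes mask
  co <- generate_cohort(cohort_config(n_samples = 60, n_genes = 80,
                                      n_informative = 10, seed = 6))
  truth <- rownames(co$expression) %in% co$true_informative_genes
  set.seed(7)
  folds <- pcascore:::stratified_folds(factor(co$true_subtype), 5)
  f_truth <- evaluate_fitness(truth, co$expression, co$true_subtype, cfg,
                              folds = folds)
  f_full <- evaluate_fitness(rep(TRUE, 80), co$expression, co$true_subtype,
                             cfg, folds = folds)
  expect_lt(f_truth, f_full)
})

test_that("hawk positions stay in the unit cube and the rabbit is monotone", {
  set.seed(8)
  G <- 15
  cfg <- vnlhho_config(pop_size = 6, max_iter = 20, seed = 1)
  target <- c(rep(TRUE, 3), rep(FALSE, G - 3))
  fitfun <- function(mask) sum(xor(mask, target)) / G  # Hamming toy fitness
  pop <- list(positions = matrix(runif(6 * G), 6, G),
              masks = matrix(FALSE, 6, G), fitness = numeric(6))
  for (i in 1:6) {
    pop$masks[i, ] <- binarize(pop$positions[i, ], cfg$transfer_slope)
    pop$fitness[i] <- fitfun(pop$masks[i, ])
  }
  b <- which.min(pop$fitness)
  rabbit <- list(position = pop$positions[b, ], mask = pop$masks[b, ],
                 fitness = pop$fitness[b])
  prev <- rabbit$fitness
  for (t in 1:20) {
    step <- pcascore:::hho_iteration(pop, rabbit, t, 20, cfg, fitfun)
    step <- pcascore:::vnl_step(step$pop, step$rabbit, 2L, cfg, fitfun)
    pop <- step$pop
    rabbit <- step$rabbit
    expect_true(all(pop$positions >= 0 & pop$positions <= 1))
    expect_lte(rabbit$fitness, prev)
    prev <- rabbit$fitness
  }
  expect_identical(rabbit$mask, target)  # toy optimum reached
})

test_that("the VNL move shifts chosen coordinates toward the best neighbour", {
  set.seed(9)
  G <- 10
  cfg <- vnlhho_config(pop_size = 4, max_iter = 5, seed = 1)
  pop <- list(positions = matrix(runif(4 * G), 4, G),
              masks = matrix(runif(4 * G) > 0.5, 4, G),
              fitness = c(5, 0.1, 7, 9))  # hawk 2 is the ring-wide best
  rabbit <- list(position = pop$positions[2, ], mask = pop$masks[2, ],
                 fitness = 0.1)
  old <- pop$positions
  step <- pcascore:::vnl_step(pop, rabbit, 3L, cfg,
                              fitfun = function(m) 0)  # always accepted
  for (i in c(1, 3, 4)) {
    xn <- as.numeric(pop$masks[2, ])
    newx <- step$pop$positions[i, ]
    moved <- which(newx != old[i, ])
    expect_lte(length(moved), G %/% 2)
    # moved coordinates lie between the old value and the neighbour target
    lo <- pmin(old[i, moved], xn[moved])
    hi <- pmax(old[i, moved], xn[moved])
    expect_true(all(newx[moved] >= lo - 1e-12 & newx[moved] <= hi + 1e-12))
  }
})

test_that("select_features is reproducible and its history non-increasing", {
  co <- generate_cohort(cohort_config(n_samples = 40, n_genes = 12,
                                      n_informative = 3, seed = 10))
  cfg <- vnlhho_config(pop_size = 8, max_iter = 15, seed = 42)
  a <- select_features(co$expression, co$true_subtype, cfg)
  b <- select_features(co$expression, co$true_subtype, cfg)
  expect_identical(a$selected_genes, b$selected_genes)
  expect_identical(a$fitness_history, b$fitness_history)
  expect_true(all(diff(a$fitness_history) <= 0))
  expect_gt(length(a$selected_genes), 0)
  expect_identical(a$best_fitness,
                   evaluate_fitness(a$best_mask, co$expression,
                                    co$true_subtype, cfg, folds = a$folds))

  expect_error(select_features(co$expression, rep(1, 40), cfg),
               "two groups")
})

test_that("the selector finds the exhaustive optimum on a 2-gene toy", {
  set.seed(12)
  n <- 30
  lab <- rep(1:2, each = n / 2)
  X <- rbind(info = c(rnorm(n / 2), rnorm(n / 2, 4)),
             noise = rnorm(n))
  colnames(X) <- paste0("s", 1:n)
  hits <- 0
  for (s in 1:10) {
    cfg <- vnlhho_config(pop_size = 6, max_iter = 20, seed = s)
    res <- select_features(X, lab, cfg)
    best <- exhaustive_best_fitness(X, lab, cfg, res$folds)
    hits <- hits + isTRUE(all.equal(res$best_fitness, best))
  }
  expect_gte(hits, 9)
})

test_that("shuffled labels yield a small selected set near the base rate", {
  co <- generate_cohort(cohort_config(n_samples = 60, n_genes = 60,
                                      n_informative = 10, seed = 13))
  set.seed(14)
  null_labels <- sample(co$true_subtype)
  res <- select_features(co$expression, null_labels,
                         vnlhho_config(seed = 3))
  expect_lt(length(res$selected_genes), 30)  # sparsity term dominates
  # no real signal: the cross-validated error stays far from zero
  err <- (res$best_fitness -
            0.01 * length(res$selected_genes) / 60) / 0.99
  expect_gt(err, 0.05)
})
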