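test_that("Kaplan-Meier handles hand-worked and degenerate inputs", {
  km <- km_curve(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(0.5, 0))
  expect_equal(km$median, 1)

  all_cens <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_length(all_cens$event_times, 0)
  expect_true(is.na(all_cens$median))

  expect_error(km_curve(numeric(0), numeric(0)), "non-empty")
  expect_error(km_curve(c(1, -1), c(1, 1)), "positive")
})

test_that("without censoring the KM curve equals one minus the ECDF", {
  dat <- make_surv_data(n = 200, cens_rate = 0, seed = 31)
  km <- km_curve(dat$times, dat$events)
  emp <- 1 - ecdf(dat$times)(km$event_times)
  expect_equal(km$survival, emp)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(diff(km$at_risk) <= 0))
})

test_that("log-rank matches the hand-computed 4-sample table", {
  # group A: times 1,2 both events; group B: times 3,4 both events
  # event-time tables give O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6)
  expect_equal(lr$chi_square, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-12)
  expect_equal(lr$chi_square, 49 / 17, tolerance = 1e-12)
})

test_that("log-rank on duplicated groups is exactly null and label-invariant", {
  dat <- make_surv_data(n = 40, cens_rate = 0.2, seed = 32)
  times <- rep(dat$times, 2)
  events <- rep(dat$events, 2)
  grp <- rep(c("x", "y"), each = 40)
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)

  lr_a <- logrank_test(dat$times, dat$events, dat$x)
  lr_b <- logrank_test(dat$times, dat$events, 1 - dat$x)
  expect_equal(lr_a$chi_square, lr_b$chi_square, tolerance = 1e-12)
  expect_gte(lr_a$chi_square, 0)

  expect_error(logrank_test(c(1, 2), c(0, 0), c(1, 2)), "no events")
})

test_that("log-rank agrees with survival::survdiff on censored data", {
  for (s in 1:4) {
    dat <- make_surv_data(n = 80, log_hr = 0.6, cens_rate = 0.25, seed = s)
    tt <- round(dat$times, 1) + 0.1  # force ties
    lr <- logrank_test(tt, dat$events, dat$x)
    ref <- survival::survdiff(survival::Surv(tt, dat$events) ~ dat$x)
    expect_equal(lr$chi_square, unname(ref$chisq), tolerance = 1e-9)
  }
})

test_that("Cox fit reproduces coxph with Efron ties", {
  set.seed(33)
  n <- 150
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
  tt <- round(rexp(n, 0.3 * exp(0.6 * X[, 1] - 0.4 * X[, 2])), 1) + 0.1
  ev <- rbinom(n, 1, 0.75)
  fit <- cox_fit(tt, ev, X)
  ref <- survival::coxph(survival::Surv(tt, ev) ~ X, ties = "efron")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$coefficients$hazard_ratio,
               exp(fit$coefficients$coef))
  expect_true(all(fit$coefficients$ci_low <= fit$coefficients$hazard_ratio &
                  fit$coefficients$hazard_ratio <= fit$coefficients$ci_high))
})

test_that("Cox null covariates stay within three standard errors", {
  set.seed(34)
  n <- 500
  x <- rnorm(n)
  tt <- rexp(n, 0.3)
  ev <- rbinom(n, 1, 0.8)
  fit <- cox_fit(tt, ev, cbind(x = x))
  expect_lt(abs(fit$coefficients$coef[1]), 3 * fit$coefficients$se[1])

  expect_error(cox_fit(tt, ev, cbind(k = rep(1, n))), "constant")
})

test_that("the prognostic screen keeps risk genes and drops null genes", {
  included <- 0
  for (s in 1:10) {
    co <- generate_cohort(cohort_config(n_samples = 300, n_genes = 30,
                                        n_informative = 8,
                                        log_hazard_ratio = 1, seed = s))
    # strongest planted gene: highest |standardized shift|
    gene <- co$true_informative_genes[1]
    hit <- gene %in% prognostic_screen(co$expression, co$clinical,
                                       genes = gene, alpha = 0.001)
    included <- included + hit
  }
  expect_gte(included, 9)

  co <- generate_cohort(cohort_config(n_samples = 200, n_genes = 40,
                                      n_informative = 5, seed = 99))
  null_genes <- setdiff(rownames(co$expression),
                        co$true_informative_genes)[1:20]
  passed <- prognostic_screen(co$expression, co$clinical,
                              genes = null_genes, alpha = 0.001)
  expect_lte(length(passed), 1)
})

test_that("time-dependent AUC reduces to Mann-Whitney without censoring", {
  set.seed(35)
  n <- 80
  times <- rexp(n, 0.4)
  events <- rep(1, n)
  score <- -times + rnorm(n, sd = 0.5)
  h <- median(times)
  case <- times <= h
  # independent enumeration of the Mann-Whitney statistic
  cmp <- outer(score[case], score[!case],
               function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(td_auc(score, times, events, h), mean(cmp), tolerance = 1e-12)
})

test_that("time-dependent AUC is calibrated under the null and informative", {
  set.seed(36)
  n <- 500
  times <- rexp(n, 0.3)
  events <- rbinom(n, 1, 0.8)
  auc_null <- td_auc(rnorm(n), times, events, median(times))
  expect_lt(abs(auc_null - 0.5), 0.08)  # ~3 SEs for this n

  co <- generate_cohort(cohort_config(n_samples = 300, n_genes = 60,
                                      n_informative = 15,
                                      log_hazard_ratio = 1.5, seed = 37))
  auc <- td_auc(co$true_risk, co$clinical$os_years, co$clinical$os_event,
                median(co$clinical$os_years))
  expect_gt(auc, 0.75)

  expect_error(td_auc(rnorm(3), c(5, 6, 7), c(1, 1, 1), 1), "case")
})

test_that("concordance matches brute-force pair enumeration", {
  # perfect concordance
  tt <- c(5, 4, 3, 2, 1)
  expect_equal(c_index(-tt, tt, rep(1, 5)), 1)

  set.seed(38)
  times <- c(2, 5, 3, 3.5, 1)
  events <- c(1, 0, 1, 1, 0)
  score <- rnorm(5)
  conc <- 0; npairs <- 0
  for (i in 1:5) for (j in 1:5) {
    if (times[i] < times[j] && events[i] == 1) {
      npairs <- npairs + 1
      conc <- conc + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
  }
  expect_equal(c_index(score, times, events), conc / npairs)

  expect_error(c_index(1:3, c(1, 1, 1), c(0, 0, 0)), "usable pairs")
})

test_that("concordance agrees with survival::concordance on untied data", {
  set.seed(39)
  n <- 60
  times <- rexp(n)
  events <- rbinom(n, 1, 0.7)
  score <- rnorm(n)
  ref <- survival::concordance(survival::Surv(times, events) ~ score,
                               reverse = TRUE)$concordance
  expect_equal(c_index(score, times, events), ref, tolerance = 1e-12)
})
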