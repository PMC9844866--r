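test_that("cohort generation is deterministic and satisfies its invariants", {
  cfg <- cohort_config(n_samples = 60, n_genes = 100, n_informative = 10,
                       seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  expect_identical(colnames(a$expression), a$clinical$sample_id)
  expect_identical(colnames(a$expression), names(a$true_subtype))
  expect_length(a$true_informative_genes, 10)
  expect_true(all(a$clinical$os_event %in% c(0, 1)))
  expect_true(all(a$clinical$os_years > 0))
  expect_false(anyNA(a$expression))
  expect_setequal(unique(a$true_subtype), c(1L, 2L))
})

test_that("zero censoring rate gives events for every sample", {
  co <- generate_cohort(cohort_config(n_samples = 50, n_genes = 20,
                                      n_informative = 5, censoring_rate = 0,
                                      seed = 11))
  expect_true(all(co$clinical$os_event == 1))
})

test_that("informative genes carry the planted shift", {
  co <- generate_cohort(cohort_config(seed = 1))  # n=120, 500 genes, 20 inf
  X <- co$expression
  g2 <- co$true_subtype == 2
  diffs <- rowMeans(X[, g2]) - rowMeans(X[, !g2])
  sds <- apply(X, 1, sd)
  std_diff <- abs(diffs) / sds
  top20 <- rownames(X)[order(std_diff, decreasing = TRUE)[1:20]]
  expect_setequal(top20, co$true_informative_genes)

  # average planted shift ~ effect_size * noise_sd within 3 SEs
  inf <- co$true_informative_genes
  se <- 1 * sqrt(1 / sum(g2) + 1 / sum(!g2)) / sqrt(length(inf))
  expect_lt(abs(mean(diffs[inf]) - 2), 3 * se)
})

test_that("higher latent risk means earlier observed events", {
  co <- generate_cohort(cohort_config(n_samples = 300, n_genes = 50,
                                      n_informative = 10,
                                      log_hazard_ratio = 1, seed = 5))
  unc <- co$clinical$os_event == 1
  tau <- cor(co$true_risk[unc], co$clinical$os_years[unc],
             method = "kendall")
  expect_lt(tau, 0)
})

test_that("invalid configurations are rejected with the violated bound named", {
  expect_error(cohort_config(n_informative = 30, n_genes = 20),
               "n_informative")
  expect_error(cohort_config(subtype_proportion = 1), "subtype_proportion")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(covariate_flip_prob = 0.5),
               "covariate_flip_prob")
})

test_that("write/read round-trip is lossless and mismatches are reported", {
  co <- generate_cohort(cohort_config(n_samples = 15, n_genes = 12,
                                      n_informative = 3, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$expression, co$expression)
  expect_equal(back$clinical, co$clinical)
  expect_identical(back$true_informative_genes, co$true_informative_genes)
  expect_equal(back$true_risk, co$true_risk)

  # drop one sample from the clinical file: the error must name it
  clin <- read.delim(file.path(dir, "clinical.tsv"), check.names = FALSE)
  write.table(clin[-4, ], file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(dir), clin$sample_id[4])

  expect_error(read_cohort(file.path(dir, "nope")), "missing input file")
})

test_that("a hand-written expression file parses to its literal cells", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_id\tsA\tsB",
               "gX\t1.25\t-0.5",
               "gY\t0\t3.75",
               "gZ\t2.125\t7"),
             file.path(dir, "expression.tsv"))
  writeLines(c("sample_id\tos_years\tos_event",
               "sA\t1.5\t1",
               "sB\t2.5\t0"),
             file.path(dir, "clinical.tsv"))
  co <- read_cohort(dir)
  expect_identical(dim(co$expression), c(3L, 2L))
  expect_equal(co$expression["gX", "sA"], 1.25)
  expect_equal(co$expression["gX", "sB"], -0.5)
  expect_equal(co$expression["gY", "sB"], 3.75)
  expect_equal(co$expression["gZ", "sA"], 2.125)
  expect_equal(co$clinical$os_years, c(1.5, 2.5))
})
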