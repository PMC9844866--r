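#' Moderated two-group t-test for log2 expression
#'
#' Per-gene pooled-variance t-tests with empirical-Bayes moderation: the
#' gene-wise variances are shrunk toward a scaled inverse-chi-square (inverse
#' gamma) prior fitted to all genes by moment matching on the log variances,
#' and the residual degrees of freedom are augmented by the estimated prior
#' degrees of freedom. Log2 fold change is the second-group mean minus the
#' first-group mean (factor level order).
#'
#' @param X log2 expression matrix, genes x samples.
#' @param labels two-group factor/vector over samples; each group needs >= 2
#'   samples.
#' @param prior_df optional override of the prior degrees of freedom: `NULL`
#'   (default) estimates it from the data, `0` disables moderation (ordinary
#'   pooled t-test), `Inf` shrinks fully to the prior variance.
#' @return `data.frame` with one row per gene: `gene_id`, `log2FC`, `t_stat`,
#'   `p_value`, `fdr` (Benjamini--Hochberg), `zero_variance` flag. Genes with
#'   no variance information at all are flagged and reported with `p = 1`.
#'   Attributes `prior_df` and `prior_var` expose the fitted prior.
#' @export
moderated_t_test <- function(X, labels, prior_df = NULL) {
  check_expression(X)
  f <- check_two_groups(labels, ncol(X), min_per_group = 2L)
  g1 <- f == levels(f)[1]
  g2 <- f == levels(f)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  df <- n1 + n2 - 2

  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, g2, drop = FALSE])
  lfc <- m2 - m1
  v1 <- rowSums((X[, g1, drop = FALSE] - m1)^2)
  v2 <- rowSums((X[, g2, drop = FALSE] - m2)^2)
  s2 <- (v1 + v2) / df

  if (is.null(prior_df)) {
    prior <- fit_inv_chisq_prior(s2[s2 > 0], df)
  } else if (prior_df == 0) {
    prior <- list(df = 0, var = 0)
  } else {
    prior <- list(df = prior_df,
                  var = if (any(s2 > 0)) mean(s2[s2 > 0]) else 0)
  }
  d0 <- prior$df
  s02 <- prior$var
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  df_total <- df + d0

  zero <- s2_post <= 0
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(zero, 0, lfc / ifelse(se == 0, 1, se))
  p <- ifelse(zero, 1, 2 * stats::pt(-abs(t_stat), df = df_total))
  out <- data.frame(gene_id = rownames(X),
                    log2FC = lfc,
                    t_stat = t_stat,
                    p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    zero_variance = s2 == 0,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  attr(out, "residual_df") <- df
  out
}

# Moment-matching fit of the scaled inverse-chi-square prior on gene variances
# (inverse-gamma on sigma^2): matches the mean and variance of log(s^2) using
# digamma/trigamma identities for the log of a scaled chi-square.
fit_inv_chisq_prior <- function(s2, df) {
  if (length(s2) < 2L) return(list(df = 0, var = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(df = d0, var = s02)
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone, convex).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Filter a differential-expression table on effect size and p-value
#'
#' Keeps genes with `|log2FC| >= lfc_min` (inclusive) and `p_value < p_max`
#' (strict), mirroring the usual reporting convention, and returns their ids
#' ordered by ascending p-value.
#'
#' @param table output of [moderated_t_test()].
#' @param lfc_min minimum absolute log2 fold change (kept when equal).
#' @param p_max p-value bound (dropped when equal).
#' @return Character vector of gene ids (possibly empty).
#' @export
filter_degs <- function(table, lfc_min = 0.5, p_max = 0.05) {
  stopifnot(is.data.frame(table),
            all(c("gene_id", "log2FC", "p_value") %in% names(table)))
  if (nrow(table) == 0L) stop("differential-expression table is empty",
                              call. = FALSE)
  keep <- abs(table$log2FC) >= lfc_min & table$p_value < p_max
  kept <- table[keep, , drop = FALSE]
  kept$gene_id[order(kept$p_value)]
}
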