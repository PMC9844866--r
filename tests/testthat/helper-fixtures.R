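# Small in-code fixtures shared across tests.

# Two-group expression matrix with `n_sep` perfectly separated genes
# (group means -delta/+delta) and the rest pure noise.
make_two_group_matrix <- function(n_genes = 20, n_per_group = 10, n_sep = 2,
                                  delta = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_group
  lab <- rep(1:2, each = n_per_group)
  X <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  if (n_sep > 0) {
    X[seq_len(n_sep), lab == 2] <- X[seq_len(n_sep), lab == 2] + delta
  }
  list(X = X, labels = lab)
}

# Exponential survival data with an optional binary covariate effect.
make_surv_data <- function(n = 100, log_hr = 0, cens_rate = 0.2, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate = 0.3 * exp(log_hr * x))
  t_c <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  list(times = pmin(t_ev, t_c), events = as.integer(t_ev <= t_c), x = x)
}

# Exhaustive search over all non-empty masks of a small gene set, using the
# same fixed folds as a select_features() run.
exhaustive_best_fitness <- function(X, labels, config, folds) {
  G <- nrow(X)
  best <- Inf
  for (code in seq_len(2^G - 1)) {
    m <- as.logical(bitwAnd(code, 2^(seq_len(G) - 1)))
    fv <- evaluate_fitness(m, X, labels, config, folds = folds)
    if (fv < best) best <- fv
  }
  best
}
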