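#' Configuration for the VNLHHO gene selector
#'
#' Parameters of the binary Harris Hawks optimizer with variable-neighbourhood
#' learning used for wrapper feature selection over candidate genes.
#'
#' @param pop_size number of hawks N (>= 4).
#' @param max_iter number of iterations T.
#' @param fitness_alpha weight of the cross-validated classification error in
#'   the fitness, in (0, 1\]; `1 - fitness_alpha` weights the selected-gene
#'   fraction (sparsity).
#' @param cv_folds stratified cross-validation folds of the wrapper.
#' @param knn_k neighbours of the k-NN wrapper classifier.
#' @param transfer_slope slope of the sigmoid transfer function mapping a
#'   continuous position coordinate to a selection probability.
#' @param levy_beta Levy-flight exponent in (1, 2\] (Mantegna algorithm).
#' @param vnl_k_max maximum ring-neighbourhood radius of the learning step.
#' @param stagnation_limit iterations without global improvement before the
#'   neighbourhood radius grows.
#' @param seed integer seed; a run is fully reproducible from it.
#' @return An object of class `vnlhho_config`.
#' @export
vnlhho_config <- function(pop_size = 30L, max_iter = 100L,
                          fitness_alpha = 0.99, cv_folds = 5L, knn_k = 5L,
                          transfer_slope = 10, levy_beta = 1.5,
                          vnl_k_max = 3L, stagnation_limit = 5L, seed = 1L) {
  bad <- function(msg) stop("invalid VNLHHO configuration: ", msg,
                            call. = FALSE)
  if (pop_size < 4) bad("pop_size must be >= 4")
  if (max_iter < 1) bad("max_iter must be >= 1")
  if (fitness_alpha <= 0 || fitness_alpha > 1) {
    bad("fitness_alpha must lie in (0, 1]")
  }
  if (cv_folds < 2) bad("cv_folds must be >= 2")
  if (knn_k < 1) bad("knn_k must be >= 1")
  if (transfer_slope <= 0) bad("transfer_slope must be positive")
  if (levy_beta <= 1 || levy_beta > 2) bad("levy_beta must lie in (1, 2]")
  if (vnl_k_max < 1) bad("vnl_k_max must be >= 1")
  if (stagnation_limit < 1) bad("stagnation_limit must be >= 1")
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 fitness_alpha = fitness_alpha,
                 cv_folds = as.integer(cv_folds),
                 knn_k = as.integer(knn_k),
                 transfer_slope = transfer_slope,
                 levy_beta = levy_beta,
                 vnl_k_max = as.integer(vnl_k_max),
                 stagnation_limit = as.integer(stagnation_limit),
                 seed = as.integer(seed)),
            class = "vnlhho_config")
}

# Stratified fold assignment: within each class, samples are dealt into folds
# in random order so fold class proportions match the data.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# k-NN cross-validated error on the masked, standardized submatrix.
# Z: samples x genes (already z-scored); folds fixed for the whole run so the
# fitness is a deterministic function of the mask.
knn_cv_error <- function(Z, y, mask, folds, kk) {
  Zm <- Z[, mask, drop = FALSE]
  a <- rowSums(Zm * Zm)
  D <- outer(a, a, "+") - 2 * tcrossprod(Zm)
  yi <- as.integer(y)
  n_err <- 0L
  for (f in sort(unique(folds))) {
    test <- which(folds == f)
    train <- which(folds != f)
    k_use <- min(kk, length(train))
    for (i in test) {
      nn <- train[order(D[i, train])[seq_len(k_use)]]
      vote <- tabulate(yi[nn], nbins = 2L)
      pred <- which.max(vote)  # tie -> lower class index, deterministic
      if (pred != yi[i]) n_err <- n_err + 1L
    }
  }
  n_err / length(y)
}

#' Wrapper fitness of a gene mask
#'
#' `fitness = alpha * err + (1 - alpha) * |mask| / G`, where `err` is the
#' stratified `cv_folds`-fold cross-validated error of a `knn_k`-nearest-
#' neighbour classifier (Euclidean distance on z-scored genes) restricted to
#' the masked genes. Lower is better; the empty mask scores `+Inf` so it can
#' never be selected as the best solution.
#'
#' @param mask logical or 0/1 vector over genes.
#' @param X expression matrix, genes x samples.
#' @param labels two-group labels over samples.
#' @param config a [vnlhho_config()].
#' @param folds optional fixed fold assignment (integer per sample). When
#'   omitted, folds are drawn from the current RNG stream — inside an optimizer
#'   run they are drawn once so every mask sees identical folds.
#' @return Numeric fitness (lower is better).
#' @export
evaluate_fitness <- function(mask, X, labels, config = vnlhho_config(),
                             folds = NULL) {
  mask <- as.logical(mask)
  if (length(mask) != nrow(X)) {
    stop("mask length must equal the number of genes", call. = FALSE)
  }
  if (!any(mask)) return(Inf)
  f <- check_two_groups(labels, ncol(X))
  Z <- standardize_samples_by_gene(X)
  if (is.null(folds)) folds <- stratified_folds(f, config$cv_folds)
  err <- knn_cv_error(Z, f, mask, folds, config$knn_k)
  config$fitness_alpha * err +
    (1 - config$fitness_alpha) * sum(mask) / length(mask)
}

# samples x genes z-scored matrix; zero-variance genes become all-zero columns.
standardize_samples_by_gene <- function(X) {
  Z <- t(X)
  mu <- colMeans(Z)
  sd_ <- apply(Z, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  sweep(sweep(Z, 2, mu, "-"), 2, sd_, "/")
}

#' Binarize a continuous hawk position
#'
#' Gene `g` is selected iff `u_g < S(position_g)` with the sigmoid transfer
#' `S(v) = 1 / (1 + exp(-slope * (v - 0.5)))` and `u_g ~ Uniform(0, 1)` drawn
#' from the current RNG stream.
#'
#' @param position numeric vector in \[0, 1\].
#' @param transfer_slope sigmoid slope.
#' @return Logical mask of the same length.
#' @export
binarize <- function(position, transfer_slope = 10) {
  stats::runif(length(position)) <
    stats::plogis(transfer_slope * (position - 0.5))
}

# Mantegna Levy-flight step with exponent beta.
levy_step <- function(n, beta) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(n) * sigma_u
  v <- stats::rnorm(n)
  u / abs(v)^(1 / beta)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# One Harris Hawks iteration over the population (canonical phase equations).
# `pop` is a list with $positions (N x G), $masks (N x G logical),
# $fitness (N); `rabbit` holds the best-ever position/mask/fitness.
# `fitfun(mask)` must be deterministic within the run.
# Escaping energy E = 2*E0*(1 - t/t_max) switches exploration (|E| >= 1) to
# the besiege/dive exploitation phases (|E| < 1).
#
# The prey location in the exploitation phases is the rabbit's realized
# binary solution (its mask, a corner of [0,1]^G), not its continuous
# position: besieging a corner drives positions toward 0/1, so the late
# phase becomes a stochastic local search around the best-known gene subset.
# Besieging the interior position instead leaves the selection probabilities
# stuck mid-range and the search cannot accumulate gene-identity information.
hho_iteration <- function(pop, rabbit, t, t_max, config, fitfun) {
  N <- nrow(pop$positions)
  G <- ncol(pop$positions)
  decay <- 1 - t / t_max
  prey <- as.numeric(rabbit$mask)
  for (i in seq_len(N)) {
    x <- pop$positions[i, ]
    E0 <- stats::runif(1, -1, 1)
    E <- 2 * E0 * decay
    dived <- FALSE
    if (abs(E) >= 1) {                      # exploration
      q <- stats::runif(1)
      if (q >= 0.5) {
        xr <- pop$positions[sample.int(N, 1L), ]
        x_new <- xr - stats::runif(1) * abs(xr - 2 * stats::runif(1) * x)
      } else {
        xm <- colMeans(pop$positions)
        x_new <- (prey - xm) -
          stats::runif(1) * (0 + stats::runif(1) * (1 - 0))  # LB=0, UB=1
      }
    } else {                                # exploitation
      r <- stats::runif(1)
      J <- 2 * (1 - stats::runif(1))
      if (r >= 0.5 && abs(E) >= 0.5) {      # soft besiege
        x_new <- (prey - x) - E * abs(J * prey - x)
      } else if (r >= 0.5) {                # hard besiege
        x_new <- prey - E * abs(prey - x)
      } else {                              # progressive rapid dives
        dived <- TRUE
        base <- if (abs(E) >= 0.5) x else colMeans(pop$positions)
        Y <- clip01(prey - E * abs(J * prey - base))
        mY <- binarize(Y, config$transfer_slope)
        fY <- fitfun(mY)
        if (fY < pop$fitness[i]) {
          pop$positions[i, ] <- Y
          pop$masks[i, ] <- mY
          pop$fitness[i] <- fY
        } else {
          Z <- clip01(Y + stats::runif(G) * levy_step(G, config$levy_beta))
          mZ <- binarize(Z, config$transfer_slope)
          fZ <- fitfun(mZ)
          if (fZ < pop$fitness[i]) {
            pop$positions[i, ] <- Z
            pop$masks[i, ] <- mZ
            pop$fitness[i] <- fZ
          }
        }
      }
    }
    if (!dived) {
      # greedy (elitist) acceptance with plateau drift: a move is kept when
      # it does not worsen the hawk. Strict improvement preserves population
      # diversity (no collapse onto the rabbit); accepting ties lets hawks
      # random-walk across equal-fitness plateaus instead of freezing.
      x_new <- clip01(x_new)
      m_new <- binarize(x_new, config$transfer_slope)
      f_new <- fitfun(m_new)
      if (f_new <= pop$fitness[i]) {
        pop$positions[i, ] <- x_new
        pop$masks[i, ] <- m_new
        pop$fitness[i] <- f_new
      }
    }
    if (pop$fitness[i] < rabbit$fitness) {
      rabbit <- list(position = pop$positions[i, ],
                     mask = pop$masks[i, ],
                     fitness = pop$fitness[i])
    }
  }
  list(pop = pop, rabbit = rabbit)
}

# Variable-neighbourhood learning step: hawks sit on a ring by index; each
# moves a random half of its coordinates toward the best hawk within +/- k
# ring positions (x <- x + u * (x_nbest - x), u ~ U(0,1) per coordinate).
# As in the besiege phases, the neighbour is represented by its realized
# binary solution, so learning pulls coordinates toward corners.
vnl_step <- function(pop, rabbit, k, config, fitfun) {
  N <- nrow(pop$positions)
  G <- ncol(pop$positions)
  old_masks <- pop$masks
  old_fitness <- pop$fitness
  for (i in seq_len(N)) {
    nbr <- unique(((i - 1 + c(-k:-1, 1:k)) %% N) + 1L)
    nbr <- setdiff(nbr, i)
    if (length(nbr) == 0L) next
    nb <- nbr[which.min(old_fitness[nbr])]
    xn <- as.numeric(old_masks[nb, ])
    x <- pop$positions[i, ]
    move <- sample.int(G, max(1L, G %/% 2L))
    u <- stats::runif(G)
    x[move] <- x[move] + u[move] * (xn[move] - x[move])
    x <- clip01(x)
    m <- binarize(x, config$transfer_slope)
    fv <- fitfun(m)
    if (fv <= pop$fitness[i]) {     # greedy acceptance, as in the HHO phase
      pop$positions[i, ] <- x
      pop$masks[i, ] <- m
      pop$fitness[i] <- fv
    }
    if (fv < rabbit$fitness) {
      rabbit <- list(position = x, mask = m, fitness = fv)
    }
  }
  list(pop = pop, rabbit = rabbit)
}

#' Select characteristic genes with the VNLHHO wrapper
#'
#' Initializes `pop_size` hawks uniformly in `[0, 1]^G`, alternates Harris
#' Hawks iterations with the variable-neighbourhood learning step for
#' `max_iter` iterations, and returns the best-ever gene mask under the
#' k-NN/sparsity wrapper fitness. The cross-validation folds are drawn once at
#' the start of the run, so fitness is a deterministic function of the mask
#' and the best-so-far fitness is monotone non-increasing. The whole run is
#' reproducible from `config$seed`.
#'
#' The neighbourhood radius starts at 1, grows by 1 (up to `vnl_k_max`) after
#' `stagnation_limit` iterations without global improvement, and resets to 1
#' on improvement.
#'
#' @param X expression matrix, genes x samples (candidate genes only, e.g.
#'   the differentially expressed set).
#' @param labels two-group labels over samples; each group needs at least
#'   `cv_folds` samples.
#' @param config a [vnlhho_config()].
#' @return A list of class `vnlhho_result`: `selected_genes` (character, in
#'   input gene order), `best_mask` (logical), `best_fitness`,
#'   `fitness_history` (length `max_iter`, non-increasing), `n_evaluations`,
#'   `folds` (the fold assignment used, enabling exact refitting of any mask's
#'   fitness), `config_echo`.
#' @export
select_features <- function(X, labels, config = vnlhho_config()) {
  check_expression(X)
  if (nrow(X) < 2L) stop("need at least 2 candidate genes", call. = FALSE)
  f <- check_two_groups(labels, ncol(X), min_per_group = config$cv_folds)
  G <- nrow(X)
  N <- config$pop_size
  Tm <- config$max_iter

  with_seed(config$seed, {
    Z <- standardize_samples_by_gene(X)
    folds <- stratified_folds(f, config$cv_folds)
    n_eval <- 0L
    fitfun <- function(mask) {
      if (!any(mask)) return(Inf)
      n_eval <<- n_eval + 1L
      config$fitness_alpha * knn_cv_error(Z, f, mask, folds, config$knn_k) +
        (1 - config$fitness_alpha) * sum(mask) / G
    }

    positions <- matrix(stats::runif(N * G), N, G)
    masks <- matrix(FALSE, N, G)
    fitness <- numeric(N)
    for (i in seq_len(N)) {
      masks[i, ] <- binarize(positions[i, ], config$transfer_slope)
      fitness[i] <- fitfun(masks[i, ])
    }
    pop <- list(positions = positions, masks = masks, fitness = fitness)
    best <- which.min(pop$fitness)
    rabbit <- list(position = pop$positions[best, ],
                   mask = pop$masks[best, ],
                   fitness = pop$fitness[best])

    history <- numeric(Tm)
    k_nbhd <- 1L
    stagnant <- 0L
    for (t in seq_len(Tm)) {
      prev_best <- rabbit$fitness
      step <- hho_iteration(pop, rabbit, t, Tm, config, fitfun)
      step <- vnl_step(step$pop, step$rabbit, k_nbhd, config, fitfun)
      pop <- step$pop
      rabbit <- step$rabbit
      history[t] <- rabbit$fitness
      if (rabbit$fitness < prev_best) {
        k_nbhd <- 1L
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= config$stagnation_limit) {
          k_nbhd <- min(k_nbhd + 1L, config$vnl_k_max)
          stagnant <- 0L
        }
      }
    }

    structure(list(selected_genes = rownames(X)[rabbit$mask],
                   best_mask = rabbit$mask,
                   best_fitness = rabbit$fitness,
                   fitness_history = history,
                   n_evaluations = n_eval,
                   folds = folds,
                   config_echo = config),
              class = "vnlhho_result")
  })
}

#' @export
print.vnlhho_result <- function(x, ...) {
  cat(sprintf("VNLHHO selection: %d genes, best fitness %.6f (%d evaluations)\n",
              length(x$selected_genes), x$best_fitness, x$n_evaluations))
  invisible(x)
}
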