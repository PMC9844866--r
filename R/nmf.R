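#' Non-negative matrix factorization by multiplicative updates
#'
#' Lee--Seung multiplicative updates minimizing the squared Frobenius error
#' `||X - W H||_F^2`, with random non-negative initialization drawn from
#' `seed`. The objective is non-increasing across iterations; iteration stops
#' when the relative error improvement drops below `tol` or at `max_iter`.
#'
#' @param X non-negative numeric matrix (genes x samples).
#' @param k factorization rank, `1 <= k < min(dim(X))`.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative-improvement stopping tolerance.
#' @return A list of class `nmf_result`: `W` (genes x k), `H` (k x samples),
#'   `reconstruction_error` (squared Frobenius, final), `error_trace`
#'   (per-iteration), `n_iter`, `converged`.
#' @export
#' @examples
#' w <- runif(20); h <- runif(10)
#' fit <- nmf(outer(w, h), k = 1, seed = 1)
#' fit$reconstruction_error  # ~ 0: exact rank-1 recovery
nmf <- function(X, k, seed = 1L, max_iter = 500L, tol = 1e-6) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("X must be a numeric matrix", call. = FALSE)
  }
  if (any(X < 0)) stop("X must have no negative entries", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k >= min(dim(X))) {
    stop(sprintf("k must satisfy 1 <= k < min(dim(X)) = %d", min(dim(X))),
         call. = FALSE)
  }
  eps <- .Machine$double.eps
  with_seed(seed, {
    scl <- sqrt(max(mean(X), eps) / k)
    W <- matrix(stats::runif(nrow(X) * k, min = eps, max = scl), nrow(X), k)
    H <- matrix(stats::runif(k * ncol(X), min = eps, max = scl), k, ncol(X))
    err <- numeric(max_iter)
    prev <- sum((X - W %*% H)^2)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
      W <- W * (X %*% t(H) / (W %*% tcrossprod(H) + eps))
      e <- sum((X - W %*% H)^2)
      err[it] <- e
      if (prev > 0 && (prev - e) / prev < tol) {
        converged <- TRUE
        break
      }
      prev <- e
    }
    structure(list(W = W, H = H,
                   reconstruction_error = err[it],
                   error_trace = err[seq_len(it)],
                   n_iter = it, converged = converged),
              class = "nmf_result")
  })
}

# Cluster assignment for one NMF run: W columns are L2-normalized with the
# scale moved into H (the factorization is only defined up to diagonal
# rescaling), then each sample goes to the factor with the largest H entry;
# ties break toward the lower factor index.
nmf_assign <- function(fit) {
  nrm <- sqrt(colSums(fit$W^2))
  nrm[nrm == 0] <- 1
  Hs <- fit$H * nrm
  max.col(t(Hs), ties.method = "first")
}

#' Consensus matrix from repeated NMF clustering
#'
#' Runs [nmf()] `n_runs` times with seeds `seed + r`, assigns each sample to
#' the dominant factor of each run, and records the fraction of runs in which
#' each sample pair co-clusters. Input with negative entries (log-scale
#' expression) is shifted by its global minimum first, which preserves all
#' between-sample contrasts.
#'
#' @param X numeric matrix (genes x samples); may contain negative values.
#' @param k number of clusters (NMF rank).
#' @param n_runs number of restarts (>= 2).
#' @param seed master seed; run `r` uses `seed + r`.
#' @param max_iter,tol forwarded to [nmf()].
#' @return Symmetric samples x samples matrix with entries in \[0, 1\] and unit
#'   diagonal, carrying sample dimnames.
#' @export
consensus_matrix <- function(X, k, n_runs = 30L, seed = 1L,
                             max_iter = 500L, tol = 1e-6) {
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  if (min(X) < 0) X <- X - min(X)
  n <- ncol(X)
  C <- matrix(0, n, n)
  for (r in seq_len(n_runs)) {
    fit <- nmf(X, k, seed = derive_seed(seed, r),
               max_iter = max_iter, tol = tol)
    cl <- nmf_assign(fit)
    C <- C + outer(cl, cl, "==")
  }
  C <- C / n_runs
  dimnames(C) <- list(colnames(X), colnames(X))
  C
}

check_consensus <- function(consensus) {
  if (!is.matrix(consensus) || nrow(consensus) != ncol(consensus)) {
    stop("consensus must be a square matrix", call. = FALSE)
  }
  if (max(abs(consensus - t(consensus))) > 1e-12) {
    stop("consensus matrix must be symmetric", call. = FALSE)
  }
  if (any(consensus < -1e-12) || any(consensus > 1 + 1e-12)) {
    stop("consensus entries must lie in [0, 1]", call. = FALSE)
  }
  invisible(consensus)
}

#' Cluster samples from a consensus matrix
#'
#' Agglomerative clustering with average linkage on the dissimilarity
#' `1 - consensus`, cut at `k` clusters. Labels are relabelled
#' deterministically: cluster 1 is the cluster of the first-occurring sample,
#' cluster 2 the next new cluster encountered, and so on.
#'
#' @param consensus symmetric co-clustering matrix in \[0, 1\].
#' @param k number of clusters.
#' @return Integer vector of labels in `1..k`, named by sample.
#' @export
cluster_from_consensus <- function(consensus, k) {
  check_consensus(consensus)
  k <- as.integer(k)
  n_distinct <- nrow(unique(round(consensus, 12)))
  if (k > n_distinct) {
    stop(sprintf(
      "cannot cut %d clusters: consensus has only %d distinct rows (degenerate structure)",
      k, n_distinct), call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  raw <- stats::cutree(hc, k = k)
  relabel <- match(raw, unique(raw))
  stats::setNames(as.integer(relabel), rownames(consensus))
}

#' Average silhouette width on consensus dissimilarity
#'
#' Standard silhouette widths computed on the dissimilarity `1 - consensus`
#' and averaged over samples; the clustering-consistency diagnostic reported
#' alongside consensus NMF subtypes. Singleton clusters contribute silhouette
#' 0 (the usual convention).
#'
#' @param consensus symmetric co-clustering matrix in \[0, 1\].
#' @param labels cluster labels covering at least two non-empty clusters.
#' @return Average silhouette width in \[-1, 1\].
#' @export
asw <- function(consensus, labels) {
  check_consensus(consensus)
  n <- nrow(consensus)
  if (length(labels) != n) stop("labels length must match consensus dimension",
                                call. = FALSE)
  f <- factor(labels)
  if (nlevels(f) < 2L) {
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  }
  D <- 1 - consensus
  s <- numeric(n)
  idx <- split(seq_len(n), f)
  for (i in seq_len(n)) {
    own <- f[i]
    mine <- setdiff(idx[[own]], i)
    if (length(mine) == 0L) { s[i] <- 0; next }  # singleton
    a <- mean(D[i, mine])
    b <- min(vapply(idx[setdiff(levels(f), own)],
                    function(j) mean(D[i, j]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the consensus dissimilarities `1 - consensus`
#' and the cophenetic distances of their average-linkage dendrogram; values
#' near 1 indicate stable, tree-like co-clustering.
#'
#' @param consensus symmetric co-clustering matrix in \[0, 1\].
#' @return Correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(consensus) {
  check_consensus(consensus)
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) {
    stop("cophenetic correlation undefined for a constant consensus matrix",
         call. = FALSE)
  }
  hc <- stats::hclust(d, method = "average")
  stats::cor(d, stats::cophenetic(hc))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples;
#' 1 means identical partitions (up to label permutation), ~0 random.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length",
                                   call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
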