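#' Fit the principal-component risk score on a signature-gene submatrix
#'
#' Genes are z-scored across samples and the sample covariance of the
#' standardized genes is eigen-decomposed; the first two components are
#' retained. Each loading vector is oriented deterministically so that its
#' largest-absolute-value entry is positive, making the fit reproducible
#' despite the sign indeterminacy of PCA. The per-sample score is the sum of
#' the PC1 and PC2 projections.
#'
#' @param X expression matrix restricted to the signature genes (genes x
#'   samples); at least 2 genes, 3 samples, and no zero-variance gene.
#' @return Object of class `score_model`: `signature_genes`, `means`, `sds`
#'   (training standardization parameters), `loadings` (genes x 2 orthonormal
#'   matrix), `explained_variance` (two fractions), `sign_convention` (the
#'   +/-1 flips applied), `degenerate_pc2` flag (second eigenvalue ~ 0),
#'   `cutpoint` (unset until assigned), `risk_direction` (one of
#'   `"high_score_high_risk"`, `"high_score_low_risk"`, `"unknown"`).
#' @export
fit_score <- function(X) {
  check_expression(X)
  if (nrow(X) < 2L) stop("need at least 2 signature genes", call. = FALSE)
  if (ncol(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance signature gene(s): ",
         paste(rownames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  means <- rowMeans(X)
  Z <- t((X - means) / sds)                 # samples x genes, z-scored
  S <- stats::cov(Z)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  loadings <- eig$vectors[, 1:2, drop = FALSE]
  sign_convention <- integer(2)
  for (j in 1:2) {
    top <- which.max(abs(loadings[, j]))
    sign_convention[j] <- if (loadings[top, j] < 0) -1L else 1L
    loadings[, j] <- loadings[, j] * sign_convention[j]
  }
  dimnames(loadings) <- list(rownames(X), c("PC1", "PC2"))
  structure(list(signature_genes = rownames(X),
                 means = means,
                 sds = sds,
                 loadings = loadings,
                 explained_variance = ev[1:2] / sum(ev),
                 sign_convention = sign_convention,
                 degenerate_pc2 = ev[2] <= 1e-12 * max(ev[1], 1),
                 cutpoint = NULL,
                 risk_direction = "unknown"),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("PCA score model: %d genes; PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
              length(x$signature_genes),
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  if (!is.null(x$cutpoint)) {
    cat(sprintf("  cutpoint = %.4f (%s)\n", x$cutpoint, x$risk_direction))
  }
  invisible(x)
}

#' Score samples with a fitted PCA score model
#'
#' Standardizes the signature genes with the training means and standard
#' deviations (never refit) and projects onto the stored loadings; the score
#' of a sample is its PC1 projection plus its PC2 projection. Applying the
#' model to its own training matrix reproduces the training scores exactly.
#'
#' @param model a [fit_score()] model.
#' @param X expression matrix containing all signature genes (extra genes are
#'   ignored); missing signature genes raise an error listing them.
#' @return `data.frame` with `sample_id`, `pc1`, `pc2`,
#'   `pca_score = pc1 + pc2`, and `stratum` (`NA` until [stratify()]).
#' @export
apply_score <- function(model, X) {
  stopifnot(inherits(model, "score_model"))
  check_expression(X)
  missing_genes <- setdiff(model$signature_genes, rownames(X))
  if (length(missing_genes)) {
    stop("signature genes missing from the matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  Xs <- X[model$signature_genes, , drop = FALSE]
  Z <- t((Xs - model$means) / model$sds)
  P <- Z %*% model$loadings
  data.frame(sample_id = colnames(X),
             pc1 = P[, 1],
             pc2 = P[, 2],
             pca_score = P[, 1] + P[, 2],
             stratum = NA_character_,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Assign low/high risk strata from the model cutpoint
#'
#' A sample is `high` iff its score strictly exceeds the cutpoint (a score
#' exactly at the cutpoint is `low`). The model's `risk_direction`, learned
#' from training survival, records which stratum carries the worse prognosis.
#'
#' @param scores output of [apply_score()].
#' @param model a `score_model` whose `cutpoint` has been set (see
#'   [set_cutpoint()]).
#' @return `scores` with the `stratum` column filled (factor low/high).
#' @export
stratify <- function(scores, model) {
  stopifnot(inherits(model, "score_model"))
  if (is.null(model$cutpoint)) {
    stop("model cutpoint is unset; derive one with max_rank_cutpoint() and set_cutpoint()",
         call. = FALSE)
  }
  scores$stratum <- factor(ifelse(scores$pca_score > model$cutpoint,
                                  "high", "low"),
                           levels = c("low", "high"))
  scores
}

#' Set the risk cutpoint (and direction) of a score model
#'
#' Stores a cutpoint — typically from [max_rank_cutpoint()] on the training
#' scores — and, when training survival data are supplied, learns which
#' stratum has the worse outcome (more observed than expected events in the
#' high stratum means `high_score_high_risk`).
#'
#' @param model a `score_model`.
#' @param cutpoint numeric cutpoint on the score scale.
#' @param scores,times,events optional training scores and outcome used to
#'   record the risk direction.
#' @return The updated model.
#' @export
set_cutpoint <- function(model, cutpoint, scores = NULL, times = NULL,
                         events = NULL) {
  stopifnot(inherits(model, "score_model"))
  model$cutpoint <- cutpoint
  if (!is.null(scores) && !is.null(times) && !is.null(events)) {
    high <- scores > cutpoint
    if (any(high) && any(!high) && sum(events) > 0) {
      mom <- logrank_moments(times, events, high)
      model$risk_direction <- if (mom$O1 >= mom$E1) {
        "high_score_high_risk"
      } else {
        "high_score_low_risk"
      }
    }
  }
  model
}
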