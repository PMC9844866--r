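#' Fit the full subtype-to-risk-score pipeline
#'
#' End-to-end construction of a prognostic expression signature:
#' \enumerate{
#'   \item consensus NMF subtyping of the samples (with average silhouette
#'     width and cophenetic diagnostics);
#'   \item moderated-t differential expression between the two subtypes and
#'     the `|log2FC| >= lfc_min`, `p < p_max` filter;
#'   \item VNLHHO wrapper selection of characteristic genes among the DEGs;
#'   \item prognostic screening of the DEGs (univariate Cox and median-split
#'     log-rank, both at `screen_alpha`);
#'   \item signature = prognostic genes that are also characteristic genes;
#'   \item PCA score fit, maximally selected rank-statistic cutpoint, and
#'     low/high stratification;
#'   \item evaluation: per-stratum Kaplan--Meier curves, log-rank test,
#'     univariate and covariate-adjusted Cox models of the score,
#'     time-dependent AUC at the requested horizons, concordance index, and
#'     (optionally) a secondary consensus clustering of the prognostic genes
#'     ("gene subtypes").
#' }
#' Each stage draws its randomness from a seed derived from `seed` by a fixed
#' offset, so the fit is fully reproducible and changing one stage's settings
#' does not perturb another stage's stream.
#'
#' @param expression log2 expression matrix, genes x samples.
#' @param clinical data.frame aligned to the columns of `expression` with
#'   `sample_id`, `os_years`, `os_event`, and optional covariates. Rows with
#'   missing survival information are dropped (with their samples).
#' @param k_subtypes number of consensus clusters (2 for the usual two-subtype
#'   analysis).
#' @param n_runs consensus NMF restarts.
#' @param lfc_min,p_max differential-expression filter thresholds.
#' @param screen_alpha significance level of the prognostic screen.
#' @param vnlhho a [vnlhho_config()]; its `seed` is overridden by the derived
#'   stage seed.
#' @param minprop minimum stratum fraction for the cutpoint search.
#' @param horizons evaluation horizons (years) for the time-dependent AUC.
#' @param gene_subtypes also re-cluster samples on the prognostic genes.
#' @param gene_subtype_alpha looser screen level used only to pick the genes
#'   for that secondary clustering.
#' @param covariates clinical covariate columns to adjust for in the
#'   multivariate Cox model (those present and non-constant are used).
#' @param seed master integer seed.
#' @return An object of class `pcascore`; see [print.pcascore()],
#'   [summary.pcascore()], [predict.pcascore()], [coef.pcascore()],
#'   [plot.pcascore()].
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_samples = 80, n_genes = 150,
#'                                         n_informative = 15, seed = 7))
#' fit <- pcascore(cohort$expression, cohort$clinical,
#'                 vnlhho = vnlhho_config(pop_size = 10, max_iter = 15),
#'                 n_runs = 10, seed = 7)
#' print(fit)
#' }
pcascore <- function(expression, clinical,
                     k_subtypes = 2L,
                     n_runs = 30L,
                     lfc_min = 0.5,
                     p_max = 0.05,
                     screen_alpha = 0.001,
                     vnlhho = vnlhho_config(),
                     minprop = 0.1,
                     horizons = c(1, 3, 5, 7),
                     gene_subtypes = TRUE,
                     gene_subtype_alpha = 0.05,
                     covariates = c("age", "grade", "IDH_status",
                                    "1p19q_status", "MGMTp_status",
                                    "Chemo_status", "Radio_status", "gender"),
                     seed = 1L) {
  call <- match.call()
  check_expression(expression)
  if (any(diff(horizons) <= 0) || any(horizons <= 0)) {
    stop("horizons must be positive and increasing", call. = FALSE)
  }
  stage <- function(name, msg) {
    stop(sprintf("[stage %s] %s", name, msg), call. = FALSE)
  }
  if (!all(c("sample_id", "os_years", "os_event") %in% names(clinical))) {
    stage("ingest", "clinical table needs sample_id, os_years, os_event")
  }
  if (!setequal(clinical$sample_id, colnames(expression))) {
    stage("ingest", "clinical sample ids do not match expression columns")
  }
  clinical <- clinical[match(colnames(expression), clinical$sample_id), ,
                       drop = FALSE]
  complete <- !is.na(clinical$os_years) & !is.na(clinical$os_event) &
    clinical$os_years > 0
  if (!all(complete)) {   # samples without complete follow-up are excluded
    clinical <- clinical[complete, , drop = FALSE]
    expression <- expression[, complete, drop = FALSE]
  }
  X <- expression
  times <- clinical$os_years
  events <- clinical$os_event

  # (2) consensus subtyping ---------------------------------------------
  s_sub <- derive_seed(seed, 101)
  consensus <- consensus_matrix(X, k = k_subtypes, n_runs = n_runs,
                                seed = s_sub)
  labels <- cluster_from_consensus(consensus, k = k_subtypes)
  subtype_asw <- asw(consensus, labels)
  subtype_cophenetic <- tryCatch(cophenetic_correlation(consensus),
                                 error = function(e) NA_real_)

  # (3) differential expression -----------------------------------------
  de_table <- moderated_t_test(X, labels)
  degs <- filter_degs(de_table, lfc_min = lfc_min, p_max = p_max)
  if (length(degs) < 2L) {
    stage("differential_expression",
          sprintf("only %d gene(s) pass |log2FC| >= %g and p < %g; relax the thresholds or check the clustering",
                  length(degs), lfc_min, p_max))
  }

  # (4) characteristic genes (VNLHHO) -----------------------------------
  vnlhho$seed <- derive_seed(seed, 202)
  selection <- select_features(X[degs, , drop = FALSE], labels,
                               config = vnlhho)

  # (5) prognostic screen ------------------------------------------------
  prognostic <- prognostic_screen(X, clinical, genes = degs,
                                  alpha = screen_alpha)

  # (6) signature ---------------------------------------------------------
  signature <- intersect(prognostic, selection$selected_genes)
  if (length(signature) < 2L) {
    stage("signature",
          sprintf("signature has %d gene(s) (need >= 2): prognostic screen found %d, selector kept %d; with weak subtype separation consider a looser screen_alpha",
                  length(signature), length(prognostic),
                  length(selection$selected_genes)))
  }

  # (7) score model -------------------------------------------------------
  model <- fit_score(X[signature, , drop = FALSE])
  scores <- apply_score(model, X)
  cut_res <- max_rank_cutpoint(scores$pca_score, times, events,
                               minprop = minprop)
  model <- set_cutpoint(model, cut_res$cutpoint, scores$pca_score,
                        times, events)
  scores <- stratify(scores, model)
  if (nlevels(droplevels(scores$stratum)) < 2L) {
    stage("stratify", "all samples fall in one stratum")
  }

  # (8) evaluation --------------------------------------------------------
  evaluation <- evaluate_scores(scores, times, events, clinical,
                                covariates, horizons)
  gene_subtype <- NULL
  if (isTRUE(gene_subtypes)) {
    gs_genes <- prognostic_screen(X, clinical, genes = degs,
                                  alpha = gene_subtype_alpha)
    if (length(gs_genes) >= 2L) {
      gs_cons <- consensus_matrix(X[gs_genes, , drop = FALSE],
                                  k = k_subtypes, n_runs = n_runs,
                                  seed = derive_seed(seed, 303))
      gs_labels <- tryCatch(cluster_from_consensus(gs_cons, k = k_subtypes),
                            error = function(e) NULL)
      if (!is.null(gs_labels)) {
        gene_subtype <- list(genes = gs_genes, labels = gs_labels,
                             asw = asw(gs_cons, gs_labels))
      }
    }
  }

  structure(list(
    call = call,
    n_samples = ncol(X),
    n_genes = nrow(X),
    subtype = list(labels = labels, consensus = consensus,
                   asw = subtype_asw, cophenetic = subtype_cophenetic,
                   k = k_subtypes, n_runs = n_runs),
    de = list(table = de_table, degs = degs,
              lfc_min = lfc_min, p_max = p_max),
    selection = selection,
    prognostic_genes = prognostic,
    signature_genes = signature,
    model = model,
    cutpoint = cut_res,
    scores = scores,
    evaluation = evaluation,
    gene_subtype = gene_subtype,
    clinical = clinical,
    config = list(k_subtypes = k_subtypes, n_runs = n_runs,
                  lfc_min = lfc_min, p_max = p_max,
                  screen_alpha = screen_alpha, vnlhho = unclass(vnlhho),
                  minprop = minprop, horizons = horizons,
                  covariates = covariates, seed = seed)
  ), class = "pcascore")
}

# Survival evaluation of a scored, stratified cohort; shared by the training
# fit and predict() on a validation cohort.
evaluate_scores <- function(scores, times, events, clinical, covariates,
                            horizons) {
  strata <- scores$stratum
  if (any(table(strata) == 0)) {
    stop("all samples fall in the '",
         names(which(table(strata) > 0))[1],
         "' stratum; stratified survival evaluation is undefined",
         call. = FALSE)
  }
  km_low <- km_curve(times[strata == "low"], events[strata == "low"])
  km_high <- km_curve(times[strata == "high"], events[strata == "high"])
  lr <- logrank_test(times, events, strata)
  cox_uni <- cox_fit(times, events,
                     matrix(scores$pca_score, ncol = 1,
                            dimnames = list(NULL, "pca_score")))
  cov_mat <- build_covariate_matrix(clinical, covariates)
  cox_multi <- NULL
  if (!is.null(cov_mat)) {
    cox_multi <- tryCatch(
      cox_fit(times, events, cbind(pca_score = scores$pca_score, cov_mat)),
      error = function(e) NULL)
  }
  aucs <- vapply(horizons, function(h) {
    tryCatch(td_auc(scores$pca_score, times, events, h),
             error = function(e) NA_real_)
  }, numeric(1))
  names(aucs) <- paste0("auc_", horizons, "y")
  list(km_low = km_low, km_high = km_high, logrank = lr,
       cox_univariate = cox_uni, cox_multivariate = cox_multi,
       td_auc = aucs,
       c_index = c_index(scores$pca_score, times, events),
       median_os = c(low = km_low$median, high = km_high$median))
}

# Numeric design matrix from clinical covariates: numeric columns as-is,
# two-level categoricals as 0/1 indicators; constant or absent columns are
# dropped silently.
build_covariate_matrix <- function(clinical, covariates) {
  cols <- intersect(covariates, names(clinical))
  if (length(cols) == 0L) return(NULL)
  mats <- list()
  for (cl in cols) {
    v <- clinical[[cl]]
    if (anyNA(v)) next
    if (is.numeric(v)) {
      if (stats::sd(v) > 0) mats[[cl]] <- v
    } else {
      f <- factor(v)
      if (nlevels(f) == 2L) {
        ind <- as.numeric(f) - 1
        if (stats::sd(ind) > 0) {
          mats[[paste0(cl, "_", levels(f)[2])]] <- ind
        }
      }
    }
  }
  if (length(mats) == 0L) return(NULL)
  do.call(cbind, mats)
}

#' @export
print.pcascore <- function(x, ...) {
  cat("Consensus-subtype PCA risk score fit\n")
  cat(sprintf("  samples: %d | genes: %d\n", x$n_samples, x$n_genes))
  cat(sprintf("  subtypes (k=%d, %d NMF runs): sizes %s, ASW = %.3f\n",
              x$subtype$k, x$subtype$n_runs,
              paste(table(x$subtype$labels), collapse = "/"),
              x$subtype$asw))
  cat(sprintf("  DEGs: %d | characteristic: %d | prognostic: %d | signature: %d\n",
              length(x$de$degs), length(x$selection$selected_genes),
              length(x$prognostic_genes), length(x$signature_genes)))
  cat(sprintf("  cutpoint: %.4f (%s); strata %s\n",
              x$model$cutpoint, x$model$risk_direction,
              paste(table(x$scores$stratum), collapse = "/")))
  cat(sprintf("  log-rank chi-square = %.2f (p = %.3g); C-index = %.3f\n",
              x$evaluation$logrank$chi_square, x$evaluation$logrank$p_value,
              x$evaluation$c_index))
  invisible(x)
}

#' Summarize a fitted pipeline
#'
#' @param object a `pcascore` fit.
#' @param ... unused.
#' @return Invisibly, a list of headline statistics.
#' @export
summary.pcascore <- function(object, ...) {
  print(object)
  hr <- object$evaluation$cox_univariate$coefficients
  cat(sprintf("  score HR per unit: %.3f [%.3f, %.3f], p = %.3g\n",
              hr$hazard_ratio[1], hr$ci_low[1], hr$ci_high[1],
              hr$p_value[1]))
  auc <- object$evaluation$td_auc
  cat("  time-dependent AUC:",
      paste(sprintf("%s = %.3f", names(auc), auc), collapse = ", "), "\n")
  med <- object$evaluation$median_os
  cat(sprintf("  median OS: low = %s, high = %s years\n",
              if (is.na(med["low"])) "not reached" else
                format(round(med["low"], 2)),
              if (is.na(med["high"])) "not reached" else
                format(round(med["high"], 2))))
  if (!is.null(object$gene_subtype)) {
    cat(sprintf("  gene subtypes: %d prognostic genes, ASW = %.3f\n",
                length(object$gene_subtype$genes), object$gene_subtype$asw))
  }
  invisible(list(asw = object$subtype$asw,
                 n_degs = length(object$de$degs),
                 n_signature = length(object$signature_genes),
                 logrank = object$evaluation$logrank,
                 hr = hr, td_auc = auc,
                 c_index = object$evaluation$c_index,
                 median_os = med))
}

#' Coefficients of the covariate-adjusted Cox model
#'
#' @param object a `pcascore` fit.
#' @param ... unused.
#' @return Named coefficient vector of the multivariate Cox model (falls back
#'   to the univariate score model when no covariates were usable).
#' @export
coef.pcascore <- function(object, ...) {
  fit <- object$evaluation$cox_multivariate %||%
    object$evaluation$cox_univariate
  stats::setNames(fit$coefficients$coef, rownames(fit$coefficients))
}

#' Score and stratify a new cohort with a fitted pipeline
#'
#' Applies the frozen score model (training standardization, loadings and
#' cutpoint; nothing is refit) to a validation expression matrix. When the
#' validation clinical table is supplied the same survival evaluation as in
#' training is run on the new cohort.
#'
#' @param object a `pcascore` fit.
#' @param expression validation expression matrix containing the signature
#'   genes.
#' @param clinical optional validation clinical table (`sample_id`,
#'   `os_years`, `os_event`, covariates).
#' @param ... unused.
#' @return A list with `scores` (data.frame with strata) and, when clinical
#'   data were given, `evaluation` (same structure as the training
#'   evaluation).
#' @export
predict.pcascore <- function(object, expression, clinical = NULL, ...) {
  scores <- apply_score(object$model, expression)
  scores <- stratify(scores, object$model)
  out <- list(scores = scores)
  if (!is.null(clinical)) {
    if (!setequal(clinical$sample_id, colnames(expression))) {
      stop("validation clinical sample ids do not match expression columns",
           call. = FALSE)
    }
    clinical <- clinical[match(colnames(expression), clinical$sample_id), ,
                         drop = FALSE]
    out$evaluation <- evaluate_scores(scores, clinical$os_years,
                                      clinical$os_event, clinical,
                                      object$config$covariates,
                                      object$config$horizons)
  }
  out
}

#' Plot a fitted pipeline
#'
#' Base-graphics displays: `"km"` draws the low/high-stratum Kaplan--Meier
#' curves, `"consensus"` the consensus co-clustering matrix ordered by
#' subtype, `"fitness"` the VNLHHO best-fitness trajectory, `"score"` the
#' score distribution split at the cutpoint.
#'
#' @param x a `pcascore` fit.
#' @param type one of `"km"`, `"consensus"`, `"fitness"`, `"score"`.
#' @param ... forwarded to the underlying plotting call.
#' @return Invisibly, `x`.
#' @export
plot.pcascore <- function(x, type = c("km", "consensus", "fitness", "score"),
                          ...) {
  type <- match.arg(type)
  if (type == "km") {
    kml <- x$evaluation$km_low
    kmh <- x$evaluation$km_high
    step_xy <- function(km) {
      list(x = c(0, rep(km$event_times, each = 2)),
           y = c(1, 1, rep(km$survival[-length(km$survival)] %||% numeric(0),
                           each = 2), km$survival[length(km$survival)]))
    }
    xmax <- max(c(kml$event_times, kmh$event_times, 1))
    graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                   xlab = "Years", ylab = "Survival probability",
                   main = sprintf("Low vs high score (log-rank p = %.3g)",
                                  x$evaluation$logrank$p_value), ...)
    for (ln in list(list(km = kml, col = "#2166AC"),
                      list(km = kmh, col = "#B2182B"))) {
      s <- step_xy(ln$km)
      if (length(s$y) >= 2) graphics::lines(s$x[seq_along(s$y)], s$y,
                                            col = ln$col, lwd = 2)
    }
    graphics::legend("bottomleft", legend = c("low", "high"),
                     col = c("#2166AC", "#B2182B"), lwd = 2, bty = "n")
  } else if (type == "consensus") {
    ord <- order(x$subtype$labels)
    graphics::image(x$subtype$consensus[ord, ord],
                    col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                    axes = FALSE,
                    main = sprintf("Consensus matrix (ASW = %.2f)",
                                   x$subtype$asw), ...)
  } else if (type == "fitness") {
    graphics::plot(x$selection$fitness_history, type = "s",
                   xlab = "Iteration", ylab = "Best fitness",
                   main = "VNLHHO trajectory", ...)
  } else {
    graphics::hist(x$scores$pca_score, breaks = 30,
                   xlab = "PCA score", main = "Score distribution", ...)
    graphics::abline(v = x$model$cutpoint, col = "#B2182B", lwd = 2)
  }
  invisible(x)
}
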