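#' Run the pipeline and write its artifacts and manifest
#'
#' Orchestrates [pcascore()] over a cohort read from disk (the
#' [write_cohort()] layout) or generated on the fly from a [cohort_config()],
#' writes every stage's outputs as plain-text files under `out_dir`, and
#' records a reproducibility manifest (configuration echo, per-stage counts,
#' md5 digests of every artifact, package version). The manifest contains no
#' timestamps, so two runs with identical configuration and seed produce
#' byte-identical artifacts and manifests.
#'
#' Files written: `subtype_consensus.tsv`, `subtype_labels.tsv`,
#' `de_table.tsv`, `selection.json`, `selected_genes.txt`,
#' `score_model.json`, `scores.tsv`, `evaluation.json`, `manifest.json`
#' (plus the cohort itself under `cohort/` when it was generated here).
#'
#' @param input a `synthetic_cohort`, a [cohort_config()] (cohort generated
#'   here), or a directory path holding `expression.tsv` / `clinical.tsv`.
#' @param out_dir output directory, created if needed.
#' @param seed master seed forwarded to [pcascore()].
#' @param validation optional second cohort (same forms as `input`) scored
#'   with the frozen training model.
#' @param ... further arguments to [pcascore()] (thresholds, `vnlhho`,
#'   `n_runs`, ...).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(input, out_dir, seed = 1L, validation = NULL, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- resolve_cohort(input)
  written <- character(0)
  if (!is.null(cohort$config) && inherits(input, c("cohort_config", "list"))) {
    written <- c(written, write_cohort(cohort, file.path(out_dir, "cohort")))
  }
  fit <- pcascore(cohort$expression, cohort$clinical, seed = seed, ...)

  p <- function(f) file.path(out_dir, f)
  utils::write.table(
    data.frame(sample_id = colnames(fit$subtype$consensus),
               fit$subtype$consensus, check.names = FALSE),
    p("subtype_consensus.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(fit$subtype$labels),
               subtype = fit$subtype$labels),
    p("subtype_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$de$table, p("de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(list(
    selected_genes = fit$selection$selected_genes,
    best_fitness = fit$selection$best_fitness,
    fitness_history = fit$selection$fitness_history,
    n_evaluations = fit$selection$n_evaluations,
    config = unclass(fit$selection$config_echo)
  ), auto_unbox = TRUE, digits = NA), p("selection.json"))
  writeLines(fit$selection$selected_genes, p("selected_genes.txt"))
  writeLines(jsonlite::toJSON(list(
    signature_genes = fit$model$signature_genes,
    means = as.list(fit$model$means),
    sds = as.list(fit$model$sds),
    loadings_pc1 = fit$model$loadings[, 1],
    loadings_pc2 = fit$model$loadings[, 2],
    explained_variance = fit$model$explained_variance,
    sign_convention = fit$model$sign_convention,
    cutpoint = fit$model$cutpoint,
    risk_direction = fit$model$risk_direction
  ), auto_unbox = TRUE, digits = NA), p("score_model.json"))
  utils::write.table(fit$scores, p("scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(evaluation_json(fit$evaluation),
                              auto_unbox = TRUE, digits = NA),
             p("evaluation.json"))

  if (!is.null(validation)) {
    vc <- resolve_cohort(validation)
    pred <- predict(fit, vc$expression, vc$clinical)
    utils::write.table(pred$scores, p("validation_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(pred$evaluation)) {
      writeLines(jsonlite::toJSON(evaluation_json(pred$evaluation),
                                  auto_unbox = TRUE, digits = NA),
                 p("validation_evaluation.json"))
    }
  }

  artifacts <- c("subtype_consensus.tsv", "subtype_labels.tsv",
                 "de_table.tsv", "selection.json", "selected_genes.txt",
                 "score_model.json", "scores.tsv", "evaluation.json")
  if (!is.null(validation)) {
    artifacts <- c(artifacts, "validation_scores.tsv",
                   "validation_evaluation.json")
  }
  digests <- as.list(tools::md5sum(file.path(out_dir, artifacts)))
  names(digests) <- artifacts

  manifest <- list(
    package_version = as.character(utils::packageVersion("pcascore")),
    seed = seed,
    config = fit$config,
    counts = list(n_samples = fit$n_samples,
                  n_genes = fit$n_genes,
                  n_degs = length(fit$de$degs),
                  n_selected = length(fit$selection$selected_genes),
                  n_prognostic = length(fit$prognostic_genes),
                  n_signature = length(fit$signature_genes)),
    stages = list(subtype = list(asw = fit$subtype$asw,
                                 k = fit$subtype$k),
                  cutpoint = fit$cutpoint$cutpoint,
                  logrank_p = fit$evaluation$logrank$p_value,
                  c_index = fit$evaluation$c_index),
    artifact_digests = digests
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             p("manifest.json"))
  invisible(manifest)
}

resolve_cohort <- function(input) {
  if (inherits(input, "synthetic_cohort")) return(input)
  if (inherits(input, "cohort_config")) return(generate_cohort(input))
  if (is.character(input) && length(input) == 1L) return(read_cohort(input))
  if (is.list(input)) return(generate_cohort(do.call(cohort_config, input)))
  stop("input must be a cohort, a cohort_config, or a directory path",
       call. = FALSE)
}

# JSON-serializable view of an evaluation list.
evaluation_json <- function(ev) {
  list(
    logrank = list(chi_square = ev$logrank$chi_square,
                   p_value = ev$logrank$p_value),
    cox_univariate = cbind(term = rownames(ev$cox_univariate$coefficients),
                           ev$cox_univariate$coefficients),
    cox_multivariate = if (!is.null(ev$cox_multivariate)) {
      cbind(term = rownames(ev$cox_multivariate$coefficients),
            ev$cox_multivariate$coefficients)
    },
    td_auc = as.list(ev$td_auc),
    c_index = ev$c_index,
    median_os = as.list(ev$median_os)
  )
}
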