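#' Kaplan--Meier product-limit curve
#'
#' Product-limit estimator of the survival function. Censorings recorded at an
#' event time are counted as at risk for that event (the standard
#' censored-after-event convention). The median is the first event time at
#' which the estimated survival drops to 0.5 or below, `NA` if never reached.
#'
#' @param times positive follow-up times.
#' @param events event indicators, 1 = event, 0 = censored.
#' @return A list of class `km_curve`: `event_times` (distinct times with at
#'   least one event, increasing), `survival` (estimate just after each event
#'   time, non-increasing from 1), `at_risk`, `n_events`, `n`, `median`.
#' @export
#' @examples
#' km <- km_curve(c(1, 2), c(1, 1))
#' km$survival  # 0.5, 0
km_curve <- function(times, events) {
  check_survival(times, events)
  n <- length(times)
  evt <- sort(unique(times[events == 1]))
  if (length(evt) == 0L) {
    return(structure(list(event_times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), n_events = integer(0),
                          n = n, median = NA_real_), class = "km_curve"))
  }
  st <- sort(times)
  at_risk <- n - findInterval(evt, st, left.open = TRUE)
  d <- vapply(evt, function(u) sum(times == u & events == 1), integer(1))
  surv <- cumprod(1 - d / at_risk)
  med <- if (any(surv <= 0.5)) evt[which(surv <= 0.5)[1]] else NA_real_
  structure(list(event_times = evt, survival = surv, at_risk = at_risk,
                 n_events = d, n = n, median = med), class = "km_curve")
}

# Step-function lookup of a km_curve: S(t) (right-continuous) or the left
# limit S(t-) when left = TRUE.
km_surv_at <- function(curve, t, left = FALSE) {
  if (length(curve$event_times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$event_times, left.open = left)
  c(1, curve$survival)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, median = %s\n",
              x$n, sum(x$n_events),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

# Log-rank ingredients at each distinct event time: at-risk and event counts
# overall and in group 1. Returns O1, E1, V.
logrank_moments <- function(times, events, g1) {
  evt <- sort(unique(times[events == 1]))
  st <- sort(times)
  st1 <- sort(times[g1])
  nt <- length(times) - findInterval(evt, st, left.open = TRUE)
  n1t <- length(st1) - findInterval(evt, st1, left.open = TRUE)
  dt <- vapply(evt, function(u) sum(times == u & events == 1), numeric(1))
  d1t <- vapply(evt, function(u) sum(times == u & events == 1 & g1),
                numeric(1))
  E1 <- dt * n1t / nt
  Vt <- ifelse(nt > 1,
               dt * (n1t / nt) * (1 - n1t / nt) * (nt - dt) / (nt - 1), 0)
  list(O1 = sum(d1t), E1 = sum(E1), V = sum(Vt))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) from observed-minus-expected events in
#' the first group under the hypergeometric null at each distinct event time.
#' Also returns the signed standardized statistic `z = (O1 - E1) / sqrt(V)`
#' (positive when group 1 has more events than expected, i.e. worse survival).
#'
#' @param times positive follow-up times.
#' @param events event indicators (0/1).
#' @param group two-level grouping vector; "group 1" is the first factor
#'   level.
#' @return List of class `logrank_test`: `chi_square`, `p_value`, `z`,
#'   `observed`, `expected` (group-1 counts), `n`.
#' @export
logrank_test <- function(times, events, group) {
  check_survival(times, events)
  f <- check_two_groups(group, length(times))
  if (sum(events) == 0) {
    stop("log-rank test undefined: no events observed", call. = FALSE)
  }
  mom <- logrank_moments(times, events, f == levels(f)[1])
  if (mom$V <= 0) {
    chi <- 0
    z <- 0
  } else {
    z <- (mom$O1 - mom$E1) / sqrt(mom$V)
    chi <- z^2
  }
  structure(list(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 z = z, observed = mom$O1, expected = mom$E1,
                 n = length(times)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards model
#'
#' Newton--Raphson maximization of the Cox partial likelihood with Efron's
#' approximation for tied event times; Wald confidence intervals and p-values
#' from the observed information at the optimum. Handles a single covariate
#' (univariate screening) through many (multivariate modelling).
#'
#' @param times positive follow-up times.
#' @param events event indicators (0/1); at least one event required.
#' @param covariates numeric matrix or data.frame, samples x covariates; no
#'   constant columns, no missing values.
#' @param max_iter Newton--Raphson iteration cap; exceeding it flags
#'   `converged = FALSE`.
#' @param tol relative log-likelihood convergence tolerance.
#' @return List of class `cox_fit`: `coefficients` data.frame (one row per
#'   covariate: `coef`, `hazard_ratio`, `se`, `ci_low`, `ci_high`, `p_value`),
#'   `loglik` (at optimum), `loglik_null`, `n`, `n_events`, `converged`,
#'   `n_iter`.
#' @export
cox_fit <- function(times, events, covariates, max_iter = 100L, tol = 1e-9) {
  check_survival(times, events)
  Xc <- as.matrix(covariates)
  storage.mode(Xc) <- "double"
  if (nrow(Xc) != length(times)) {
    stop("covariate rows must match the number of samples", call. = FALSE)
  }
  if (anyNA(Xc) || any(!is.finite(Xc))) {
    stop("covariates must be finite and non-missing", call. = FALSE)
  }
  if (is.null(colnames(Xc))) colnames(Xc) <- paste0("x", seq_len(ncol(Xc)))
  sds <- apply(Xc, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant covariate column(s): ",
         paste(colnames(Xc)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (sum(events) < 1) stop("at least one event is required", call. = FALSE)

  ord <- order(times)
  tt <- times[ord]
  ee <- events[ord]
  XX <- Xc[ord, , drop = FALSE]
  n <- length(tt)
  p <- ncol(XX)

  evt_times <- unique(tt[ee == 1])
  # risk-set start index (first sorted position with time >= u) per event time
  risk_start <- findInterval(evt_times, tt, left.open = TRUE) + 1L
  tied <- lapply(evt_times, function(u) which(tt == u & ee == 1))

  partial <- function(beta) {
    eta <- drop(XX %*% beta)
    eta <- eta - max(eta)          # stabilize exponentials
    w <- exp(eta)
    wX <- XX * w
    # reverse cumulative sums over sorted samples
    cw <- rev(cumsum(rev(w)))
    cwx <- apply(wX, 2, function(col) rev(cumsum(rev(col))))
    cwx <- matrix(cwx, nrow = n)
    cwxx <- array(0, dim = c(n, p, p))
    acc <- matrix(0, p, p)
    for (i in n:1) {
      acc <- acc + w[i] * tcrossprod(XX[i, ])
      cwxx[i, , ] <- acc
    }
    ll <- 0
    grad <- numeric(p)
    hess <- matrix(0, p, p)
    for (j in seq_along(evt_times)) {
      Du <- tied[[j]]
      d <- length(Du)
      i0 <- risk_start[j]
      S0 <- cw[i0]
      S1 <- cwx[i0, ]
      S2 <- cwxx[i0, , ]
      s0d <- sum(w[Du])
      s1d <- colSums(wX[Du, , drop = FALSE])
      s2d <- matrix(0, p, p)
      for (i in Du) s2d <- s2d + w[i] * tcrossprod(XX[i, ])
      ll <- ll + sum(eta[Du])
      grad <- grad + colSums(XX[Du, , drop = FALSE])
      for (l in seq_len(d) - 1L) {
        phi <- l / d
        z0 <- S0 - phi * s0d
        z1 <- S1 - phi * s1d
        z2 <- S2 - phi * s2d
        ll <- ll - log(z0)
        grad <- grad - z1 / z0
        hess <- hess - (z2 / z0 - tcrossprod(z1) / z0^2)
      }
    }
    list(ll = ll, grad = grad, hess = hess)
  }

  beta <- numeric(p)
  cur <- partial(beta)
  loglik_null <- cur$ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    step <- tryCatch(solve(cur$hess, cur$grad),
                     error = function(e) NULL)
    if (is.null(step)) break
    step <- -step
    new_beta <- beta + step
    new_cur <- partial(new_beta)
    halvings <- 0L
    while ((!is.finite(new_cur$ll) || new_cur$ll < cur$ll) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_cur <- partial(new_beta)
      halvings <- halvings + 1L
    }
    done <- is.finite(new_cur$ll) &&
      abs(new_cur$ll - cur$ll) < tol * (abs(cur$ll) + tol)
    beta <- new_beta
    cur <- new_cur
    if (done) {
      converged <- TRUE
      break
    }
  }
  # monotone likelihood / separation heuristic
  if (any(abs(beta) > 15)) converged <- FALSE

  info_inv <- tryCatch(solve(-cur$hess), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(info_inv), 0))
  zq <- stats::qnorm(0.975)
  coefs <- data.frame(
    coef = beta,
    hazard_ratio = exp(beta),
    se = se,
    ci_low = exp(beta - zq * se),
    ci_high = exp(beta + zq * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    row.names = colnames(XX)
  )
  structure(list(coefficients = coefs, loglik = cur$ll,
                 loglik_null = loglik_null, n = n, n_events = sum(ee),
                 converged = converged, n_iter = it),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, %d events%s\n",
              x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$coefficients$coef, rownames(object$coefficients))
}

#' Screen genes for prognostic value
#'
#' A gene passes when both (a) the univariate Cox model on its standardized
#' continuous expression and (b) the log-rank test on its median-split
#' dichotomization reject at level `alpha`. Requiring both tests is the
#' stricter reading of a combined Kaplan--Meier / univariate-Cox screen;
#' set `require_both = FALSE` for the either-test variant.
#'
#' @param X expression matrix, genes x samples.
#' @param clinical data.frame with `os_years` and `os_event` aligned to the
#'   columns of `X`.
#' @param genes gene ids to screen (default: all rows of `X`).
#' @param alpha significance level for both tests.
#' @param require_both require both tests (default) or either.
#' @return Character vector of passing gene ids (input order preserved).
#' @export
prognostic_screen <- function(X, clinical, genes = rownames(X),
                              alpha = 0.001, require_both = TRUE) {
  check_expression(X)
  missing_genes <- setdiff(genes, rownames(X))
  if (length(missing_genes)) {
    stop("genes absent from the expression matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  times <- clinical$os_years
  events <- clinical$os_event
  check_survival(times, events)
  if (nrow(clinical) != ncol(X)) {
    stop("clinical rows must match expression columns", call. = FALSE)
  }
  pass <- vapply(genes, function(g) {
    expr <- X[g, ]
    if (stats::sd(expr) == 0) return(FALSE)
    z <- as.numeric(scale(expr))
    cox_p <- tryCatch({
      fit <- cox_fit(times, events, matrix(z, ncol = 1,
                                           dimnames = list(NULL, g)))
      fit$coefficients$p_value[1]
    }, error = function(e) 1)
    grp <- factor(expr > stats::median(expr), levels = c(FALSE, TRUE),
                  labels = c("low", "high"))
    lr_p <- if (nlevels(droplevels(grp)) < 2L) 1 else {
      tryCatch(logrank_test(times, events, grp)$p_value,
               error = function(e) 1)
    }
    if (require_both) cox_p < alpha && lr_p < alpha
    else cox_p < alpha || lr_p < alpha
  }, logical(1))
  genes[pass]
}

#' Maximally selected rank-statistic cutpoint
#'
#' Evaluates the standardized log-rank statistic at every candidate cutpoint
#' between consecutive distinct score values whose low/high split leaves both
#' groups with at least `minprop * n` samples, and returns the cutpoint
#' maximizing the absolute statistic (ties broken toward the lower cutpoint).
#' The low group is `score <= cutpoint`. The selection p-value, which must
#' account for scanning many cutpoints, is estimated by permutation when
#' `n_perm > 0`.
#'
#' @param score continuous per-sample score (>= 2 distinct values).
#' @param times,events survival outcome.
#' @param minprop minimum fraction of samples per group.
#' @param n_perm permutations for the selection-adjusted p-value (0 = skip).
#' @return List of class `cutpoint_result`: `cutpoint`, `max_statistic`
#'   (absolute standardized log-rank statistic), `minprop`, `group_sizes`
#'   (low, high), `p_value` (`NA` when `n_perm = 0`).
#' @export
max_rank_cutpoint <- function(score, times, events, minprop = 0.1,
                              n_perm = 0L) {
  check_survival(times, events)
  if (length(score) != length(times)) {
    stop("score length must match the survival vectors", call. = FALSE)
  }
  if (length(unique(score)) < 2L) {
    stop("cutpoint undefined: all scores are equal", call. = FALSE)
  }
  scan <- scan_cutpoints(score, times, events, minprop)
  if (is.null(scan)) {
    stop("no feasible cutpoint under minprop = ", minprop, call. = FALSE)
  }
  p_value <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      sb <- sample(score)
      scan_b <- scan_cutpoints(sb, times, events, minprop)
      if (!is.null(scan_b) && scan_b$max_statistic >= scan$max_statistic) {
        exceed <- exceed + 1L
      }
    }
    p_value <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(cutpoint = scan$cutpoint,
                 max_statistic = scan$max_statistic,
                 minprop = minprop,
                 group_sizes = scan$group_sizes,
                 p_value = p_value),
            class = "cutpoint_result")
}

scan_cutpoints <- function(score, times, events, minprop) {
  n <- length(score)
  us <- sort(unique(score))
  cands <- us[-length(us)]
  n_low <- vapply(cands, function(c) sum(score <= c), numeric(1))
  ok <- n_low >= minprop * n & (n - n_low) >= minprop * n
  cands <- cands[ok]
  if (length(cands) == 0L) return(NULL)
  stat <- vapply(cands, function(c) {
    grp <- factor(score <= c, levels = c(TRUE, FALSE))
    mom <- logrank_moments(times, events, grp == levels(grp)[1])
    if (mom$V <= 0) 0 else abs(mom$O1 - mom$E1) / sqrt(mom$V)
  }, numeric(1))
  best <- which.max(stat)  # which.max takes the first (lowest cutpoint) tie
  c_best <- cands[best]
  list(cutpoint = c_best, max_statistic = stat[best],
       group_sizes = c(low = sum(score <= c_best),
                       high = sum(score > c_best)))
}

#' Time-dependent AUC with censoring weights
#'
#' Cumulative-case / dynamic-control AUC at a horizon: cases are samples with
#' an observed event at or before the horizon, controls are samples still at
#' risk beyond it, and both are weighted by the inverse of the product-limit
#' estimate of the censoring distribution (cases at the left limit of their
#' event time, controls at the horizon). Score ties count 0.5. Without
#' censoring this reduces exactly to the Mann--Whitney statistic between
#' cases and controls.
#'
#' @param score risk score (higher = assumed higher risk).
#' @param times,events survival outcome.
#' @param horizon evaluation time.
#' @return AUC in \[0, 1\].
#' @export
td_auc <- function(score, times, events, horizon) {
  check_survival(times, events)
  if (length(score) != length(times)) {
    stop("score length must match the survival vectors", call. = FALSE)
  }
  case <- times <= horizon & events == 1
  ctrl <- times > horizon
  if (!any(case) || !any(ctrl)) {
    stop("time-dependent AUC undefined: need at least one case and one control at the horizon",
         call. = FALSE)
  }
  cens_km <- km_curve(times, 1 - events)
  w_case <- 1 / km_surv_at(cens_km, times[case], left = TRUE)
  w_ctrl <- rep(1 / km_surv_at(cens_km, horizon), sum(ctrl))
  if (any(!is.finite(w_case)) || any(!is.finite(w_ctrl))) {
    stop("censoring-distribution weight is infinite at the horizon",
         call. = FALSE)
  }
  sc <- score[case]
  st <- score[ctrl]
  cmp <- outer(sc, st, ">") + 0.5 * outer(sc, st, "==")
  ww <- outer(w_case, w_ctrl)
  sum(ww * cmp) / sum(ww)
}

#' Harrell's concordance index
#'
#' Probability that, among usable pairs (the earlier time is an observed
#' event and the times differ), the sample with the earlier event has the
#' higher score; score ties count 0.5.
#'
#' @param score risk score (higher = predicted earlier event).
#' @param times,events survival outcome.
#' @return C-index in \[0, 1\].
#' @export
c_index <- function(score, times, events) {
  check_survival(times, events)
  if (length(score) != length(times)) {
    stop("score length must match the survival vectors", call. = FALSE)
  }
  usable <- outer(times, times, "<") & (events == 1)
  n_pairs <- sum(usable)
  if (n_pairs == 0L) {
    stop("no usable pairs for the concordance index", call. = FALSE)
  }
  conc <- sum(usable & outer(score, score, ">")) +
    0.5 * sum(usable & outer(score, score, "=="))
  conc / n_pairs
}
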