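# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage / per-run seed from a master seed, kept inside 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + as.double(offset)) %% 2147483647)
}

# Validate a genes x samples expression matrix: numeric, finite, unique ids.
check_expression <- function(X, what = "expression matrix") {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("%s must be a numeric matrix (genes x samples)", what),
         call. = FALSE)
  }
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop(sprintf("%s must carry gene rownames and sample colnames", what),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(X)) || anyDuplicated(colnames(X))) {
    stop(sprintf("%s has duplicated gene or sample identifiers", what),
         call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop(sprintf("%s contains missing or non-finite values", what),
         call. = FALSE)
  }
  invisible(X)
}

# Coerce a two-group label vector into a factor with exactly two levels.
check_two_groups <- function(labels, n, min_per_group = 1L) {
  if (length(labels) != n) {
    stop(sprintf("labels length (%d) does not match sample count (%d)",
                 length(labels), n), call. = FALSE)
  }
  f <- factor(labels)
  if (nlevels(f) != 2L) {
    stop(sprintf("exactly two groups are required, found %d", nlevels(f)),
         call. = FALSE)
  }
  if (any(table(f) < min_per_group)) {
    stop(sprintf("each group needs at least %d samples", min_per_group),
         call. = FALSE)
  }
  f
}

check_survival <- function(times, events) {
  if (length(times) != length(events) || length(times) == 0L) {
    stop("`times` and `events` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (anyNA(times) || any(times <= 0)) {
    stop("all survival times must be positive and non-missing", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) {
    stop("event indicators must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
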