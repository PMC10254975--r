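# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' @noRd
stop_bad_arg <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# Run an expression under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Small deterministic sub-seed derivation; keeps results < 2^31.
# Arithmetic in doubles (exact below 2^53) to avoid integer overflow.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

check_matrix <- function(M, what) {
  if (!is.matrix(M) || !is.numeric(M)) {
    stop_bad_arg(what, " must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stop_bad_arg(what, " must have feature rownames and sample colnames")
  }
  invisible(M)
}

# Design matrix from a covariate data frame: model.matrix with intercept,
# checking full column rank and that the tested column is present.
build_design <- function(covariates, formula = NULL) {
  if (is.matrix(covariates)) {
    X <- covariates
  } else {
    if (is.null(formula)) {
      formula <- stats::as.formula(paste("~", paste(names(covariates), collapse = " + ")))
    }
    X <- stats::model.matrix(formula, data = covariates)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_bad_arg("design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", "))
  }
  X
}
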