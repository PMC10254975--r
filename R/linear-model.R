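#' Per-feature ordinary least squares across a feature x sample matrix
#'
#' Fits the same linear model to every row of `Y` (one feature at a time,
#' shared design), returning for each feature the coefficient of the tested
#' column, its standard error, the residual standard deviation `sigma`, the
#' residual degrees of freedom and the unscaled standard error factor
#' `stdev_unscaled` = sqrt of the tested diagonal element of (X'X)^-1, so
#' that `se = sigma * stdev_unscaled`. Features containing missing values
#' are dropped from the fit and reported.
#'
#' @param Y Feature x sample numeric matrix (rows = features).
#' @param design Design matrix (samples x covariates) or a covariate data
#'   frame expanded with an intercept via `model.matrix`.
#' @param coef Name of the tested design column, e.g. `"exposure"`. `NULL`
#'   fits the model without reporting a tested coefficient (intercept-only
#'   summaries).
#' @return A `feature_fit` object; `tidy()` returns the per-feature table.
#' @export
#' @examples
#' Y <- matrix(rnorm(40), 4, 10,
#'   dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
#' X <- cbind(intercept = 1, x = rep(0:1, each = 5))
#' fit <- fit_feature_lm(Y, X, coef = "x")
#' tidy(fit)
fit_feature_lm <- function(Y, design, coef = NULL) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  X <- build_design(design)
  n <- ncol(Y)
  if (nrow(X) != n) stop_bad_arg("design rows must match the sample count")
  if (anyNA(X)) stop_bad_arg("design matrix contains missing values")
  if (n <= ncol(X)) stop_bad_arg("need more samples than design columns")
  if (!is.null(coef) && !coef %in% colnames(X)) {
    stop_bad_arg("tested column '", coef, "' not found in design")
  }

  complete <- !apply(is.na(Y), 1, any)
  dropped <- rownames(Y)[!complete]
  Yc <- Y[complete, , drop = FALSE]

  qr_x <- qr(X)
  d <- n - qr_x$rank
  B <- qr.coef(qr_x, t(Yc))                      # p x G
  res <- t(Yc) - X %*% B
  s2 <- unname(colSums(res^2)) / d
  xtx_inv <- solve(crossprod(X))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))

  if (is.null(coef)) {
    tab <- tibble::tibble(
      feature = rownames(Yc),
      coef = NA_real_, se = NA_real_,
      sigma = sqrt(s2), df = d, stdev_unscaled = NA_real_,
      zero_variance = s2 < .Machine$double.eps * 100
    )
  } else {
    su <- sqrt(xtx_inv[coef, coef])
    tab <- tibble::tibble(
      feature = rownames(Yc),
      coef = unname(B[coef, ]),
      se = sqrt(s2) * su,
      sigma = sqrt(s2),
      df = d,
      stdev_unscaled = su,
      zero_variance = s2 < .Machine$double.eps * 100
    )
  }
  structure(list(
    table = tab, tested = coef, df_residual = d,
    design = X, dropped = dropped
  ), class = "feature_fit")
}

# Newton inversion of the trigamma function (for the prior-df estimate).
trigamma_inverse <- function(y, tol = 1e-8, maxit = 50L) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < tol * x) break
  }
  x
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks each feature's residual variance toward a pooled prior and forms
#' moderated t-statistics. The prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by the method of moments on log s^2: with
#' `e = log(s^2) - digamma(d/2) + log(d/2)`, the excess of `var(e)` over
#' `trigamma(d/2)` equals `trigamma(d0/2)`, inverted by Newton iteration
#' (tolerance 1e-8); `s0^2` follows from `mean(e)`. The posterior variance
#' is `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`, the moderated t is
#' `coef / (s~ * stdev_unscaled)` with `d0 + d` degrees of freedom, and BH
#' FDR is attached. When the log-variances show no excess dispersion the
#' `d0 = Inf` branch is taken and every posterior variance equals `s0^2`.
#'
#' @param fit A [fit_feature_lm()] result with a tested coefficient.
#' @param prior_df,prior_var Optional fixed values overriding estimation
#'   (`prior_df = 0` reproduces ordinary t exactly; `prior_df = Inf` uses
#'   the pooled variance everywhere).
#' @return A `moderated_fit` object; `tidy()` gives the per-feature table
#'   (coef, se, t, p, fdr), `glance()` the prior estimates.
#' @export
ebayes_moderate <- function(fit, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(fit, "feature_fit"))
  if (is.null(fit$tested)) {
    stop_bad_arg("fit has no tested coefficient to moderate")
  }
  tab <- fit$table
  d <- tab$df
  s2 <- tab$sigma^2
  usable <- s2 > 0 & d > 0

  if (is.null(prior_df) || is.null(prior_var)) {
    if (sum(usable) < 2) {
      stop_bad_arg("need >= 2 features with positive residual variance ",
                   "to estimate the variance prior")
    }
    e <- log(s2[usable]) - digamma(d[usable] / 2) + log(d[usable] / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(d[usable] / 2))
    if (is.na(evar) || evar <= 0) {
      est_d0 <- Inf
      est_s02 <- exp(emean)
    } else {
      est_d0 <- 2 * trigamma_inverse(evar)
      est_s02 <- exp(emean + digamma(est_d0 / 2) - log(est_d0 / 2))
    }
    if (is.null(prior_df)) prior_df <- est_d0
    if (is.null(prior_var)) prior_var <- est_s02
  }

  s2_post <- if (is.infinite(prior_df)) {
    rep(prior_var, length(s2))
  } else {
    (prior_df * prior_var + d * s2) / (prior_df + d)
  }
  df_total <- prior_df + d
  t_mod <- tab$coef / (sqrt(s2_post) * tab$stdev_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)

  out <- tibble::tibble(
    feature = tab$feature,
    coef = tab$coef,
    se = sqrt(s2_post) * tab$stdev_unscaled,
    sigma = tab$sigma,
    s2_post = s2_post,
    df_total = df_total,
    t = t_mod,
    p = p,
    fdr = bh_fdr(p)
  )
  structure(list(
    table = out, prior_df = prior_df, prior_var = prior_var,
    tested = fit$tested, df_residual = fit$df_residual
  ), class = "moderated_fit")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, order-preserving with the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_bad_arg("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Genomic inflation factor
#'
#' Converts two-sided p-values to 1-df chi-square quantiles and returns the
#' ratio of the observed median to the null median (about 0.4549). Lambda
#' near 1 indicates calibrated tests; values well above 1 indicate residual
#' confounding or test miscalibration.
#'
#' @param p Non-empty vector of p-values in (0, 1\].
#' @return The inflation factor lambda (a single number; `Inf` with a
#'   warning if any p-value is exactly 0).
#' @export
genomic_inflation <- function(p) {
  if (length(p) == 0) stop_bad_arg("p must be non-empty")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_bad_arg("p-values must lie in [0, 1]")
  }
  if (any(p == 0)) {
    warning("p-value of exactly 0: inflation factor is infinite")
    return(Inf)
  }
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Principal component scores of a feature x sample matrix
#'
#' Centers each feature (row) and returns the top-`k` sample scores of the
#' resulting covariance structure, for use as design covariates capturing
#' batch/structure. Component signs are fixed by making each component's
#' largest-magnitude feature loading positive, so results are fully
#' deterministic.
#'
#' @param M Feature x sample numeric matrix.
#' @param k Number of components (<= min(dim(M))).
#' @return Sample x `k` score matrix with columns `PC1..PCk`.
#' @export
pca_scores <- function(M, k) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (anyNA(M)) stop_bad_arg("M contains missing values")
  if (k < 1 || k > min(dim(M))) {
    stop_bad_arg("k must be between 1 and min(dim(M)) = ", min(dim(M)))
  }
  Mc <- M - rowMeans(M)
  sv <- svd(Mc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    u <- sv$u[, j]
    sign(u[which.max(abs(u))])
  }, numeric(1))
  scores <- sv$v[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)] * flip, nrow = k)
  dimnames(scores) <- list(colnames(M), paste0("PC", seq_len(k)))
  scores
}

#' Moderated-t association scan of a feature matrix
#'
#' Convenience wrapper running [fit_feature_lm()] + [ebayes_moderate()] for
#' a binary exposure with covariate adjustment and optional principal
#' component scores of the response matrix itself, the shared engine behind
#' both the methylation (EWAS) and expression (DGE) scans.
#'
#' @param Y Feature x sample matrix (beta values or log2 expression).
#' @param covariates Covariate tibble including the tested column; character
#'   columns are expanded to dummies.
#' @param test Name of the tested covariate column (default `"exposure"`).
#' @param adjust Character vector of adjustment covariate names present in
#'   `covariates`.
#' @param n_pcs Number of principal components of `Y` appended as
#'   covariates (0 for none).
#' @param extra Optional extra numeric covariate matrix (samples x columns),
#'   e.g. estimated cell-type proportions.
#' @return A `moderated_fit` (see [ebayes_moderate()]).
#' @export
moderated_scan <- function(Y, covariates, test = "exposure",
                           adjust = character(0), n_pcs = 0, extra = NULL) {
  stopifnot(test %in% names(covariates))
  keep <- unique(c(test, adjust))
  form <- stats::as.formula(paste("~", paste(keep, collapse = " + ")))
  X <- stats::model.matrix(form, data = covariates[keep])
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  if (n_pcs > 0) X <- cbind(X, pca_scores(Y, n_pcs))
  fit <- fit_feature_lm(Y, X, coef = test)
  ebayes_moderate(fit)
}
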