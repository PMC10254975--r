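#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname fit_feature_lm
#' @param x A `feature_fit`.
#' @param ... Unused.
tidy.feature_fit <- function(x, ...) x$table

#' @export
#' @rdname ebayes_moderate
#' @param x A `moderated_fit`.
#' @param ... Unused.
tidy.moderated_fit <- function(x, ...) x$table

#' @export
#' @rdname ebayes_moderate
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$table),
    prior_df = x$prior_df,
    prior_var = x$prior_var,
    df_residual = x$df_residual,
    tested = x$tested,
    lambda = genomic_inflation(pmax(x$table$p, .Machine$double.xmin))
  )
}

#' @export
print.feature_fit <- function(x, ...) {
  cat("Per-feature linear fit: ", nrow(x$table), " features, residual df ",
      x$df_residual, ", tested column: ",
      if (is.null(x$tested)) "<none>" else x$tested, "\n", sep = "")
  if (length(x$dropped)) {
    cat("  dropped (missing values): ", length(x$dropped), " features\n",
        sep = "")
  }
  invisible(x)
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("Moderated per-feature statistics: ", nrow(x$table), " features\n",
      "  prior df d0 = ", format(x$prior_df, digits = 4),
      ", prior variance s0^2 = ", format(x$prior_var, digits = 4), "\n",
      sep = "")
  print(utils::head(dplyr::arrange(x$table, .data$p), 5))
  invisible(x)
}
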