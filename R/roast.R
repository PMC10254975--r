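#' Configuration for the rotation gene set test
#'
#' @param nrot Number of random rotations (default 9999). The smallest
#'   achievable p-value is `1 / (nrot + 1)`.
#' @param set_statistic Summary of the member moderated t-statistics:
#'   `"mean"` (default; mixed hypothesis uses the mean absolute value) or
#'   `"msq"` (mixed hypothesis uses the mean squared value; the directional
#'   statistics remain means).
#' @param seed Integer seed for the rotation draws.
#' @param hypotheses Which alternatives to report: subset of
#'   `c("up", "down", "mixed")`.
#' @return A `roast_config` list.
#' @export
roast_config <- function(nrot = 9999,
                         set_statistic = c("mean", "msq"),
                         seed = 1L,
                         hypotheses = c("up", "down", "mixed")) {
  if (nrot < 1) stop_bad_arg("nrot must be >= 1")
  hypotheses <- match.arg(hypotheses, several.ok = TRUE)
  structure(list(
    nrot = as.integer(nrot),
    set_statistic = match.arg(set_statistic),
    seed = as.integer(seed),
    hypotheses = hypotheses
  ), class = "roast_config")
}

# Orthonormal reduction of the design: returns the n x (d+1) basis whose
# first column spans the tested effect (orthogonal to the other covariates,
# sign-aligned with the tested coefficient) and whose remaining d columns
# span the residual space.
effect_residual_basis <- function(X, coef) {
  if (!coef %in% colnames(X)) {
    stop_bad_arg("tested column '", coef, "' not found in design")
  }
  n <- nrow(X)
  p <- ncol(X)
  Xr <- X[, c(setdiff(colnames(X), coef), coef), drop = FALSE]
  qr_x <- qr(Xr)
  if (qr_x$rank < p) stop_bad_arg("design matrix is rank deficient")
  Q <- qr.Q(qr_x, complete = TRUE)
  r_pp <- qr.R(qr_x)[p, p]
  U <- cbind(Q[, p] * sign(r_pp), Q[, (p + 1):n, drop = FALSE])
  U
}

# Shared variance prior estimated once from every gene in E.
roast_prior <- function(E, X, coef) {
  fit <- fit_feature_lm(E, X, coef = coef)
  mod <- ebayes_moderate(fit)
  list(prior_df = mod$prior_df, prior_var = mod$prior_var)
}

moderated_t_coords <- function(z1, ss_total, d, d0, s02) {
  s2 <- (ss_total - z1^2) / d
  s2_post <- if (is.infinite(d0)) {
    array(s02, dim = dim(s2) %||% length(s2))
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  z1 / sqrt(s2_post)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Self-contained rotation gene set test of one set
#'
#' Tests whether the member genes of a set are associated with the tested
#' design column, using random rotations rather than permutation so the
#' test remains valid at small sample sizes and preserves the inter-gene
#' correlation of the set. Each gene's data are reduced to the
#' (d+1)-dimensional subspace spanned by the tested effect and the residual
#' space; moderated t-statistics use a variance prior estimated once from
#' all genes. Each rotation replaces the effect axis by a random direction
#' of the (d+1)-sphere, shared by all genes in that rotation, and the
#' rotation p-value is `(b + 1) / (nrot + 1)` with `b` the number of
#' rotations whose set statistic reaches the observed one.
#'
#' @param E Gene x sample log2 expression matrix (all genes, not only the
#'   set: the variance prior uses every row unless `prior` is supplied).
#' @param design Design matrix or covariate data frame.
#' @param coef Tested design column name.
#' @param members Character vector of member gene ids.
#' @param config A [roast_config()].
#' @param prior Optional list with `prior_df`, `prior_var` (estimated from
#'   `E` when `NULL`).
#' @param set_name Label for the result row.
#' @return One-row tibble: `set`, `n_genes`, `prop_up` (fraction of members
#'   with positive moderated t), observed statistics and `p.up`, `p.down`,
#'   `p.mixed` (NA for hypotheses not requested, and everything NA when no
#'   member is present in `E`).
#' @export
roast_set <- function(E, design, coef, members, config = roast_config(),
                      prior = NULL, set_name = "set") {
  X <- build_design(design)
  present <- intersect(members, rownames(E))
  empty_row <- tibble::tibble(
    set = set_name, n_genes = length(present), prop_up = NA_real_,
    stat_up = NA_real_, stat_down = NA_real_, stat_mixed = NA_real_,
    p.up = NA_real_, p.down = NA_real_, p.mixed = NA_real_
  )
  if (length(present) == 0) return(empty_row)

  if (is.null(prior)) prior <- roast_prior(E, X, coef)
  d0 <- prior$prior_df
  s02 <- prior$prior_var
  n <- ncol(E)
  d <- n - qr(X)$rank
  U <- effect_residual_basis(X, coef)

  Z <- E[present, , drop = FALSE] %*% U      # m x (d+1)
  ss_total <- rowSums(Z^2)
  t_obs <- moderated_t_coords(Z[, 1], ss_total, d, d0, s02)

  msq <- config$set_statistic == "msq"
  obs <- c(
    up = mean(t_obs),
    down = -mean(t_obs),
    mixed = if (msq) mean(t_obs^2) else mean(abs(t_obs))
  )

  nrot <- config$nrot
  dim1 <- d + 1
  rot_t <- with_seed(config$seed, {
    R <- matrix(stats::rnorm(nrot * dim1), nrot, dim1)
    R <- R / sqrt(rowSums(R^2))
    Zrot <- Z %*% t(R)                        # m x nrot
    moderated_t_coords(Zrot, matrix(ss_total, nrow(Zrot), nrot), d, d0, s02)
  })
  rot_up <- colMeans(rot_t)
  rot_mixed <- if (msq) colMeans(rot_t^2) else colMeans(abs(rot_t))

  p_count <- function(rot, o) (sum(rot >= o) + 1) / (nrot + 1)
  p <- c(
    up = p_count(rot_up, obs["up"]),
    down = p_count(-rot_up, obs["down"]),
    mixed = p_count(rot_mixed, obs["mixed"])
  )
  p[setdiff(names(p), config$hypotheses)] <- NA_real_

  tibble::tibble(
    set = set_name, n_genes = length(present),
    prop_up = mean(t_obs > 0),
    stat_up = unname(obs["up"]), stat_down = unname(obs["down"]),
    stat_mixed = unname(obs["mixed"]),
    p.up = unname(p["up"]), p.down = unname(p["down"]),
    p.mixed = unname(p["mixed"])
  )
}

#' Rotation gene set tests across a collection of sets
#'
#' Runs [roast_set()] for every set with a reproducibly derived per-set
#' sub-seed and a variance prior estimated once from all genes, then applies
#' BH adjustment across sets separately within each hypothesis column.
#'
#' @param E,design,coef See [roast_set()].
#' @param sets Gene-set tibble from [build_gene_sets()] (columns `set`,
#'   `members`, optionally `region`/`direction`), or a named list of member
#'   vectors.
#' @param config A [roast_config()].
#' @return A `roast_result` tibble, one row per set, with `p.up`, `p.down`,
#'   `p.mixed` and `FDR.up`, `FDR.down`, `FDR.mixed` columns (empty sets
#'   keep NA p-values and are skipped by the adjustment).
#' @export
roast_all_sets <- function(E, design, coef, sets, config = roast_config()) {
  if (is.list(sets) && !is.data.frame(sets)) {
    sets <- tibble::tibble(set = names(sets), members = unname(sets))
  }
  if (nrow(sets) == 0 || all(lengths(sets$members) == 0)) {
    warning("all gene sets are empty")
  }
  X <- build_design(design)
  prior <- roast_prior(E, X, coef)

  rows <- purrr::map(seq_len(nrow(sets)), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    roast_set(E, X, coef, sets$members[[i]], config = cfg, prior = prior,
              set_name = sets$set[i])
  })
  out <- dplyr::bind_rows(rows)
  for (extra in intersect(c("region", "direction"), names(sets))) {
    out[[extra]] <- sets[[extra]]
  }
  for (h in c("up", "down", "mixed")) {
    pcol <- paste0("p.", h)
    fcol <- paste0("FDR.", h)
    out[[fcol]] <- NA_real_
    ok <- !is.na(out[[pcol]])
    if (any(ok)) out[[fcol]][ok] <- bh_fdr(out[[pcol]][ok])
  }
  front <- intersect(c("set", "region", "direction", "n_genes", "prop_up"),
                     names(out))
  out <- dplyr::relocate(out, dplyr::all_of(front))
  class(out) <- c("roast_result", class(out))
  attr(out, "prior") <- prior
  attr(out, "nrot") <- config$nrot
  out
}
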