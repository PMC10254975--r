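#' Synthetic leukocyte reference panel
#'
#' Generates a reference panel of mean methylation profiles for the six
#' major white-blood-cell types (CD8T, CD4T, NK, Bcell, Mono, Gran) at a set
#' of discriminating CpGs. Profiles are logit-normal with cell-type-specific
#' shifts at type-discriminating CpGs, so the columns are well separated.
#' This is a synthetic stand-in for purified-cell reference data; a real
#' panel can be loaded with [read_reference_panel()].
#'
#' @param n_cpgs Number of panel CpGs (default 200).
#' @param cell_types Cell type names (>= 2).
#' @param seed Integer seed.
#' @return A `reference_panel`: list with `profiles` (CpG x cell type beta
#'   matrix) and `cell_types`.
#' @export
synthetic_reference_panel <- function(n_cpgs = 200,
                                      cell_types = c("CD8T", "CD4T", "NK",
                                                     "Bcell", "Mono", "Gran"),
                                      seed = 1L) {
  if (length(cell_types) < 2) stop_bad_arg("need at least 2 cell types")
  with_seed(seed, {
    k <- length(cell_types)
    base <- stats::rnorm(n_cpgs, 0, 1.5)
    # each CpG discriminates one cell type strongly
    marker_of <- sample.int(k, n_cpgs, replace = TRUE)
    shift <- matrix(stats::rnorm(n_cpgs * k, 0, 0.3), n_cpgs, k)
    shift[cbind(seq_len(n_cpgs), marker_of)] <-
      sample(c(-3, 3), n_cpgs, replace = TRUE)
    profiles <- inv_logit(base + shift)
    dimnames(profiles) <- list(sprintf("panel_cg%05d", seq_len(n_cpgs)),
                               cell_types)
    structure(list(profiles = profiles, cell_types = cell_types),
              class = "reference_panel")
  })
}

#' Estimate blood cell-type proportions by constrained projection
#'
#' Reference-based deconvolution: for each sample, solves
#' min || profiles %*% w - beta_sample ||^2 subject to w >= 0, via
#' non-negative least squares (Lawson-Hanson), with optional renormalization
#' to sum to one. Panel CpGs absent from `beta` are dropped and reported via
#' a warning.
#'
#' @param beta Probe x sample beta matrix containing (some of) the panel
#'   CpGs as rows.
#' @param panel A `reference_panel` (or a CpG x cell-type beta matrix).
#' @param sum_to_one Renormalise each sample's proportions to sum to 1
#'   (default `TRUE`).
#' @return Sample x cell-type matrix of estimated proportions.
#' @export
estimate_cell_proportions <- function(beta, panel, sum_to_one = TRUE) {
  profiles <- if (inherits(panel, "reference_panel")) panel$profiles else panel
  common <- intersect(rownames(profiles), rownames(beta))
  if (length(common) == 0) {
    stop_bad_arg("no panel CpGs found in the beta matrix")
  }
  if (length(common) < nrow(profiles)) {
    warning(nrow(profiles) - length(common),
            " panel CpG(s) missing from the beta matrix; dropped")
  }
  A <- profiles[common, , drop = FALSE]
  B <- beta[common, , drop = FALSE]
  W <- t(apply(B, 2, function(b) pracma::lsqnonneg(A, b)$x))
  dimnames(W) <- list(colnames(beta), colnames(profiles))
  if (sum_to_one) {
    tot <- rowSums(W)
    tot[tot == 0] <- 1
    W <- W / tot
  }
  W
}

#' Read / write a reference panel as TSV
#'
#' The TSV has the CpG id in the first column and one column per cell type.
#'
#' @param path File path.
#' @return `read_reference_panel()` returns a `reference_panel`.
#' @export
read_reference_panel <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  profiles <- as.matrix(df[, -1])
  rownames(profiles) <- df[[1]]
  structure(list(profiles = profiles, cell_types = colnames(profiles)),
            class = "reference_panel")
}

#' @rdname read_reference_panel
#' @param panel A `reference_panel`.
#' @export
write_reference_panel <- function(panel, path) {
  df <- tibble::as_tibble(panel$profiles, rownames = "cpg")
  readr::write_tsv(df, path)
  invisible(path)
}
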