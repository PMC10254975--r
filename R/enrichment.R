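#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of a query gene list:
#' with universe size N, term size K (after restriction to the universe) and
#' query size n, the p-value is the upper hypergeometric tail
#' P(X >= k) for the observed overlap k, BH-adjusted across tested terms.
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query Character vector of query gene ids (e.g. upregulated genes).
#' @param db Gene-set tibble from [read_gmt()] (columns `set`, `members`,
#'   optionally `description`).
#' @param universe Character vector of background gene ids (e.g. all genes
#'   measured on the platform after QC).
#' @param min_overlap Minimum overlap for a term to be tested (default 1;
#'   use 0 to test all terms).
#' @return Tibble: `set`, `description`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `fdr`, ordered by p.
#' @export
#' @examples
#' db <- tibble::tibble(set = "term1", description = "",
#'                      members = list(paste0("g", 1:5)))
#' ora_test(paste0("g", 1:5), db, universe = paste0("g", 1:20))
ora_test <- function(query, db, universe, min_overlap = 1) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_bad_arg("universe must be non-empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe; dropped")
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)

  rows <- purrr::map(seq_len(nrow(db)), function(i) {
    members <- intersect(db$members[[i]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    if (k < min_overlap || K == 0) return(NULL)
    tibble::tibble(
      set = db$set[i],
      description = if ("description" %in% names(db)) db$description[i] else "",
      overlap = k, set_size = K, query_size = n, universe_size = N,
      p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      set = character(0), description = character(0), overlap = integer(0),
      set_size = integer(0), query_size = integer(0),
      universe_size = integer(0), p = numeric(0), fdr = numeric(0)
    ))
  }
  out$fdr <- bh_fdr(out$p)
  dplyr::arrange(out, .data$p)
}
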