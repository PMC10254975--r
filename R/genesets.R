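#' Select genome-wide significant differentially methylated positions
#'
#' Applies a Bonferroni family-wise threshold `alpha / n_tests` (strict
#' inequality) to a moderated EWAS result and labels each retained probe's
#' direction from the sign of its coefficient: `hypo` (negative, lower
#' methylation in the exposed group) or `hyper` (positive).
#'
#' @param ewas A `moderated_fit` or its `tidy()` tibble (columns `feature`,
#'   `coef`, `p`).
#' @param n_tests Number of tests for the Bonferroni correction (typically
#'   the number of probes analysed).
#' @param alpha Family-wise error level (default 0.05).
#' @return Tibble of DMPs: `probe`, `coef`, `p`, `direction`. Probes with a
#'   coefficient of exactly 0 are excluded with a warning (direction
#'   undefined).
#' @export
select_significant_dmps <- function(ewas, n_tests, alpha = 0.05) {
  if (inherits(ewas, "moderated_fit")) ewas <- ewas$table
  if (n_tests < 1) stop_bad_arg("n_tests must be >= 1")
  threshold <- alpha / n_tests
  hits <- dplyr::filter(ewas, .data$p < threshold)
  zero <- hits$coef == 0
  if (any(zero)) {
    warning(sum(zero), " significant probe(s) with coefficient exactly 0: ",
            "direction undefined, excluded")
    hits <- hits[!zero, , drop = FALSE]
  }
  tibble::tibble(
    probe = hits$feature,
    coef = hits$coef,
    p = hits$p,
    direction = ifelse(hits$coef < 0, "hypo", "hyper")
  )
}

#' Build direction-by-region gene sets from significant DMPs
#'
#' For each of the seven array region labels and each methylation direction,
#' the member genes are those with at least one contributing DMP annotated
#' to that gene with that region label; the `Promoter` category is the union
#' of TSS200, TSS1500, 5'UTR and 1stExon members of the same direction.
#' This yields 16 sets (8 region categories x 2 directions), retained even
#' when empty. Probes without a gene link contribute nothing; probes linked
#' to two genes contribute to both. Genes in `exclude_genes` (e.g.
#' independently detected differentially expressed genes) are removed from
#' every set.
#'
#' @param dmps DMP tibble from [select_significant_dmps()].
#' @param annotation Probe annotation (see [generate_annotation()]).
#' @param exclude_genes Character vector of genes to remove from all sets.
#' @return A tibble with one row per set: `set`, `region`, `direction`,
#'   `n_genes`, `members` (list-column), `provenance` (list-column of
#'   contributing probe/gene pairs) and attribute `excluded` recording
#'   exclusions actually applied.
#' @export
build_gene_sets <- function(dmps, annotation, exclude_genes = character(0)) {
  unknown <- setdiff(dmps$probe, annotation$probe)
  if (length(unknown) > 0) {
    stop_bad_arg("DMP probe(s) absent from annotation: ",
                 paste(utils::head(unknown, 5), collapse = ", "))
  }
  links <- annotation[!is.na(annotation$gene), c("probe", "gene", "region")]
  contrib <- dplyr::inner_join(
    links, dmps[, c("probe", "direction")], by = "probe",
    relationship = "many-to-many"
  )

  grid <- tidyr::expand_grid(
    region = region_categories(),
    direction = c("hypo", "hyper")
  )
  rows <- purrr::pmap(grid, function(region, direction) {
    labs <- if (region == "Promoter") promoter_region_labels() else region
    hits <- contrib[contrib$region %in% labs &
                      contrib$direction == direction, , drop = FALSE]
    members <- setdiff(sort(unique(hits$gene)), exclude_genes)
    hits <- hits[hits$gene %in% members, , drop = FALSE]
    tibble::tibble(
      set = paste(region, direction, sep = "_"),
      region = region,
      direction = direction,
      n_genes = length(members),
      members = list(members),
      provenance = list(dplyr::distinct(hits[, c("probe", "gene")]))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- intersect(exclude_genes, unique(contrib$gene))
  out
}

#' Write gene sets to a GMT file
#'
#' One line per set: name, description, then tab-separated member genes.
#'
#' @param sets Gene-set tibble from [build_gene_sets()], or any tibble with
#'   `set` and `members` (list) columns; a `description` column is used when
#'   present, otherwise `region|direction`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- if ("description" %in% names(sets)) {
    sets$description
  } else if (all(c("region", "direction") %in% names(sets))) {
    paste(sets$region, sets$direction, sep = "|")
  } else {
    rep("", nrow(sets))
  }
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[i], desc[i], sets$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file path.
#' @return Tibble with `set`, `description` and `members` (list-column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    set = vapply(parts, `[`, character(1), 1),
    description = vapply(parts, function(x) {
      if (length(x) >= 2) x[2] else ""
    }, character(1)),
    members = lapply(parts, function(x) {
      if (length(x) > 2) unique(x[-(1:2)]) else character(0)
    })
  )
}
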