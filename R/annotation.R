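#' Genomic region categories used for gene-set construction
#'
#' The seven per-probe region labels used on Illumina-style methylation
#' arrays, plus the derived `Promoter` category (the union of TSS200,
#' TSS1500, 5'UTR and first exon).
#'
#' @return Character vector of the eight region category labels.
#' @export
region_categories <- function() {
  c(array_region_labels(), "Promoter")
}

array_region_labels <- function() {
  c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR", "ExonBnd")
}

promoter_region_labels <- function() {
  c("TSS200", "TSS1500", "5UTR", "1stExon")
}

#' Generate a synthetic probe annotation
#'
#' Builds an array-style CpG probe annotation: per-probe chromosome and
#' 1-based position, with zero, one or two gene links, each link carrying its
#' own region label (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR, ExonBnd).
#' A configurable fraction of probes is intergenic (no gene link) and a small
#' fraction links to two genes, emulating multi-gene annotation rows such as
#' "PALM2; PALM2-AKAP2" on real arrays. Only autosomes are emitted.
#'
#' @param n_genes Number of genes to annotate (>= 0; 0 is allowed only when
#'   `n_intergenic` asks for intergenic probes).
#' @param probes_per_gene Expected number of probes per gene. When
#'   `ensure_all_regions` is `TRUE`, one probe per region label is always
#'   placed and the remainder (Poisson-distributed) is spread across labels
#'   with gene-body probes most common.
#' @param intergenic_fraction Target fraction of probes with no gene link.
#' @param multi_gene_fraction Fraction of gene-linked probes that link to a
#'   second gene.
#' @param n_intergenic Optional explicit count of intergenic probes,
#'   overriding `intergenic_fraction`.
#' @param ensure_all_regions Force at least one probe per region label per
#'   gene.
#' @param seed Integer seed; identical seeds give identical annotations.
#'
#' @return A tibble with one row per (probe, gene) link — intergenic probes
#'   have one row with `NA` gene and region — and columns `probe`, `chrom`,
#'   `pos`, `gene`, `region`.
#' @export
#' @examples
#' ann <- generate_annotation(n_genes = 5, seed = 1)
#' dplyr::count(ann, region)
generate_annotation <- function(n_genes,
                                probes_per_gene = 10,
                                intergenic_fraction = 0.2,
                                multi_gene_fraction = 0.05,
                                n_intergenic = NULL,
                                ensure_all_regions = TRUE,
                                seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 0 ||
      n_genes != round(n_genes)) {
    stop_bad_arg("n_genes must be a single non-negative integer")
  }
  if (n_genes == 0 && (is.null(n_intergenic) || n_intergenic < 1)) {
    stop_bad_arg("n_genes must be positive unless n_intergenic > 0 ",
                 "(intergenic-only annotation)")
  }
  regions <- array_region_labels()
  # body probes dominate on real arrays; boundary probes are rare
  region_weights <- c(
    TSS1500 = 0.15, TSS200 = 0.10, `5UTR` = 0.12, `1stExon` = 0.05,
    Body = 0.40, `3UTR` = 0.10, ExonBnd = 0.08
  )

  with_seed(seed, {
    links <- NULL
    if (n_genes > 0) {
      genes <- sprintf("G%04d", seq_len(n_genes))
      gene_chrom <- sample(paste0("chr", 1:22), n_genes, replace = TRUE)
      gene_start <- sample.int(2e8, n_genes, replace = TRUE)

      per_gene <- lapply(seq_len(n_genes), function(i) {
        base <- if (ensure_all_regions) regions else character(0)
        n_extra <- stats::rpois(1, max(probes_per_gene - length(base), 0))
        extra <- sample(regions, n_extra, replace = TRUE, prob = region_weights)
        labs <- c(base, extra)
        tibble::tibble(
          chrom = gene_chrom[i],
          pos = gene_start[i] + sort(sample.int(5e4, length(labs))),
          gene = genes[i],
          region = labs
        )
      })
      links <- dplyr::bind_rows(per_gene)
      links$probe <- sprintf("cg%08d", sample.int(1e8 - 1, nrow(links)))

      # second gene link for a small fraction of probes
      n_multi <- round(multi_gene_fraction * nrow(links))
      if (n_multi > 0 && n_genes > 1) {
        idx <- sample.int(nrow(links), n_multi)
        second <- links[idx, ]
        second$gene <- vapply(second$gene, function(g) {
          sample(setdiff(genes, g), 1L)
        }, character(1))
        second$region <- sample(regions, n_multi, replace = TRUE,
                                prob = region_weights)
        links <- dplyr::bind_rows(links, second)
      }
    }

    n_linked_probes <- if (is.null(links)) 0L else dplyr::n_distinct(links$probe)
    n_inter <- if (!is.null(n_intergenic)) {
      as.integer(n_intergenic)
    } else {
      round(intergenic_fraction / (1 - intergenic_fraction) * n_linked_probes)
    }
    inter <- NULL
    if (n_inter > 0) {
      inter <- tibble::tibble(
        chrom = sample(paste0("chr", 1:22), n_inter, replace = TRUE),
        pos = sample.int(2e8, n_inter, replace = TRUE),
        gene = NA_character_,
        region = NA_character_,
        probe = sprintf("cg%08d", 1e8 - seq_len(n_inter))
      )
    }

    out <- dplyr::bind_rows(links, inter)
    out <- dplyr::select(out, "probe", "chrom", "pos", "gene", "region")
    dplyr::arrange(out, .data$chrom, .data$pos, .data$probe, .data$gene)
  })
}

# distinct probes with location, one row per probe
annotation_probes <- function(annotation) {
  dplyr::distinct(annotation, .data$probe, .data$chrom, .data$pos)
}
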