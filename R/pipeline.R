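#' Configuration for the full integrative pipeline
#'
#' Drives the end-to-end flow: QC -> (optional) cell-type deconvolution ->
#' methylation association scan (EWAS) with inflation diagnostic -> DMP
#' selection at a Bonferroni family-wise level -> expression scan (DGE) ->
#' optional over-representation analysis of up/down genes -> construction of
#' the 16 direction-by-region gene sets with DEG exclusion -> rotation gene
#' set tests.
#'
#' @param simulate A [sim_config()] describing the synthetic cohort, or
#'   `NULL` when `input_dir` (an [export_cohort()] directory) or an explicit
#'   cohort is supplied to [run_pipeline()].
#' @param input_dir Optional directory of TSV inputs (see [read_cohort()]).
#' @param qc A [qc_config()].
#' @param ewas_covariates,dge_covariates Adjustment covariates (names in the
#'   covariate table).
#' @param ewas_n_pcs Principal components of the beta matrix added to the
#'   EWAS design (default 30; capped so the design keeps residual df).
#' @param dge_n_pcs Principal components of the expression matrix added to
#'   the DGE design (default 10).
#' @param alpha Family-wise level for the Bonferroni DMP threshold.
#' @param dge_fdr_cutoff FDR cutoff defining differentially expressed genes
#'   excluded from the gene sets (default 0.05).
#' @param exclude_genes Extra genes to exclude from sets (e.g. previously
#'   published exposure-related genes).
#' @param reference_panel Optional `reference_panel` for cell-type
#'   deconvolution; estimated proportions (one type dropped) then enter the
#'   EWAS design.
#' @param go_gmt Optional path to a GMT annotation for the
#'   over-representation step (skipped when `NULL`).
#' @param roast A [roast_config()].
#' @param output_dir Optional directory for TSV artifacts and the manifest.
#' @param seed Master seed; sub-seeds for simulation and rotations are
#'   derived from it deterministically.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            input_dir = NULL,
                            qc = qc_config(),
                            ewas_covariates = c("age", "sex", "bmi",
                                                "alcohol", "ses"),
                            ewas_n_pcs = 30,
                            dge_covariates = c("age", "sex", "bmi",
                                               "alcohol", "ses"),
                            dge_n_pcs = 10,
                            alpha = 0.05,
                            dge_fdr_cutoff = 0.05,
                            exclude_genes = character(0),
                            reference_panel = NULL,
                            go_gmt = NULL,
                            roast = roast_config(),
                            output_dir = NULL,
                            seed = 1L) {
  if (alpha <= 0 || alpha >= 1 || dge_fdr_cutoff <= 0 || dge_fdr_cutoff >= 1) {
    stop_bad_arg("alpha and dge_fdr_cutoff must be in (0, 1)")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop_bad_arg("input_dir does not exist: ", input_dir)
  }
  structure(list(
    simulate = simulate, input_dir = input_dir, qc = qc,
    ewas_covariates = ewas_covariates, ewas_n_pcs = ewas_n_pcs,
    dge_covariates = dge_covariates, dge_n_pcs = dge_n_pcs,
    alpha = alpha, dge_fdr_cutoff = dge_fdr_cutoff,
    exclude_genes = exclude_genes, reference_panel = reference_panel,
    go_gmt = go_gmt, roast = roast, output_dir = output_dir,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

# design = intercept + tested + adjustment dummies + extra numeric block +
# top PCs of the response, capped to keep residual df
scan_design <- function(Y, covariates, test, adjust, n_pcs, extra = NULL) {
  keep <- unique(c(test, adjust))
  form <- stats::as.formula(paste("~", paste(keep, collapse = " + ")))
  X <- stats::model.matrix(form, data = covariates[keep])
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  max_pcs <- min(n_pcs, ncol(Y) - ncol(X) - 2, nrow(Y))
  if (n_pcs > 0 && max_pcs < n_pcs) {
    message("reducing requested PCs from ", n_pcs, " to ", max_pcs,
            " to preserve residual degrees of freedom")
  }
  if (max_pcs > 0 && n_pcs > 0) X <- cbind(X, pca_scores(Y, max_pcs))
  X
}

# Table-2-style results table: feature, location, genes, coef, SE, t, p, FDR
association_table <- function(mod, annotation = NULL) {
  tab <- dplyr::select(mod$table, "feature", "coef", "se", "t", "p", "fdr")
  if (!is.null(annotation)) {
    loc <- annotation_probes(annotation)
    genes <- dplyr::summarise(
      dplyr::group_by(annotation[!is.na(annotation$gene), ], .data$probe),
      genes = paste(unique(.data$gene), collapse = ";"), .groups = "drop")
    tab <- dplyr::left_join(tab, loc, by = c(feature = "probe"))
    tab <- dplyr::left_join(tab, genes, by = c(feature = "probe"))
    tab <- dplyr::relocate(tab, "feature", "chrom", "pos", "genes")
  }
  dplyr::arrange(tab, .data$p)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full integrative methylome/transcriptome analysis
#'
#' Executes every stage of the analysis on a simulated or imported cohort
#' and (optionally) writes the artifact set: EWAS and DGE result tables in
#' the standard per-feature schema, the DMP table, the 16 gene sets as GMT,
#' rotation-test results, over-representation tables, and a run manifest
#' with the seed and per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional `simulated_cohort` (overrides `config$simulate` /
#'   `config$input_dir`).
#' @return A `pipeline_result` list: `cohort`, `qc` (probe report),
#'   `cell_proportions`, `ewas` (`moderated_fit`), `ewas_table`, `lambda`,
#'   `dmps`, `dge`, `dge_table`, `degs`, `ora_up`, `ora_down`, `sets`,
#'   `roast` and `manifest` (tibble of stage counts).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  cohort <- run_stage("input", {
    if (!is.null(cohort)) {
      cohort
    } else if (!is.null(config$input_dir)) {
      raw <- read_cohort(config$input_dir)
      structure(list(
        beta = raw$beta, expression = raw$expression,
        covariates = raw$covariates, annotation = raw$annotation,
        true_proportions = NULL, truth = NULL,
        config = sim_config(n_samples = ncol(raw$beta),
                            seed = config$seed)
      ), class = "simulated_cohort")
    } else {
      cfg <- config$simulate
      cfg$seed <- derive_seed(config$seed, cfg$seed)
      generate_cohort(cfg)
    }
  })
  message("cohort: ", nrow(cohort$beta), " probes, ",
          nrow(cohort$expression), " genes, ", ncol(cohort$beta), " samples")

  qc_res <- run_stage("qc", {
    det <- matrix(0, nrow(cohort$beta), ncol(cohort$beta),
                  dimnames = dimnames(cohort$beta))
    filter_probes(cohort$beta, det, cohort$annotation, config$qc)
  })
  beta <- qc_res$beta
  message("qc: ", length(qc_res$retained), " probes retained, ",
          nrow(qc_res$report), " removed")

  cell_props <- NULL
  cell_covs <- NULL
  if (!is.null(config$reference_panel)) {
    cell_props <- run_stage("cell_composition",
      estimate_cell_proportions(beta, config$reference_panel))
    # drop the largest compartment to avoid design collinearity
    drop_type <- colnames(cell_props)[which.max(colMeans(cell_props))]
    cell_covs <- cell_props[, setdiff(colnames(cell_props), drop_type),
                            drop = FALSE]
    message("cell_composition: estimated ", ncol(cell_props),
            " cell types; dropped '", drop_type, "' from the design")
  }

  ewas <- run_stage("ewas", {
    X <- scan_design(beta, cohort$covariates, "exposure",
                     config$ewas_covariates, config$ewas_n_pcs, cell_covs)
    ebayes_moderate(fit_feature_lm(beta, X, coef = "exposure"))
  })
  lambda <- run_stage("lambda", genomic_inflation(ewas$table$p))
  message("ewas: lambda = ", round(lambda, 3))

  dmps <- run_stage("dmp_selection",
    select_significant_dmps(ewas, n_tests = nrow(beta), alpha = config$alpha))
  message("dmp_selection: ", nrow(dmps), " DMPs at p < ",
          signif(config$alpha / nrow(beta), 2))

  dge <- run_stage("dge", {
    X <- scan_design(cohort$expression, cohort$covariates, "exposure",
                     config$dge_covariates, config$dge_n_pcs)
    ebayes_moderate(fit_feature_lm(cohort$expression, X, coef = "exposure"))
  })
  degs <- dge$table$feature[dge$table$fdr < config$dge_fdr_cutoff]
  message("dge: ", length(degs), " DEGs at FDR < ", config$dge_fdr_cutoff)

  ora_up <- ora_down <- NULL
  if (!is.null(config$go_gmt)) {
    db <- read_gmt(config$go_gmt)
    universe <- rownames(cohort$expression)
    up <- dge$table$feature[dge$table$fdr < config$dge_fdr_cutoff &
                              dge$table$coef > 0]
    down <- dge$table$feature[dge$table$fdr < config$dge_fdr_cutoff &
                                dge$table$coef < 0]
    ora_up <- run_stage("ora", ora_test(up, db, universe))
    ora_down <- run_stage("ora", ora_test(down, db, universe))
  }

  sets <- run_stage("geneset_construction",
    build_gene_sets(dmps, cohort$annotation,
                    exclude_genes = union(degs, config$exclude_genes)))
  message("geneset_construction: ", nrow(sets), " sets (",
          sum(sets$n_genes > 0), " non-empty)")

  roast_res <- run_stage("roast", {
    cfg <- config$roast
    cfg$seed <- derive_seed(config$seed, cfg$seed + 7L)
    X <- scan_design(cohort$expression, cohort$covariates, "exposure",
                     config$dge_covariates, config$dge_n_pcs)
    roast_all_sets(cohort$expression, X, "exposure", sets, cfg)
  })

  manifest <- tibble::tibble(
    stage = c("samples", "probes_input", "probes_retained", "genes",
              "dmps", "degs", "gene_sets", "nonempty_sets", "nrot", "seed"),
    count = c(ncol(beta), nrow(cohort$beta), nrow(beta),
              nrow(cohort$expression), nrow(dmps), length(degs),
              nrow(sets), sum(sets$n_genes > 0), config$roast$nrot,
              config$seed)
  )

  result <- structure(list(
    cohort = cohort, qc = qc_res$report, cell_proportions = cell_props,
    ewas = ewas, ewas_table = association_table(ewas, cohort$annotation),
    lambda = lambda, dmps = dmps,
    dge = dge, dge_table = association_table(dge),
    degs = degs, ora_up = ora_up, ora_down = ora_down,
    sets = sets, roast = roast_res, manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    write_pipeline_artifacts(result, config$output_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$ewas_table, file.path(dir, "ewas.tsv"))
  readr::write_tsv(result$dge_table, file.path(dir, "dge.tsv"))
  readr::write_tsv(result$dmps, file.path(dir, "dmps.tsv"))
  write_gmt(result$sets, file.path(dir, "gene_sets.gmt"))
  roast_flat <- dplyr::select(result$roast, -dplyr::any_of("members"),
                              -dplyr::any_of("provenance"))
  readr::write_tsv(roast_flat, file.path(dir, "roast.tsv"))
  if (!is.null(result$ora_up)) {
    readr::write_tsv(result$ora_up, file.path(dir, "ora_up.tsv"))
    readr::write_tsv(result$ora_down, file.path(dir, "ora_down.tsv"))
  }
  if (!is.null(result$cell_proportions)) {
    readr::write_tsv(
      tibble::as_tibble(result$cell_proportions, rownames = "sample"),
      file.path(dir, "cell_proportions.tsv"))
  }
  manifest <- result$manifest
  manifest$value <- format(manifest$count)
  writeLines(
    c(paste0("methroast\t", as.character(utils::packageVersion("methroast"))),
      paste0("R\t", R.version.string),
      paste(manifest$stage, manifest$value, sep = "\t")),
    file.path(dir, "run_manifest.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Integrative methylome/transcriptome pipeline result\n")
  print(x$manifest, n = nrow(x$manifest))
  cat("lambda (genomic inflation): ", round(x$lambda, 3), "\n", sep = "")
  invisible(x)
}
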