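#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the cohort structure the generator emulates: 1114
#' participants of whom 150 are exposed (daily smokers), planted methylation
#' differences on the beta scale within the range of reported genome-wide
#' significant effects (|coef| about 0.006-0.034), and small coordinated
#' log2-expression shifts in the genes of affected sets.
#'
#' @param n_samples Number of samples.
#' @param exposure_fraction Fraction of exposed samples, strictly in (0, 1).
#' @param n_genes Number of genes on the expression side (and annotated on
#'   the methylation side).
#' @param probes_per_gene Expected probes per gene (see
#'   [generate_annotation()]).
#' @param n_affected_per_region Affected (differentially methylated) probes
#'   per (region, direction) cell. Either a single count applied to every
#'   cell, or a named vector with names like `"Body_hypo"`, `"TSS200_hyper"`;
#'   cells not named get 0. Region labels are the seven array labels
#'   (`Promoter` is derived downstream, not planted directly).
#' @param delta_beta Planted exposure effect on the beta scale (positive
#'   magnitude; sign is taken from the direction of each cell).
#' @param delta_expr Planted log2 expression shift for genes linked to
#'   affected probes; genes linked to hypomethylated probes are shifted up
#'   by `delta_expr`, genes linked to hypermethylated probes down.
#' @param noise_sd_meth Logit-scale residual SD of methylation.
#' @param noise_sd_expr Log2-scale residual SD of expression.
#' @param confounder_effects Named vector of SDs of per-feature covariate
#'   coefficients (logit / log2 scale) for `age`, `sex`, `bmi`, `alcohol`.
#'   Covariates correlate with exposure, so nonzero values induce real
#'   confounding.
#' @param cell_mixing Optional named vector of Dirichlet concentrations per
#'   blood cell type; when supplied, sample-specific cell compositions are
#'   mixed into the methylation signal (default `NULL`: off).
#' @param seed Integer seed.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 1114,
                       exposure_fraction = 150 / 1114,
                       n_genes = 1000,
                       probes_per_gene = 10,
                       n_affected_per_region = 3,
                       delta_beta = 0.02,
                       delta_expr = 0.1,
                       noise_sd_meth = 0.3,
                       noise_sd_expr = 0.3,
                       confounder_effects = c(age = 0.003, sex = 0.05,
                                              bmi = 0.002, alcohol = 0.02),
                       cell_mixing = NULL,
                       seed = 1L) {
  if (exposure_fraction <= 0 || exposure_fraction >= 1) {
    stop_bad_arg("exposure_fraction must be strictly between 0 and 1")
  }
  if (n_samples < 2 || n_genes < 0 || any(n_affected_per_region < 0)) {
    stop_bad_arg("counts must be non-negative (and n_samples >= 2)")
  }
  if (noise_sd_meth <= 0 || noise_sd_expr <= 0) {
    stop_bad_arg("noise SDs must be positive")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    exposure_fraction = exposure_fraction,
    n_genes = as.integer(n_genes),
    probes_per_gene = probes_per_gene,
    n_affected_per_region = n_affected_per_region,
    delta_beta = abs(delta_beta),
    delta_expr = delta_expr,
    noise_sd_meth = noise_sd_meth,
    noise_sd_expr = noise_sd_expr,
    confounder_effects = confounder_effects,
    cell_mixing = cell_mixing,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# expand n_affected_per_region to a tibble(region, direction, n)
affected_cells <- function(spec) {
  cells <- tidyr::expand_grid(
    region = array_region_labels(),
    direction = c("hypo", "hyper")
  )
  if (length(spec) == 1L && is.null(names(spec))) {
    cells$n <- as.integer(spec)
  } else {
    key <- paste(cells$region, cells$direction, sep = "_")
    cells$n <- as.integer(spec[key])
    cells$n[is.na(cells$n)] <- 0L
  }
  cells
}

#' Generate a paired methylome/transcriptome cohort with known truth
#'
#' Methylation is generated on the logit scale as baseline + covariate
#' effects + optional cell-composition effect + exposure effect (applied only
#' to affected probes, signed by direction) + Gaussian noise, then
#' inverse-logit transformed (hence in (0, 1)). Expression is generated on
#' the log2 scale as baseline + covariate effects + exposure x `delta_expr`
#' on affected genes + noise. All planted effects are recorded in a truth
#' ledger.
#'
#' @param config A [sim_config()].
#' @param annotation Optional probe annotation from [generate_annotation()];
#'   generated from `config` when missing.
#'
#' @return A `simulated_cohort` list with elements `beta` (probe x sample),
#'   `expression` (gene x sample), `covariates` (tibble), `annotation`,
#'   `true_proportions` (sample x cell type, or `NULL`) and `truth` (ledger
#'   with `affected_cpgs`, `affected_genes` and per-feature null flags).
#' @export
generate_cohort <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(annotation)) {
    annotation <- generate_annotation(
      n_genes = config$n_genes,
      probes_per_gene = config$probes_per_gene,
      seed = derive_seed(config$seed, 1L)
    )
  }
  cells <- affected_cells(config$n_affected_per_region)

  with_seed(derive_seed(config$seed, 2L), {
    n <- config$n_samples
    sample_id <- sprintf("S%04d", seq_len(n))
    n_exposed <- max(1L, round(n * config$exposure_fraction))
    exposure <- c(rep(1L, n_exposed), rep(0L, n - n_exposed))

    covariates <- tibble::tibble(
      sample = sample_id,
      exposure = exposure,
      age = pmin(pmax(round(stats::rnorm(n, 41, 5)), 34), 49),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.54, 0.46)),
      bmi = round(stats::rnorm(n, 26.5, 4.8), 1),
      alcohol = round(pmax(stats::rnorm(n, 0.7 + 0.7 * exposure, 1.2), 0), 2),
      ses = ifelse(exposure == 1,
        sample(c("Low", "Medium", "High"), n, replace = TRUE,
               prob = c(0.29, 0.43, 0.28)),
        sample(c("Low", "Medium", "High"), n, replace = TRUE,
               prob = c(0.18, 0.39, 0.43))
      )
    )

    probes <- annotation_probes(annotation)
    p <- nrow(probes)
    if (p == 0) stop_bad_arg("annotation contains no probes")

    # bimodal baseline methylation typical of array data
    comp <- sample.int(3, p, replace = TRUE, prob = c(0.35, 0.35, 0.3))
    mu <- c(-2.5, 2.5, 0)[comp] + stats::rnorm(p, 0, c(0.8, 0.8, 1)[comp])

    # per-probe covariate coefficients (confounding: covariates correlate
    # with exposure by construction)
    ce <- config$confounder_effects
    cov_num <- cbind(
      age = covariates$age - mean(covariates$age),
      sex = as.numeric(covariates$sex == "M") - mean(covariates$sex == "M"),
      bmi = covariates$bmi - mean(covariates$bmi),
      alcohol = covariates$alcohol - mean(covariates$alcohol)
    )
    coef_meth <- vapply(colnames(cov_num), function(v) {
      stats::rnorm(p, 0, if (v %in% names(ce)) ce[[v]] else 0)
    }, numeric(p))

    logit_meth <- matrix(mu, p, n) + coef_meth %*% t(cov_num)

    # optional cell-composition confounding
    true_proportions <- NULL
    if (!is.null(config$cell_mixing)) {
      conc <- config$cell_mixing
      k <- length(conc)
      w <- matrix(stats::rgamma(n * k, shape = rep(conc, each = n)), n, k)
      w <- w / rowSums(w)
      dimnames(w) <- list(sample_id, names(conc))
      profile_dev <- matrix(stats::rnorm(p * k, 0, 0.3), p, k)
      logit_meth <- logit_meth + profile_dev %*% t(w - matrix(colMeans(w), n, k, byrow = TRUE))
      true_proportions <- w
    }

    # plant exposure effects probe-by-probe: the logit shift that moves the
    # baseline beta by +/- delta_beta, so the ledger effect is on beta scale
    cells <- cells[cells$n > 0, , drop = FALSE]
    affected <- NULL
    if (nrow(cells) > 0) {
      linked <- annotation[!is.na(annotation$gene), ]
      taken <- character(0)
      picks <- vector("list", nrow(cells))
      for (i in seq_len(nrow(cells))) {
        pool <- unique(linked$probe[linked$region == cells$region[i]])
        pool <- setdiff(pool, taken)
        if (length(pool) < cells$n[i]) {
          stop_bad_arg("not enough probes for cell (", cells$region[i], ", ",
                       cells$direction[i], "): need ", cells$n[i],
                       ", have ", length(pool))
        }
        chosen <- sample(pool, cells$n[i])
        taken <- c(taken, chosen)
        picks[[i]] <- tibble::tibble(
          probe = chosen, region = cells$region[i],
          direction = cells$direction[i]
        )
      }
      affected <- dplyr::bind_rows(picks)
    }

    shift <- numeric(p)
    names(shift) <- probes$probe
    if (!is.null(affected)) {
      idx <- match(affected$probe, probes$probe)
      b0 <- inv_logit(mu[idx])
      sgn <- ifelse(affected$direction == "hypo", -1, 1)
      target <- pmin(pmax(b0 + sgn * config$delta_beta, 1e-4), 1 - 1e-4)
      shift[idx] <- logit(target) - logit(b0)
      affected$delta_beta <- sgn * config$delta_beta
    }

    logit_meth <- logit_meth + outer(shift, as.numeric(exposure)) +
      matrix(stats::rnorm(p * n, 0, config$noise_sd_meth), p, n)
    beta <- inv_logit(logit_meth)
    beta <- pmin(pmax(beta, 0), 1)
    dimnames(beta) <- list(probes$probe, sample_id)

    # expression: genes linked to hypomethylated probes shift up
    expression <- NULL
    affected_genes <- tibble::tibble(gene = character(0), delta_expr = numeric(0))
    if (config$n_genes > 0) {
      genes <- sort(unique(annotation$gene[!is.na(annotation$gene)]))
      g <- length(genes)
      base_expr <- stats::rnorm(g, 8, 1.5)
      coef_expr <- vapply(colnames(cov_num), function(v) {
        stats::rnorm(g, 0, if (v %in% names(ce)) ce[[v]] else 0)
      }, numeric(g))
      gene_delta <- numeric(g)
      names(gene_delta) <- genes
      if (!is.null(affected)) {
        link <- annotation[!is.na(annotation$gene) &
                             annotation$probe %in% affected$probe, ]
        link <- dplyr::left_join(link,
          dplyr::distinct(affected, .data$probe, .data$direction),
          by = "probe")
        per_gene <- dplyr::summarise(dplyr::group_by(link, .data$gene),
          up = any(.data$direction == "hypo"), .groups = "drop")
        gene_delta[per_gene$gene] <- ifelse(per_gene$up, 1, -1) * config$delta_expr
        affected_genes <- tibble::tibble(
          gene = per_gene$gene,
          delta_expr = unname(gene_delta[per_gene$gene])
        )
      }
      expression <- matrix(base_expr, g, n) + coef_expr %*% t(cov_num) +
        outer(gene_delta, as.numeric(exposure)) +
        matrix(stats::rnorm(g * n, 0, config$noise_sd_expr), g, n)
      dimnames(expression) <- list(genes, sample_id)
    }

    if (!is.null(affected)) {
      # realized mean group difference on the beta scale
      diff <- rowMeans(beta[affected$probe, exposure == 1, drop = FALSE]) -
        rowMeans(beta[affected$probe, exposure == 0, drop = FALSE])
      affected$realized_beta_diff <- unname(diff)
      link_genes <- dplyr::summarise(
        dplyr::group_by(annotation[!is.na(annotation$gene), ], .data$probe),
        gene = paste(.data$gene, collapse = ";"), .groups = "drop")
      affected <- dplyr::left_join(affected, link_genes, by = "probe")
      affected <- dplyr::select(affected, "probe", "gene", "region",
                                "direction", "delta_beta",
                                "realized_beta_diff")
    } else {
      affected <- tibble::tibble(
        probe = character(0), gene = character(0), region = character(0),
        direction = character(0), delta_beta = numeric(0),
        realized_beta_diff = numeric(0)
      )
    }

    truth <- list(
      affected_cpgs = affected,
      affected_genes = affected_genes,
      probes = tibble::tibble(
        probe = probes$probe,
        affected = probes$probe %in% affected$probe
      ),
      genes = tibble::tibble(
        gene = if (is.null(expression)) character(0) else rownames(expression),
        affected = if (is.null(expression)) logical(0) else
          rownames(expression) %in% affected_genes$gene
      )
    )

    structure(list(
      beta = beta,
      expression = expression,
      covariates = covariates,
      annotation = annotation,
      true_proportions = true_proportions,
      truth = truth,
      config = config
    ), class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated methylome/transcriptome cohort\n")
  cat("  samples:    ", ncol(x$beta),
      " (", sum(x$covariates$exposure), " exposed)\n", sep = "")
  cat("  CpG probes: ", nrow(x$beta), "\n", sep = "")
  cat("  genes:      ", if (is.null(x$expression)) 0 else nrow(x$expression),
      "\n", sep = "")
  cat("  planted DMPs: ", nrow(x$truth$affected_cpgs),
      "; affected genes: ", nrow(x$truth$affected_genes), "\n", sep = "")
  invisible(x)
}

#' Export a simulated cohort as TSV files
#'
#' Writes five data files (`beta.tsv`, `expression.tsv`, `covariates.tsv`,
#' `annotation.tsv`, `truth.tsv`) plus a `manifest.txt` listing the files and
#' the generator seed. Matrices are written with the feature identifier as
#' the first column. The export round-trips through [read_cohort()].
#'
#' @param cohort A `simulated_cohort`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the manifest as a character vector of file paths.
#' @export
export_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (ncol(cohort$beta) == 0 || nrow(cohort$covariates) == 0) {
    stop_bad_arg("refusing to export a cohort with 0 samples")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)

  write_matrix <- function(M, path, id_col) {
    df <- tibble::as_tibble(M, rownames = id_col)
    readr::write_tsv(df, path)
  }
  files <- c(
    beta = "beta.tsv", expression = "expression.tsv",
    covariates = "covariates.tsv", annotation = "annotation.tsv",
    truth = "truth.tsv"
  )
  write_matrix(cohort$beta, file.path(directory, files["beta"]), "probe")
  write_matrix(cohort$expression, file.path(directory, files["expression"]), "gene")
  readr::write_tsv(cohort$covariates, file.path(directory, files["covariates"]))
  readr::write_tsv(cohort$annotation, file.path(directory, files["annotation"]))

  truth_long <- dplyr::bind_rows(
    dplyr::mutate(cohort$truth$affected_cpgs, feature_type = "probe",
                  delta = .data$delta_beta),
    dplyr::mutate(cohort$truth$affected_genes, feature_type = "gene",
                  probe = NA_character_, region = NA_character_,
                  direction = NA_character_, delta = .data$delta_expr,
                  realized_beta_diff = NA_real_)
  )
  truth_long <- dplyr::select(truth_long, "feature_type", "probe", "gene",
                              "region", "direction", "delta",
                              "realized_beta_diff")
  readr::write_tsv(truth_long, file.path(directory, files["truth"]))

  manifest <- file.path(directory, "manifest.txt")
  writeLines(c(
    paste0("seed\t", cohort$config$seed),
    paste0("file\t", unname(files))
  ), manifest)
  invisible(file.path(directory, unname(files)))
}

#' Read back a cohort exported with [export_cohort()]
#'
#' @param directory Directory containing the exported TSV files.
#' @return A list with `beta`, `expression`, `covariates`, `annotation` and
#'   `truth` (the long-format ledger), numeric values at TSV print precision.
#' @export
read_cohort <- function(directory) {
  read_matrix <- function(path, id_col) {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    M <- as.matrix(df[, -1])
    rownames(M) <- df[[id_col]]
    M
  }
  list(
    beta = read_matrix(file.path(directory, "beta.tsv"), "probe"),
    expression = read_matrix(file.path(directory, "expression.tsv"), "gene"),
    covariates = readr::read_tsv(file.path(directory, "covariates.tsv"),
                                 show_col_types = FALSE),
    annotation = readr::read_tsv(file.path(directory, "annotation.tsv"),
                                 show_col_types = FALSE),
    truth = readr::read_tsv(file.path(directory, "truth.tsv"),
                            show_col_types = FALSE)
  )
}
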