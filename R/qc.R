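#' Quality-control configuration
#'
#' @param detection_p_threshold Per-measurement detection p-value threshold
#'   (default 0.01).
#' @param probe_fail_sample_fraction A probe is removed when its detection
#'   p-value exceeds the threshold in more than this fraction of samples
#'   (default 0.01).
#' @param sample_detection_rule Aggregate rule for sample filtering:
#'   `"mean"` (default) retains samples whose mean detection p-value is
#'   below `sample_detection_threshold`; `"sum"` applies the same rule to
#'   the sum across probes.
#' @param sample_detection_threshold Threshold for the aggregate statistic
#'   (default 0.01).
#' @param cross_reactive Character vector of cross-reactive probe ids to
#'   drop (may be empty).
#' @param snp_probes Character vector of SNP-overlapping probe ids to drop.
#' @param autosomes_only Drop probes on chrX/chrY when the annotation
#'   contains any (default `TRUE`).
#' @return A `qc_config` list.
#' @export
qc_config <- function(detection_p_threshold = 0.01,
                      probe_fail_sample_fraction = 0.01,
                      sample_detection_rule = c("mean", "sum"),
                      sample_detection_threshold = 0.01,
                      cross_reactive = character(0),
                      snp_probes = character(0),
                      autosomes_only = TRUE) {
  if (detection_p_threshold <= 0 || detection_p_threshold >= 1) {
    stop_bad_arg("detection_p_threshold must be in (0, 1)")
  }
  if (probe_fail_sample_fraction < 0 || probe_fail_sample_fraction > 1) {
    stop_bad_arg("probe_fail_sample_fraction must be in [0, 1]")
  }
  structure(list(
    detection_p_threshold = detection_p_threshold,
    probe_fail_sample_fraction = probe_fail_sample_fraction,
    sample_detection_rule = match.arg(sample_detection_rule),
    sample_detection_threshold = sample_detection_threshold,
    cross_reactive = cross_reactive,
    snp_probes = snp_probes,
    autosomes_only = autosomes_only
  ), class = "qc_config")
}

#' Methylation beta value from probe intensities
#'
#' The beta value is the ratio of the methylated intensity to the total
#' intensity, `meth / (meth + unmeth + offset)`; the offset stabilises the
#' ratio at low total intensity. Vectorised.
#'
#' @param meth,unmeth Non-negative methylated / unmethylated intensities.
#' @param offset Non-negative stabilising offset (default 100).
#' @return Beta values in \[0, 1\].
#' @export
#' @examples
#' compute_beta(600, 200, 100)
compute_beta <- function(meth, unmeth, offset = 100) {
  if (any(meth < 0) || any(unmeth < 0) || any(offset < 0)) {
    stop_bad_arg("intensities and offset must be non-negative")
  }
  denom <- meth + unmeth + offset
  if (any(denom == 0)) {
    stop_bad_arg("beta undefined: meth + unmeth + offset is zero")
  }
  meth / denom
}

#' Probe-level quality filtering
#'
#' Removes probes that (in this order, each probe counted once under its
#' first matching reason): fail detection in more than the allowed fraction
#' of samples, lie on a sex chromosome, appear in the cross-reactive
#' blacklist, or appear in the SNP blacklist. The retained set is the
#' intersection of all pass criteria; the fixed order only determines which
#' reason is reported.
#'
#' @param beta Probe x sample beta matrix.
#' @param detection_p Detection p-value matrix aligned to `beta`.
#' @param annotation Probe annotation tibble (see [generate_annotation()]).
#' @param config A [qc_config()].
#' @return A list with `retained` (probe ids), `beta` (filtered matrix) and
#'   `report` (tibble of excluded probe, reason).
#' @export
filter_probes <- function(beta, detection_p, annotation, config = qc_config()) {
  check_matrix(beta, "beta")
  if (!identical(dim(beta), dim(detection_p)) ||
      !identical(rownames(beta), rownames(detection_p)) ||
      !identical(colnames(beta), colnames(detection_p))) {
    stop_bad_arg("detection_p is not aligned to beta (dimnames must match)")
  }
  fail_frac <- rowMeans(detection_p > config$detection_p_threshold)
  fail_det <- fail_frac > config$probe_fail_sample_fraction

  probe_chrom <- annotation_probes(annotation)
  chrom <- probe_chrom$chrom[match(rownames(beta), probe_chrom$probe)]
  on_sex <- config$autosomes_only & !is.na(chrom) & chrom %in% c("chrX", "chrY")

  in_xr <- rownames(beta) %in% config$cross_reactive
  in_snp <- rownames(beta) %in% config$snp_probes

  reason <- rep(NA_character_, nrow(beta))
  reason[in_snp] <- "snp"
  reason[in_xr] <- "cross-reactive"
  reason[on_sex] <- "sex-chromosome"
  reason[fail_det] <- "detection"

  keep <- is.na(reason)
  list(
    retained = rownames(beta)[keep],
    beta = beta[keep, , drop = FALSE],
    report = tibble::tibble(
      probe = rownames(beta)[!keep],
      reason = reason[!keep]
    )
  )
}

#' Sample-level quality filtering
#'
#' Retains samples whose aggregate detection statistic (mean of detection
#' p-values by default, sum if configured) is below the configured
#' threshold.
#'
#' @param detection_p Probe x sample detection p-value matrix.
#' @param config A [qc_config()].
#' @return A list with `retained` (sample ids) and `report` (tibble of
#'   excluded sample, statistic).
#' @export
filter_samples <- function(detection_p, config = qc_config()) {
  if (!is.matrix(detection_p) || length(detection_p) == 0) {
    stop_bad_arg("detection_p must be a non-empty matrix")
  }
  stat <- switch(config$sample_detection_rule,
    mean = colMeans(detection_p),
    sum = colSums(detection_p)
  )
  keep <- stat < config$sample_detection_threshold
  list(
    retained = colnames(detection_p)[keep],
    report = tibble::tibble(
      sample = colnames(detection_p)[!keep],
      statistic = unname(stat[!keep]),
      rule = config$sample_detection_rule
    )
  )
}
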