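# Shared fixture builders; all randomness goes through explicit seeds.

two_group_design <- function(n) {
  cbind(intercept = 1, exposure = rep(0:1, each = n / 2))
}

# gene x sample null expression matrix, optionally with exchangeable
# inter-gene correlation rho (shared per-sample component)
null_expression <- function(g, n, rho = 0, seed = 1) {
  methroast:::with_seed(seed, {
    shared <- rnorm(n)
    E <- sqrt(rho) * matrix(shared, g, n, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(g * n), g, n) + 8
    dimnames(E) <- list(sprintf("G%03d", seq_len(g)),
                        sprintf("s%03d", seq_len(n)))
    E
  })
}

small_cohort <- function(seed = 42, ...) {
  cfg <- sim_config(n_samples = 80, n_genes = 40, probes_per_gene = 8,
                    seed = seed, ...)
  generate_cohort(cfg)
}

# hand-rolled BH step-up, the independent oracle for bh_fdr()
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
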