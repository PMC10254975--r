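test_that("an exact linear trend fits with zero residual variance", {
  Y <- matrix(c(1, 2, 3), 1, 3, dimnames = list("f1", c("a", "b", "c")))
  X <- cbind(intercept = 1, x = c(0, 1, 2))
  fit <- fit_feature_lm(Y, X, coef = "x")
  tab <- tidy(fit)
  expect_equal(tab$coef, 1)
  expect_lt(tab$sigma, 1e-12)
  expect_true(tab$zero_variance)
})

test_that("intercept-only fits summarise the row mean", {
  Y <- matrix(rnorm(30), 3, 10,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:10)))
  fit <- fit_feature_lm(Y, matrix(1, 10, 1, dimnames = list(NULL, "intercept")))
  tab <- tidy(fit)
  expect_true(all(is.na(tab$coef)))
  expect_equal(tab$sigma, unname(apply(Y, 1, sd)))
  expect_equal(tab$df, rep(9L, 3))
})

test_that("coefficients and SEs match the normal-equations oracle", {
  methroast:::with_seed(101, {
    for (rep in 1:3) {
      Y <- matrix(rnorm(50 * 20), 50, 20,
                  dimnames = list(paste0("f", 1:50), paste0("s", 1:20)))
      X <- cbind(intercept = 1, exposure = rep(0:1, 10),
                 age = rnorm(20), bmi = rnorm(20))
      fit <- tidy(fit_feature_lm(Y, X, coef = "exposure"))
      xtx_inv <- solve(t(X) %*% X)
      B <- xtx_inv %*% t(X) %*% t(Y)
      res <- t(Y) - X %*% B
      s2 <- colSums(res^2) / (20 - 4)
      expect_equal(fit$coef, unname(B["exposure", ]), tolerance = 1e-10)
      expect_equal(fit$se, unname(sqrt(s2 * xtx_inv["exposure", "exposure"])),
                   tolerance = 1e-10)
    }
  })
})

test_that("rank-deficient designs fail naming the collinear column", {
  Y <- matrix(rnorm(20), 2, 10,
              dimnames = list(c("f1", "f2"), paste0("s", 1:10)))
  X <- cbind(intercept = 1, a = 1:10, b = 2 * (1:10))
  expect_error(fit_feature_lm(Y, X, "a"), "rank deficient.*b")
})

test_that("features with missing values are dropped and reported", {
  Y <- matrix(rnorm(30), 3, 10,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:10)))
  Y[2, 4] <- NA
  fit <- fit_feature_lm(Y, two_group_design(10), "exposure")
  expect_identical(fit$dropped, "f2")
  expect_identical(tidy(fit)$feature, c("f1", "f3"))
})

test_that("moderation collapses to ordinary t at d0 = 0 and pools at d0 = Inf", {
  Y <- null_expression(30, 12, seed = 2)
  X <- two_group_design(12)
  fit <- fit_feature_lm(Y, X, "exposure")
  tab <- tidy(fit)

  mod0 <- ebayes_moderate(fit, prior_df = 0, prior_var = 1)
  expect_equal(mod0$table$t, tab$coef / tab$se, tolerance = 1e-12)

  modInf <- ebayes_moderate(fit, prior_df = Inf, prior_var = 0.7)
  expect_equal(modInf$table$s2_post, rep(0.7, 30))
  # posterior variance lies between s^2 and s0^2 in general
  mod <- ebayes_moderate(fit)
  lo <- pmin(tab$sigma^2, mod$prior_var)
  hi <- pmax(tab$sigma^2, mod$prior_var)
  expect_true(all(mod$table$s2_post >= lo - 1e-12 &
                    mod$table$s2_post <= hi + 1e-12))
})

test_that("moderated statistics agree with the reference implementation", {
  skip_if_not_installed("limma")
  methroast:::with_seed(33, {
    G <- 400; n <- 10
    sigma2 <- 1.5 * 5 / rchisq(G, 5)
    Y <- matrix(rnorm(G * n, 0, rep(sqrt(sigma2), n)), G, n,
                dimnames = list(paste0("f", 1:G), paste0("s", 1:n)))
    X <- two_group_design(n)
    mod <- ebayes_moderate(fit_feature_lm(Y, X, "exposure"))
    ref <- limma::eBayes(limma::lmFit(Y, X))
    expect_equal(mod$prior_df, ref$df.prior, tolerance = 1e-6)
    expect_equal(mod$prior_var, ref$s2.prior, tolerance = 1e-6)
    expect_equal(mod$table$t, unname(ref$t[, "exposure"]), tolerance = 1e-8)
    expect_equal(mod$table$p, unname(ref$p.value[, "exposure"]),
                 tolerance = 1e-8)
  })
})

test_that("|moderated t| increases with |coefficient| at fixed variance", {
  Y <- null_expression(20, 12, seed = 5)
  X <- two_group_design(12)
  fit <- fit_feature_lm(Y, X, "exposure")
  mod <- ebayes_moderate(fit)
  scaled <- fit
  scaled$table$coef <- fit$table$coef * 3
  mod3 <- ebayes_moderate(scaled, prior_df = mod$prior_df,
                          prior_var = mod$prior_var)
  expect_true(all(abs(mod3$table$t) >= abs(mod$table$t)))
})

test_that("BH adjustment follows step-up and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  methroast:::with_seed(8, {
    p <- runif(237)
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup_oracle(p))
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  })
})

test_that("the genomic inflation factor is calibrated and handles edge cases", {
  n <- 2000
  expect_equal(genomic_inflation((seq_len(n) - 0.5) / n), 1, tolerance = 1e-3)
  expect_equal(genomic_inflation(rep(0.5, 11)), 1)
  expect_warning(lam <- genomic_inflation(c(0, 0.5)), "infinite")
  expect_identical(lam, Inf)
  expect_error(genomic_inflation(numeric(0)), "non-empty")
})

test_that("PCA scores are deterministic, orthogonal and complete", {
  methroast:::with_seed(13, {
    # rank-1 matrix: one component carries all variance
    u <- rnorm(30); v <- rnorm(12)
    M1 <- outer(u, v)
    dimnames(M1) <- list(paste0("f", 1:30), paste0("s", 1:12))
    M1c <- M1 - rowMeans(M1)
    s1 <- pca_scores(M1, 2)
    expect_equal(sum(s1[, 1]^2) / sum(M1c^2), 1, tolerance = 1e-10)

    M <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = dimnames(M1))
    k <- 11
    sc <- pca_scores(M, k)
    gram <- crossprod(sc)
    expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
    # completeness: row-centering leaves rank <= n - 1, so n - 1 components
    # carry the full centered sum of squares
    Mc <- M - rowMeans(M)
    expect_equal(sum(sc^2), sum(Mc^2), tolerance = 1e-10)
    # deterministic including sign
    expect_identical(sc, pca_scores(M, k))
    expect_error(pca_scores(M, 13), "between 1 and")
  })
})

test_that("a null moderated scan is calibrated", {
  co <- generate_cohort(sim_config(
    n_samples = 100, n_genes = 40, probes_per_gene = 6,
    n_affected_per_region = 0, delta_expr = 0,
    confounder_effects = c(age = 0), seed = 21))
  mod <- moderated_scan(co$beta, co$covariates,
                        adjust = c("age", "sex", "bmi", "alcohol", "ses"))
  expect_gt(stats::ks.test(mod$table$p, "punif")$p.value, 0.01)
  rej <- mean(mod$table$p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / nrow(mod$table))
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})
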