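test_that("ANOVA decomposition matches the brute-force oracle on F1", {
  F1 <- fixture_F1()
  ms <- anova_decompose(F1)

  # frozen values computed with the loop oracle
  expect_equal(ms$ss_subject, 351.1666666667, tolerance = 1e-10)
  expect_equal(ms$ss_rater, 60.75, tolerance = 1e-10)
  expect_equal(ms$ss_interaction, 0.5, tolerance = 1e-10)
  expect_equal(ms$ss_error, 16.5, tolerance = 1e-10)
  expect_equal(
    unlist(ms[c("df_subject", "df_rater", "df_interaction", "df_error")]),
    c(df_subject = 2, df_rater = 1, df_interaction = 2, df_error = 6)
  )

  oracle <- brute_ss(F1)
  expect_equal(
    c(
      ss_subject = ms$ss_subject, ss_rater = ms$ss_rater,
      ss_interaction = ms$ss_interaction, ss_error = ms$ss_error
    ),
    oracle,
    tolerance = 1e-10
  )
})

test_that("sums of squares: zero on constants, translation invariant, additive", {
  const <- array(17, c(4, 3, 2))
  ms <- anova_decompose(const)
  expect_equal(
    c(ms$ss_subject, ms$ss_rater, ms$ss_interaction, ms$ss_error),
    c(0, 0, 0, 0)
  )

  F1 <- fixture_F1()
  shifted <- anova_decompose(F1 + 10)
  orig <- anova_decompose(F1)
  for (f in c("ss_subject", "ss_rater", "ss_interaction", "ss_error")) {
    expect_equal(shifted[[f]], orig[[f]], tolerance = 1e-9)
  }

  for (s in 1:20) {
    Y <- random_design_array(s)
    msr <- anova_decompose(Y)
    total <- sum((Y - mean(Y))^2)
    expect_equal(
      msr$ss_subject + msr$ss_rater + msr$ss_interaction + msr$ss_error,
      total,
      tolerance = 1e-8 * total
    )
    expect_equal(brute_ss(Y)[["ss_error"]], msr$ss_error, tolerance = 1e-8)
  }
})

test_that("MS and coefficients are invariant to label permutation and scale", {
  Y <- random_design_array(101, n = 7, k = 4, m = 3)
  base_ms <- anova_decompose(Y)
  base_rho <- reliability_point(estimate_components(base_ms))

  perm <- Y[sample(7), , , drop = FALSE]
  perm <- perm[, sample(4), , drop = FALSE]
  ms_p <- anova_decompose(perm)
  for (f in c("ms_subject", "ms_rater", "ms_interaction", "ms_error")) {
    expect_equal(ms_p[[f]], base_ms[[f]], tolerance = 1e-9)
  }

  scaled_rho <- reliability_point(estimate_components(anova_decompose(Y * 3)))
  expect_equal(scaled_rho, base_rho, tolerance = 1e-10)
})

test_that("variance components match MoM truncation rules and oracles", {
  # all mean squares equal: everything but error truncates to zero
  flat <- structure(
    list(
      n = 5, k = 3, m = 2,
      ms_subject = 4, ms_rater = 4, ms_interaction = 4, ms_error = 4
    ),
    class = "mean_squares"
  )
  vc <- estimate_components(flat)
  expect_equal(vc$sigma2_subject, 0)
  expect_equal(vc$sigma2_rater, 0)
  expect_equal(vc$sigma2_interaction, 0)
  expect_equal(vc$sigma2_error, 4)

  for (s in 1:20) {
    Y <- random_design_array(s)
    vc <- estimate_components(anova_decompose(Y))
    expect_equal(
      c(
        sigma2_subject = vc$sigma2_subject, sigma2_rater = vc$sigma2_rater,
        sigma2_interaction = vc$sigma2_interaction,
        sigma2_error = vc$sigma2_error
      ),
      brute_components(Y),
      tolerance = 1e-8
    )
  }
})

test_that("components agree with a REML mixed-model fit on balanced data", {
  skip_if_not_installed("lme4")
  checked <- 0
  for (s in 1:12) {
    Y <- random_design_array(s, n = 10, k = 4, m = 3)
    vc <- estimate_components(anova_decompose(Y))
    est <- c(
      vc$sigma2_subject, vc$sigma2_rater, vc$sigma2_interaction,
      vc$sigma2_error
    )
    if (any(est[1:3] < 0.05)) next # skip fixtures where truncation binds
    df <- expand.grid(i = factor(1:10), j = factor(1:4), l = 1:3)
    df$y <- as.vector(Y)
    fit <- lme4::lmer(
      y ~ 1 + (1 | i) + (1 | j) + (1 | i:j),
      data = df, REML = TRUE,
      control = lme4::lmerControl(
        optimizer = "bobyqa",
        optCtrl = list(rhobeg = 0.2, rhoend = 1e-12),
        check.conv.singular = "ignore"
      )
    )
    vcl <- as.data.frame(lme4::VarCorr(fit))
    reml <- c(
      vcl$vcov[vcl$grp == "i"], vcl$vcov[vcl$grp == "j"],
      vcl$vcov[vcl$grp == "i:j"], vcl$vcov[vcl$grp == "Residual"]
    )
    expect_equal(est, reml, tolerance = 1e-5)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("components are recovered from a large simulated table", {
  tbl <- simulate_ratings(
    n = 800, k = 4, m = 3, mu = 50, total_var = 8,
    rho_inter = 0.5, rho_intra = 0.75, seed = 77
  ) # components (4, 1, 1, 2)
  vc <- estimate_components(anova_decompose(extract_balanced(tbl, "A")))
  expect_equal(vc$sigma2_subject, 4, tolerance = 0.15)
  expect_equal(vc$sigma2_error, 2, tolerance = 0.1)
  expect_equal(vc$sigma2_interaction, 1, tolerance = 0.15)
  # only k-1 = 3 df inform the rater component: wide Monte-Carlo band
  expect_lt(abs(vc$sigma2_rater - 1), 1.5)
})

test_that("reliability_point follows its defining arithmetic", {
  expect_equal(
    reliability_point(components_from_targets(0.5, 0.75, 8)),
    c(rho_inter = 0.5, rho_intra = 0.75)
  )
  perfect <- components_from_targets(1, 1, 4)
  expect_equal(
    reliability_point(perfect),
    c(rho_inter = 1, rho_intra = 1)
  )
  nosubj <- structure(
    list(
      sigma2_subject = 0, sigma2_rater = 1, sigma2_interaction = 1,
      sigma2_error = 2
    ),
    class = "variance_components"
  )
  expect_equal(reliability_point(nosubj), c(rho_inter = 0, rho_intra = 0.5))
  zero <- structure(
    list(
      sigma2_subject = 0, sigma2_rater = 0, sigma2_interaction = 0,
      sigma2_error = 0
    ),
    class = "variance_components"
  )
  expect_error(reliability_point(zero), class = "ki67agree_degenerate_data_error")
})

test_that("intra bound matches an independent evaluation of the F interval", {
  F1 <- fixture_F1()
  ms <- anova_decompose(F1)

  # frozen value from the formula oracle (separately sourced F quantile)
  expect_equal(intra_lower_bound(ms, 0.05), 0.7447815, tolerance = 1e-6)

  # recompute from scratch in the test
  nk <- 6
  m <- 2
  F_obs <- ((ms$ss_subject + ms$ss_rater + ms$ss_interaction) / (nk - 1)) /
    (ms$ss_error / (nk * (m - 1)))
  F_L <- F_obs / qf(0.95, nk - 1, nk * (m - 1))
  expect_equal(intra_lower_bound(ms, 0.05), (F_L - 1) / (F_L + m - 1),
    tolerance = 1e-12
  )

  # monotone in alpha; perfect replicate agreement gives bound 1
  expect_gte(intra_lower_bound(ms, 0.10), intra_lower_bound(ms, 0.05))
  perfect <- anova_decompose(array(rep(c(10, 20, 30), 4), c(3, 2, 2)))
  expect_equal(perfect$ms_error, 0)
  expect_equal(intra_lower_bound(perfect), 1)
  expect_equal(intra_pvalue(perfect), 0)
})

test_that("intra p-value and bound are dual across a fixture grid", {
  # p <= alpha exactly when the (1 - alpha) lower bound >= rho0
  for (s in 1:8) {
    Y <- random_design_array(s, n = 6, k = 3, m = 2)
    ms <- anova_decompose(Y)
    for (rho0 in c(0.3, 0.6, 0.8, 0.95)) {
      for (alpha in c(0.05, 0.2)) {
        p <- intra_pvalue(ms, rho0)
        bound <- intra_lower_bound(ms, alpha)
        expect_equal(p <= alpha, bound >= rho0)
      }
    }
  }
})

test_that("intra p-value behaves at the limits", {
  tbl <- simulate_ratings(
    n = 100, k = 4, m = 3, mu = 50, total_var = 100,
    rho_inter = 0.8, rho_intra = 0.95, seed = 15
  )
  ms <- anova_decompose(extract_balanced(tbl, "A"))
  expect_lt(intra_pvalue(ms, 0.6), 1e-6) # true rho_intra far above 0.6
  expect_lt(intra_pvalue(ms, 0), 1e-10)
  expect_gt(intra_pvalue(ms, 0.99), 0.999)
})

test_that("inter bootstrap bound is deterministic and below the point estimate", {
  tbl <- simulate_ratings(
    n = 50, k = 4, m = 3, mu = 50, total_var = 100,
    rho_inter = 0.7, rho_intra = 0.85, seed = 23
  )
  design <- extract_balanced(tbl, "A")
  b1 <- inter_lower_bound(design, alpha = 0.05, B = 500, seed = 9)
  b2 <- inter_lower_bound(design, alpha = 0.05, B = 500, seed = 9)
  expect_identical(b1, b2)

  point <- reliability_point(estimate_components(anova_decompose(design)))
  expect_lt(b1, point[["rho_inter"]])

  p1 <- inter_pvalue(design, rho0 = 0.6, B = 500, seed = 9)
  p2 <- inter_pvalue(design, rho0 = 0.6, B = 500, seed = 9)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lt(p1, 1)

  flat <- array(5, c(10, 3, 2))
  expect_error(
    inter_lower_bound(flat, B = 500, seed = 1),
    class = "ki67agree_degenerate_data_error"
  )
})

test_that("estimate_reliability assembles a coherent fit", {
  tbl <- simulate_ratings(n = 30, k = 4, m = 3, seed = 41)
  design <- extract_balanced(tbl, "A")
  fit <- estimate_reliability(design, B = 500, seed = 3)
  expect_s3_class(fit, "reliability_fit")
  expect_lte(fit$rho_inter, fit$rho_intra)
  expect_lte(fit$lower_intra, fit$rho_intra)
  expect_lt(fit$lower_inter, fit$rho_inter)

  td <- tidy(fit)
  expect_equal(td$coefficient, c("rho_inter", "rho_intra"))
  expect_equal(td$estimate, c(fit$rho_inter, fit$rho_intra))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$method, "A")
})
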