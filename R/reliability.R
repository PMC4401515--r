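#' Two-way crossed ANOVA decomposition with replicates
#'
#' Decomposes the total sum of squares of a balanced subjects x raters x
#' repetitions array into subject, rater, subject-by-rater interaction, and
#' replicate-error components, the variance analysis underlying simultaneous
#' inter-/intra-observer reliability estimation.
#'
#' @param design A `balanced_design` from [extract_balanced()], or an
#'   n x k x m numeric array.
#' @return A `mean_squares` object: list with design sizes `n`, `k`, `m`,
#'   sums of squares `ss_subject`, `ss_rater`, `ss_interaction`, `ss_error`,
#'   degrees of freedom `df_*`, and mean squares `ms_*`.
#' @export
#' @examples
#' design <- extract_balanced(simulate_ratings(n = 6, k = 3, m = 2, seed = 1), "A")
#' anova_decompose(design)
anova_decompose <- function(design) {
  values <- design_values(design)
  dims <- dim(values)
  n <- dims[1]
  k <- dims[2]
  m <- dims[3]
  if (m < 2) {
    abort_ki67(
      "At least 2 repetitions are required (replicate error term undefined).",
      "ki67agree_insufficient_design_error"
    )
  }
  ss <- ss_decompose_multi(matrix(as.vector(values), ncol = 1), n, k, m)
  df <- list(
    df_subject = n - 1, df_rater = k - 1,
    df_interaction = (n - 1) * (k - 1), df_error = n * k * (m - 1)
  )
  structure(
    c(
      list(n = n, k = k, m = m),
      lapply(ss, as.numeric), df,
      list(
        ms_subject = ss$ss_subject / df$df_subject,
        ms_rater = ss$ss_rater / df$df_rater,
        ms_interaction = ss$ss_interaction / df$df_interaction,
        ms_error = ss$ss_error / df$df_error
      )
    ),
    class = "mean_squares"
  )
}

design_values <- function(design) {
  if (inherits(design, "balanced_design")) {
    return(design$values)
  }
  if (is.array(design) && length(dim(design)) == 3) {
    return(design)
  }
  abort_ki67(
    "Expected a balanced_design or an n x k x m array.",
    "ki67agree_validation_error"
  )
}

#' @export
print.mean_squares <- function(x, ...) {
  cat(sprintf(
    "<mean_squares> n=%d k=%d m=%d\n", x$n, x$k, x$m
  ))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.mean_squares <- function(x, ...) {
  tibble::tibble(
    term = c("subject", "rater", "interaction", "error"),
    df = c(x$df_subject, x$df_rater, x$df_interaction, x$df_error),
    sumsq = c(x$ss_subject, x$ss_rater, x$ss_interaction, x$ss_error),
    meansq = c(x$ms_subject, x$ms_rater, x$ms_interaction, x$ms_error)
  )
}

#' Method-of-moments variance components from mean squares
#'
#' Inverts the expected mean squares of the balanced two-way crossed model
#' with replicates; negative estimates are truncated at zero so the
#' reliability coefficients stay in \[0, 1\].
#'
#' @param ms A `mean_squares` object from [anova_decompose()].
#' @return A `variance_components` object.
#' @export
estimate_components <- function(ms) {
  stopifnot(inherits(ms, "mean_squares"))
  vc <- vc_from_ms_multi(
    ms$ms_subject, ms$ms_rater, ms$ms_interaction, ms$ms_error,
    ms$n, ms$k, ms$m
  )
  new_variance_components(
    vc$sigma2_subject, vc$sigma2_rater, vc$sigma2_interaction, vc$sigma2_error
  )
}

#' Point estimates of inter- and intra-observer reliability
#'
#' `rho_inter` is the share of total variance attributable to true subject
#' differences; `rho_intra` excludes only replicate measurement error, so
#' `rho_inter <= rho_intra` always.
#'
#' @param vc A `variance_components` object.
#' @return Named numeric vector `c(rho_inter = , rho_intra = )`.
#' @export
#' @examples
#' reliability_point(components_from_targets(0.5, 0.75, 8)) # c(0.5, 0.75)
reliability_point <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  total <- vc$sigma2_subject + vc$sigma2_rater + vc$sigma2_interaction +
    vc$sigma2_error
  if (total <= 0) {
    abort_ki67(
      "All variance components are zero; reliability is undefined.",
      "ki67agree_degenerate_data_error"
    )
  }
  c(
    rho_inter = vc$sigma2_subject / total,
    rho_intra = (vc$sigma2_subject + vc$sigma2_rater + vc$sigma2_interaction) /
      total
  )
}

#' One-sided lower confidence bound for intra-observer reliability
#'
#' Collapses the crossed design to a one-way layout over the n*k
#' subject-rater cells with m replicates each and applies the exact
#' F-interval: `F_L = F_obs / qf(1 - alpha, nk - 1, nk(m - 1))`, bound
#' `(F_L - 1) / (F_L + m - 1)`, clipped to \[0, 1\].
#'
#' @param ms A `mean_squares` object.
#' @param alpha One-sided error level, default 0.05.
#' @return Lower (1 - alpha) confidence bound in \[0, 1\]. If the replicate
#'   error mean square is exactly zero the bound is 1.
#' @export
intra_lower_bound <- function(ms, alpha = 0.05) {
  stopifnot(inherits(ms, "mean_squares"), alpha > 0, alpha < 1)
  f <- intra_f_statistic(ms)
  if (is.infinite(f$F_obs)) {
    return(1)
  }
  F_L <- f$F_obs / qf(1 - alpha, f$df1, f$df2)
  min(max((F_L - 1) / (F_L + ms$m - 1), 0), 1)
}

intra_f_statistic <- function(ms) {
  nk <- ms$n * ms$k
  ss_between <- ms$ss_subject + ms$ss_rater + ms$ss_interaction
  df1 <- nk - 1
  df2 <- nk * (ms$m - 1)
  ms_between <- ss_between / df1
  ms_within <- ms$ms_error
  F_obs <- if (ms_within == 0) Inf else ms_between / ms_within
  list(F_obs = F_obs, df1 = df1, df2 = df2)
}

#' One-sided p-value for H0: intra-observer reliability <= rho0
#'
#' Based on the same one-way collapse as [intra_lower_bound()]:
#' `p = P(F > F_obs / theta0)` with `theta0 = 1 + m * rho0 / (1 - rho0)` on
#' `(nk - 1, nk(m - 1))` degrees of freedom. The p-value falls below `alpha`
#' exactly when the (1 - alpha) lower bound exceeds `rho0`.
#'
#' @param ms A `mean_squares` object.
#' @param rho0 Null reliability threshold, default 0.6.
#' @return One-sided p-value.
#' @export
intra_pvalue <- function(ms, rho0 = 0.6) {
  stopifnot(inherits(ms, "mean_squares"), rho0 >= 0, rho0 < 1)
  f <- intra_f_statistic(ms)
  if (is.infinite(f$F_obs)) {
    return(0)
  }
  theta0 <- 1 + ms$m * rho0 / (1 - rho0)
  pf(f$F_obs / theta0, f$df1, f$df2, lower.tail = FALSE)
}

# Parametric bootstrap replicates of rho_inter for a fitted design.
inter_bootstrap <- function(design, B, seed) {
  values <- design_values(design)
  dims <- dim(values)
  n <- dims[1]
  k <- dims[2]
  m <- dims[3]
  ms <- anova_decompose(values)
  vc <- estimate_components(ms)
  total <- vc$sigma2_subject + vc$sigma2_rater + vc$sigma2_interaction +
    vc$sigma2_error
  if (total <= 0) {
    abort_ki67(
      "Fitted model is degenerate (all variance components zero).",
      "ki67agree_degenerate_data_error"
    )
  }
  mu <- mean(values)
  boot <- withr::with_seed(seed, {
    # blocks keep peak memory modest at large B
    block <- max(1L, min(B, as.integer(ceiling(2e6 / (n * k * m)))))
    starts <- seq(1L, B, by = block)
    unlist(lapply(starts, function(s) {
      b <- min(block, B - s + 1L)
      rho_multi(sim_matrix(n, k, m, b, mu, vc), n, k, m)$rho_inter
    }))
  })
  boot[is.na(boot)] <- 0 # degenerate resample: no subject signal
  list(boot = boot, point = reliability_point(vc), ms = ms, vc = vc)
}

#' One-sided bootstrap lower bound for inter-observer reliability
#'
#' Fits the crossed random-effects model, draws `B` parametric-bootstrap
#' datasets of the same dimensions from the fitted normal model, re-estimates
#' `rho_inter` on each, and returns the empirical `alpha`-quantile of the
#' bootstrap estimates.
#'
#' @param design A `balanced_design` or n x k x m array.
#' @param alpha One-sided error level, default 0.05.
#' @param B Number of bootstrap datasets (>= 500), default 2000.
#' @param seed Integer seed (required; the bound is deterministic given the
#'   seed).
#' @return Lower (1 - alpha) confidence bound for `rho_inter`.
#' @export
inter_lower_bound <- function(design, alpha = 0.05, B = 2000, seed) {
  stopifnot(alpha > 0, alpha < 1, B >= 500)
  if (missing(seed)) {
    abort_ki67("A seed is required for the bootstrap bound.", "ki67agree_validation_error")
  }
  bt <- inter_bootstrap(design, B, seed)
  unname(quantile(bt$boot, alpha))
}

#' One-sided p-value for H0: inter-observer reliability <= rho0
#'
#' Add-one smoothed fraction of parametric-bootstrap estimates of
#' `rho_inter` that do not exceed `rho0`: `(count + 1) / (B + 1)`.
#'
#' @inheritParams inter_lower_bound
#' @param rho0 Null reliability threshold, default 0.6.
#' @return One-sided p-value.
#' @export
inter_pvalue <- function(design, rho0 = 0.6, B = 2000, seed) {
  stopifnot(B >= 500)
  if (missing(seed)) {
    abort_ki67("A seed is required for the bootstrap test.", "ki67agree_validation_error")
  }
  bt <- inter_bootstrap(design, B, seed)
  (sum(bt$boot <= rho0) + 1) / (B + 1)
}

#' Simultaneous inter-/intra-observer reliability estimation
#'
#' Runs the full reliability analysis for one balanced design: ANOVA
#' decomposition, variance components, point estimates of `rho_inter` and
#' `rho_intra`, one-sided (1 - alpha) lower confidence bounds (exact one-way
#' F construction for intra; seeded parametric percentile bootstrap for
#' inter) and one-sided p-values against `H0: rho <= rho0`. P-values are
#' reported unadjusted.
#'
#' @param design A `balanced_design` or n x k x m array.
#' @param alpha One-sided error level, default 0.05.
#' @param rho0 Null reliability threshold, default 0.6.
#' @param B Bootstrap datasets for the inter bound (>= 500), default 2000.
#' @param seed Integer seed for the bootstrap (required).
#' @return A `reliability_fit` object; see [tidy.reliability_fit()] and
#'   [glance.reliability_fit()].
#' @export
#' @examples
#' design <- extract_balanced(simulate_ratings(n = 20, k = 4, m = 3, seed = 7), "A")
#' fit <- estimate_reliability(design, B = 500, seed = 1)
#' tidy(fit)
estimate_reliability <- function(design, alpha = 0.05, rho0 = 0.6, B = 2000,
                                 seed) {
  stopifnot(alpha > 0, alpha < 1, B >= 500)
  if (missing(seed)) {
    abort_ki67("A seed is required for the bootstrap.", "ki67agree_validation_error")
  }
  bt <- inter_bootstrap(design, B, seed)
  ms <- bt$ms
  point <- bt$point
  structure(
    list(
      method = if (inherits(design, "balanced_design")) design$method else NA_character_,
      n = ms$n, k = ms$k, m = ms$m,
      mean_squares = ms, components = bt$vc,
      rho_inter = unname(point["rho_inter"]),
      rho_intra = unname(point["rho_intra"]),
      lower_inter = unname(quantile(bt$boot, alpha)),
      lower_intra = intra_lower_bound(ms, alpha),
      p_inter = (sum(bt$boot <= rho0) + 1) / (B + 1),
      p_intra = intra_pvalue(ms, rho0),
      alpha = alpha, rho0 = rho0, B = B, seed = seed
    ),
    class = "reliability_fit"
  )
}

#' @export
print.reliability_fit <- function(x, ...) {
  cat(sprintf(
    "<reliability_fit> %s(n=%d, k=%d, m=%d)\n",
    if (is.na(x$method)) "" else paste0("method ", x$method, " "),
    x$n, x$k, x$m
  ))
  cat(sprintf(
    "  rho_inter %.3f (lower %.3f, p=%.4g) | rho_intra %.3f (lower %.3f, p=%.4g)\n",
    x$rho_inter, x$lower_inter, x$p_inter,
    x$rho_intra, x$lower_intra, x$p_intra
  ))
  cat(sprintf("  one-sided %g%% bounds vs rho0 = %g\n", 100 * (1 - x$alpha), x$rho0))
  invisible(x)
}

#' Tidy a reliability fit
#'
#' @param x A `reliability_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`rho_inter`, `rho_intra`):
#'   estimate, one-sided lower bound, and p-value versus `rho0`.
#' @export
tidy.reliability_fit <- function(x, ...) {
  tibble::tibble(
    coefficient = c("rho_inter", "rho_intra"),
    estimate = c(x$rho_inter, x$rho_intra),
    lower = c(x$lower_inter, x$lower_intra),
    p_value = c(x$p_inter, x$p_intra)
  )
}

#' Glance at a reliability fit
#'
#' @param x A `reliability_fit`.
#' @param ... Unused.
#' @return One-row tibble with the design sizes, both coefficients and the
#'   analysis settings.
#' @export
glance.reliability_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n = x$n, k = x$k, m = x$m,
    rho_inter = x$rho_inter, rho_intra = x$rho_intra,
    lower_inter = x$lower_inter, lower_intra = x$lower_intra,
    p_inter = x$p_inter, p_intra = x$p_intra,
    alpha = x$alpha, rho0 = x$rho0, B = x$B, seed = x$seed
  )
}
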