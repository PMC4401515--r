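#' Analytic power for the one-sided intra-observer reliability test
#'
#' Power of the exact F test of `H0: rho_intra <= rho0` versus
#' `H1: rho_intra = rho1` in a design with `n` subjects, `k` raters and `m`
#' repetitions, using the one-way collapse over the `N = n * k`
#' subject-rater cells with `m` replicates each. With
#' `theta(rho) = 1 + m * rho / (1 - rho)`, power is
#' `P(F > (theta(rho0) / theta(rho1)) * F_crit)` on
#' `(N - 1, N (m - 1))` degrees of freedom.
#'
#' @param n,k,m Design sizes (subjects, raters, repetitions).
#' @param alpha One-sided significance level, default 0.05.
#' @param rho0 Null reliability, default 0.6.
#' @param rho1 Alternative reliability, default 0.75 (effect size 0.15 on
#'   the reliability scale).
#' @return Power in \[0, 1\]. Returns `alpha` when `rho1 == rho0` and 1 when
#'   `rho1 == 1`.
#' @export
#' @examples
#' intra_power_analytic(n = 50, k = 5, m = 3)
intra_power_analytic <- function(n, k, m, alpha = 0.05, rho0 = 0.6,
                                 rho1 = 0.75) {
  stopifnot(n >= 2, k >= 1, m >= 2, alpha > 0, alpha < 1)
  if (rho1 < rho0) {
    abort_ki67("rho1 must be >= rho0.", "ki67agree_validation_error")
  }
  if (rho1 >= 1) {
    return(1)
  }
  N <- n * k
  df1 <- N - 1
  df2 <- N * (m - 1)
  theta <- function(rho) 1 + m * rho / (1 - rho)
  crit <- qf(1 - alpha, df1, df2)
  pf((theta(rho0) / theta(rho1)) * crit, df1, df2, lower.tail = FALSE)
}

#' Monte-Carlo power for the one-sided inter-observer reliability test
#'
#' Simulates `R` rating tables from the crossed random-effects model with
#' true `rho_inter = rho1`, applies the parametric-bootstrap test of
#' `H0: rho_inter <= rho0` at level `alpha` to each, and reports the
#' rejection fraction with its binomial Monte-Carlo standard error.
#'
#' The simulation mean and total variance default to `mu = 50`,
#' `total_var = 100`: the coefficients are location/scale invariant, and a
#' central mean keeps clamping at the \[0, 100\] percentage bounds
#' negligible, so the estimate reflects the test rather than truncation.
#'
#' @param n,k,m Design sizes.
#' @param alpha One-sided level, default 0.05.
#' @param rho0 Null reliability, default 0.6.
#' @param rho1 True inter-observer reliability under the alternative,
#'   default 0.75.
#' @param rho_intra True intra-observer reliability, default 0.9.
#' @param rater_share Variance-slice allocation, default 0.5 (see
#'   [components_from_targets()]).
#' @param R Monte-Carlo replicates (>= 500), default 2000.
#' @param B Bootstrap resamples inside each test (>= 500), default 500.
#' @param seed Integer master seed (required).
#' @param mu,total_var Simulation location and scale, defaults 50 and 100.
#' @return One-row tibble: `power`, `se`, `n_reject`, `R`, `B`, and the
#'   design parameters.
#' @export
#' @examples
#' \donttest{
#' inter_power_mc(n = 50, k = 5, m = 3, R = 500, seed = 1)
#' }
inter_power_mc <- function(n = 50, k = 5, m = 3, alpha = 0.05, rho0 = 0.6,
                           rho1 = 0.75, rho_intra = 0.9, rater_share = 0.5,
                           R = 2000, B = 500, seed, mu = 50, total_var = 100) {
  stopifnot(R >= 500, B >= 500)
  if (missing(seed)) {
    abort_ki67("A seed is required for the Monte-Carlo run.", "ki67agree_validation_error")
  }
  vc <- components_from_targets(rho1, rho_intra, total_var, rater_share)
  seeds <- derive_seeds(seed, R + 1L)
  rejections <- withr::with_seed(seeds[R + 1L], {
    vapply(seq_len(R), function(i) {
      y <- sim_matrix(n, k, m, 1L, mu, vc)
      y <- pmin(pmax(y, 0), 100) # percentage bounds, as in the generator
      design <- array(y, c(n, k, m))
      p <- inter_pvalue(design, rho0 = rho0, B = B, seed = seeds[i])
      p <= alpha
    }, logical(1))
  })
  p_hat <- mean(rejections)
  tibble::tibble(
    power = p_hat, se = sqrt(p_hat * (1 - p_hat) / R),
    n_reject = sum(rejections), R = R, B = B,
    n = n, k = k, m = m, alpha = alpha, rho0 = rho0, rho1 = rho1,
    rho_intra = rho_intra, rater_share = rater_share, seed = seed
  )
}

#' Smallest number of subjects reaching a target power
#'
#' Scans `n` upward (doubling, then bisection) using the analytic
#' intra-observer power, which is monotone increasing in `n`.
#'
#' @param k,m Raters and repetitions.
#' @param alpha One-sided level, default 0.05.
#' @param rho0,rho1 Null and alternative reliability, defaults 0.6 / 0.75.
#' @param target_power Required power, in (`alpha`, 1).
#' @param n_max Search ceiling, default 100000.
#' @return One-row tibble with `n` (the design floor is 2) and the power
#'   achieved at that `n`.
#' @export
#' @examples
#' minimum_n(k = 5, m = 3, target_power = 0.8)
minimum_n <- function(k, m, alpha = 0.05, rho0 = 0.6, rho1 = 0.75,
                      target_power = 0.8, n_max = 100000) {
  stopifnot(target_power > alpha, target_power < 1)
  pw <- function(n) intra_power_analytic(n, k, m, alpha, rho0, rho1)
  lo <- 2L
  if (pw(lo) >= target_power) {
    return(tibble::tibble(n = lo, power = pw(lo)))
  }
  hi <- 4L
  while (hi <= n_max && pw(hi) < target_power) {
    lo <- hi
    hi <- hi * 2L
  }
  if (hi > n_max) {
    abort_ki67(
      sprintf("Target power not reached by n = %d.", n_max),
      "ki67agree_validation_error"
    )
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  tibble::tibble(n = hi, power = pw(hi))
}
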