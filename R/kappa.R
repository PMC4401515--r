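#' Dichotomize labelling-index percentages at a clinical cut-off
#'
#' Values at or below the cut-off are classed `"low"`, values above it
#' `"high"` — the boundary is inclusive on the low side (a value of exactly
#' 14 is "low" at the 14\% cut-off).
#'
#' @param values Numeric percentages in \[0, 100\].
#' @param cutoff Cut-off in percent, strictly between 0 and 100. Clinical
#'   defaults in breast pathology are 14 and 20.
#' @return Factor with levels `c("low", "high")`.
#' @export
#' @examples
#' dichotomize(c(10, 14, 14.01, 25), 14)
dichotomize <- function(values, cutoff) {
  stopifnot(length(cutoff) == 1, cutoff > 0, cutoff < 100)
  if (any(values < 0 | values > 100, na.rm = TRUE)) {
    abort_ki67("Values must lie in [0, 100].", "ki67agree_validation_error")
  }
  factor(ifelse(values <= cutoff, "low", "high"), levels = c("low", "high"))
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement for `N` subjects each rated on `r` occasions,
#' from the per-subject category-count matrix:
#' `P_i = (sum_c n_ic^2 - r) / (r (r - 1))`, `Pbar = mean_i P_i`,
#' `p_c = sum_i n_ic / (N r)`, `Pbar_e = sum_c p_c^2`,
#' `kappa = (Pbar - Pbar_e) / (1 - Pbar_e)`.
#'
#' @param counts Integer matrix, one row per subject, one column per
#'   category; every row must sum to the same `r >= 2`.
#' @return Fleiss' kappa in \[-1, 1\].
#' @export
#' @examples
#' counts <- rbind(c(12, 0), c(0, 12), c(11, 1), c(3, 9))
#' fleiss_kappa(counts)
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) {
    abort_ki67("Need at least 2 subjects.", "ki67agree_validation_error")
  }
  r <- unique(rowSums(counts))
  if (length(r) != 1 || r < 2) {
    abort_ki67(
      "Every subject must have the same number of ratings r >= 2.",
      "ki67agree_validation_error"
    )
  }
  N <- nrow(counts)
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  p_c <- colSums(counts) / (N * r)
  Pbar_e <- sum(p_c^2)
  if (Pbar_e >= 1) {
    abort_ki67(
      "All ratings fall in a single category; kappa is undefined.",
      "ki67agree_degenerate_agreement_error"
    )
  }
  (mean(P_i) - Pbar_e) / (1 - Pbar_e)
}

#' Per-subject low/high count matrix for a balanced design
#'
#' Pools all `k * m` rating occasions per subject by default (each
#' rater-repetition counted once); alternatively restricts to a single
#' repetition, giving `k` occasions per subject.
#'
#' @param design A `balanced_design`.
#' @param cutoff Dichotomization cut-off in percent.
#' @param repetition `NULL` (default) to pool all repetitions, or a single
#'   repetition index to use only that round of assessments.
#' @return Integer matrix with columns `low`, `high`, one row per subject.
#' @export
kappa_counts <- function(design, cutoff, repetition = NULL) {
  values <- design_values(design)
  if (!is.null(repetition)) {
    stopifnot(length(repetition) == 1, repetition >= 1, repetition <= dim(values)[3])
    values <- values[, , repetition, drop = FALSE]
  }
  n <- dim(values)[1]
  low <- matrix(as.integer(dichotomize(as.vector(values), cutoff) == "low"),
    nrow = n
  )
  n_low <- rowSums(low)
  cbind(low = n_low, high = ncol(low) - n_low)
}

#' Fleiss' kappa with bias-corrected bootstrap inference
#'
#' Dichotomizes a balanced design at a clinical cut-off, computes Fleiss'
#' kappa over the pooled rating occasions, and obtains a one-sided
#' bias-corrected (BC) percentile bootstrap lower bound and a p-value against
#' `H0: kappa <= rho0` by resampling subjects with replacement. The BC bound
#' at level `alpha` is the bootstrap quantile at
#' `pnorm(2 * z0 + qnorm(alpha))` with `z0 = qnorm(#\{kappa* < kappa_hat\}/B)`;
#' the p-value is the smallest level at which the corresponding BC lower
#' bound exceeds `rho0`, found by inverting over a fine level grid. Bootstrap
#' replicates whose resampled table is single-category are dropped and
#' counted; more than 20\% such replicates is an error.
#'
#' @inheritParams kappa_counts
#' @param alpha One-sided error level, default 0.05.
#' @param rho0 Null agreement threshold, default 0.6.
#' @param B Bootstrap resamples (>= 500), default 2000.
#' @param seed Integer seed (required).
#' @return A `kappa_fit` object with fields `cutoff`, `kappa`, `lower_bound`,
#'   `p_value`, `r` (ratings per subject), `B`, `n_degenerate`, `alpha`,
#'   `rho0`, `seed`.
#' @export
#' @examples
#' design <- extract_balanced(simulate_ratings(n = 20, k = 4, m = 3, seed = 3), "A")
#' kappa_with_bootstrap(design, cutoff = 14, B = 500, seed = 1)
kappa_with_bootstrap <- function(design, cutoff, alpha = 0.05, rho0 = 0.6,
                                 B = 2000, seed, repetition = NULL) {
  stopifnot(alpha > 0, alpha < 1, B >= 500)
  if (missing(seed)) {
    abort_ki67("A seed is required for the bootstrap.", "ki67agree_validation_error")
  }
  counts <- kappa_counts(design, cutoff, repetition)
  n <- nrow(counts)
  r <- sum(counts[1, ])
  khat <- fleiss_kappa(counts)

  n_low <- counts[, "low"]
  idx <- withr::with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), n, B))
  NL <- matrix(n_low[idx], n, B)
  # binary Fleiss' kappa, vectorised over resamples
  P_i <- (NL^2 + (r - NL)^2 - r) / (r * (r - 1))
  p_low <- .colMeans(NL, n, B) / r
  Pbar_e <- p_low^2 + (1 - p_low)^2
  degenerate <- Pbar_e >= 1 - 1e-12
  kstar <- (.colMeans(P_i, n, B) - Pbar_e) / (1 - Pbar_e)
  kstar <- kstar[!degenerate]
  n_deg <- sum(degenerate)
  if (n_deg > 0.2 * B) {
    abort_ki67(
      sprintf(
        "Bootstrap unstable: %d of %d resamples were single-category.",
        n_deg, B
      ),
      "ki67agree_unstable_bootstrap_error"
    )
  }
  Bk <- length(kstar)
  frac_below <- min(max(sum(kstar < khat) / Bk, 1 / (Bk + 1)), Bk / (Bk + 1))
  z0 <- qnorm(frac_below)
  lower <- unname(quantile(kstar, pnorm(2 * z0 + qnorm(alpha))))

  # invert the BC lower bound over a level grid: smallest alpha' whose bound
  # exceeds rho0 (bound is nondecreasing in the level)
  grid <- seq(1 / (Bk + 1), Bk / (Bk + 1), length.out = 2001)
  bounds <- unname(quantile(kstar, pnorm(2 * z0 + qnorm(grid))))
  hit <- which(bounds > rho0)
  p_value <- if (length(hit) == 0) 1 else grid[hit[1]]

  structure(
    list(
      cutoff = cutoff, kappa = khat, lower_bound = lower, p_value = p_value,
      r = r, n_subjects = n, B = B, n_degenerate = n_deg,
      alpha = alpha, rho0 = rho0, seed = seed,
      repetition = repetition
    ),
    class = "kappa_fit"
  )
}

#' @export
print.kappa_fit <- function(x, ...) {
  cat(sprintf(
    "<kappa_fit> cut-off %g%%: kappa %.3f (BC lower %.3f, p=%.4g vs %g)\n",
    x$cutoff, x$kappa, x$lower_bound, x$p_value, x$rho0
  ))
  cat(sprintf(
    "  %d subjects x %d ratings; B=%d (%d degenerate resamples dropped)\n",
    x$n_subjects, x$r, x$B, x$n_degenerate
  ))
  invisible(x)
}

#' @export
tidy.kappa_fit <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff, kappa = x$kappa, lower_bound = x$lower_bound,
    p_value = x$p_value, r = x$r, B = x$B, n_degenerate = x$n_degenerate
  )
}

#' @export
glance.kappa_fit <- function(x, ...) {
  tidy(x) %>%
    dplyr::mutate(alpha = x$alpha, rho0 = x$rho0, seed = x$seed)
}
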