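#' Variance components from reliability targets
#'
#' Inverts the definition of the simultaneous inter-/intra-observer
#' reliability coefficients of a crossed two-way random-effects model:
#' given targets `rho_inter = sigma2_subject / total` and
#' `rho_intra = (total - sigma2_error) / total`, allocates the total variance
#' to the subject, rater, subject-by-rater interaction, and replicate-error
#' components. The slice `(rho_intra - rho_inter) * total_var` lying between
#' the two coefficients is split between the pure rater component
#' (`rater_share`) and the interaction (the remainder).
#'
#' @param rho_inter Target inter-observer reliability in \[0, 1\].
#' @param rho_intra Target intra-observer reliability in \[`rho_inter`, 1\].
#' @param total_var Total variance in percent squared (>= 0).
#' @param rater_share Fraction of the between-coefficient variance slice
#'   assigned to the pure rater component, in \[0, 1\]. Default 0.5.
#' @return A `variance_components` object: list with `sigma2_subject`,
#'   `sigma2_rater`, `sigma2_interaction`, `sigma2_error`, all >= 0 and
#'   summing to `total_var`.
#' @export
#' @examples
#' components_from_targets(0.5, 0.75, 8) # (4, 1, 1, 2)
components_from_targets <- function(rho_inter, rho_intra, total_var,
                                    rater_share = 0.5) {
  if (rho_inter < 0 || rho_intra > 1 || rater_share < 0 || rater_share > 1 ||
    total_var < 0) {
    abort_ki67(
      "Need 0 <= rho_inter <= rho_intra <= 1, rater_share in [0,1], total_var >= 0.",
      "ki67agree_validation_error"
    )
  }
  if (rho_inter > rho_intra) {
    abort_ki67(
      "rho_inter must not exceed rho_intra.",
      "ki67agree_ordering_error"
    )
  }
  slice <- (rho_intra - rho_inter) * total_var
  new_variance_components(
    sigma2_subject = rho_inter * total_var,
    sigma2_rater = rater_share * slice,
    sigma2_interaction = (1 - rater_share) * slice,
    sigma2_error = (1 - rho_intra) * total_var
  )
}

new_variance_components <- function(sigma2_subject, sigma2_rater,
                                    sigma2_interaction, sigma2_error) {
  structure(
    list(
      sigma2_subject = sigma2_subject,
      sigma2_rater = sigma2_rater,
      sigma2_interaction = sigma2_interaction,
      sigma2_error = sigma2_error
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> (percent^2)\n")
  cat(sprintf(
    "  subject %.4g | rater %.4g | interaction %.4g | error %.4g\n",
    x$sigma2_subject, x$sigma2_rater, x$sigma2_interaction, x$sigma2_error
  ))
  invisible(x)
}

#' @export
tidy.variance_components <- function(x, ...) {
  tibble::tibble(
    component = c("subject", "rater", "interaction", "error"),
    variance = c(
      x$sigma2_subject, x$sigma2_rater, x$sigma2_interaction, x$sigma2_error
    )
  )
}

#' Simulate a ratings table from the crossed random-effects model
#'
#' Draws `Y_ijl = mu + s_i + r_j + sr_ij + e_ijl` with independent zero-mean
#' normal effects for subjects, raters, subject-by-rater interaction, and
#' replicate error, then clamps values to \[0, 100\] and optionally rounds to
#' the nearest multiple of 5 (mimicking "eyeballed" percentages that cluster
#' on 0/5 endings). Each random-effect component draws from its own
#' sub-stream derived from `seed`, so e.g. changing `n` does not perturb the
#' rater effects.
#'
#' @param n,k,m Numbers of subjects, raters and repetitions.
#' @param mu Mean labelling index in percent. Default 18.
#' @param total_var Total variance in percent squared. Default 80.
#' @param rho_inter,rho_intra Target reliability coefficients. Defaults 0.7
#'   and 0.85.
#' @param rater_share See [components_from_targets()]. Default 0.5.
#' @param method Method code attached to all records. Default `"A"`.
#' @param round_to_five Round each value to the nearest multiple of 5 after
#'   clamping. Default `FALSE`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A ratings tibble (see [read_ratings()]) with a `"metadata"`
#'   attribute recording the configuration and the fraction of values clamped
#'   at 0 or 100 (`truncation_fraction`, flagged via `truncation_warning`
#'   when above 1\%).
#' @export
#' @examples
#' simulate_ratings(n = 5, k = 4, m = 3, seed = 42)
simulate_ratings <- function(n = 50, k = 4, m = 3, mu = 18, total_var = 80,
                             rho_inter = 0.7, rho_intra = 0.85,
                             rater_share = 0.5, method = "A",
                             round_to_five = FALSE, seed) {
  stopifnot(n >= 1, k >= 1, m >= 1)
  if (missing(seed)) {
    abort_ki67("A seed is required for reproducible simulation.", "ki67agree_validation_error")
  }
  vc <- components_from_targets(rho_inter, rho_intra, total_var, rater_share)

  seeds <- derive_seeds(seed, 4L)
  s <- withr::with_seed(seeds[1], rnorm(n, 0, sqrt(vc$sigma2_subject)))
  r <- withr::with_seed(seeds[2], rnorm(k, 0, sqrt(vc$sigma2_rater)))
  sr <- withr::with_seed(
    seeds[3],
    matrix(rnorm(n * k, 0, sqrt(vc$sigma2_interaction)), n, k)
  )
  e <- withr::with_seed(
    seeds[4],
    array(rnorm(n * k * m, 0, sqrt(vc$sigma2_error)), c(n, k, m))
  )

  raw <- mu + array(s, c(n, k, m)) +
    array(rep(r, each = n), c(n, k, m)) +
    array(as.vector(sr), c(n, k, m)) + e
  trunc_frac <- mean(raw < 0 | raw > 100)
  values <- pmin(pmax(raw, 0), 100)
  if (round_to_five) values <- 5 * round(values / 5)

  samples <- sprintf("S%02d", seq_len(n))
  raters <- sprintf("R%d", seq_len(k))
  grid <- expand.grid(
    sample_id = samples, rater_id = raters, repetition = seq_len(m),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tbl <- tibble::tibble(
    sample_id = grid$sample_id,
    rater_id = grid$rater_id,
    method = method,
    repetition = as.integer(grid$repetition),
    value = as.vector(values)
  )
  tbl <- validate_ratings(tbl)
  meta <- attr(tbl, "metadata")
  meta$config <- list(
    n = n, k = k, m = m, mu = mu, total_var = total_var,
    rho_inter = rho_inter, rho_intra = rho_intra, rater_share = rater_share,
    method = method, round_to_five = round_to_five, seed = seed
  )
  meta$truncation_fraction <- trunc_frac
  meta$truncation_warning <- trunc_frac > 0.01
  attr(tbl, "metadata") <- meta
  tbl
}

#' Reliability presets calibrated to a published seven-method Ki-67 study
#'
#' Returns the per-method (inter, intra) reliability pairs reported for seven
#' Ki-67 assessment methods (A--G) in a multi-pathologist breast-cancer
#' agreement study, usable as simulation targets.
#'
#' @return A tibble with columns `method`, `rho_inter`, `rho_intra`.
#' @export
study_presets <- function() {
  tibble::tibble(
    method = LETTERS[1:7],
    rho_inter = c(0.71, 0.63, 0.74, 0.57, 0.55, 0.40, 0.60),
    rho_intra = c(0.88, 0.72, 0.82, 0.69, 0.89, 0.76, 0.81)
  )
}

#' Simulate a full seven-method study
#'
#' Generates one ratings table covering all methods in `presets` under the
#' study-mimicking default design (50 subjects, 4 raters, 3 repetitions,
#' mean labelling index 18\%, total variance 80).
#'
#' @param presets Tibble with `method`, `rho_inter`, `rho_intra`; defaults to
#'   [study_presets()].
#' @param n,k,m,mu,total_var,rater_share,round_to_five As in
#'   [simulate_ratings()].
#' @param seed Integer master seed; one sub-seed is derived per method.
#' @return A ratings tibble covering all methods.
#' @export
simulate_study <- function(presets = study_presets(), n = 50, k = 4, m = 3,
                           mu = 18, total_var = 80, rater_share = 0.5,
                           round_to_five = FALSE, seed) {
  if (missing(seed)) {
    abort_ki67("A seed is required for reproducible simulation.", "ki67agree_validation_error")
  }
  seeds <- derive_seeds(seed, nrow(presets))
  tabs <- purrr::pmap(
    list(presets$method, presets$rho_inter, presets$rho_intra, seeds),
    function(method, ri, ra, s) {
      simulate_ratings(
        n = n, k = k, m = m, mu = mu, total_var = total_var,
        rho_inter = ri, rho_intra = ra, rater_share = rater_share,
        method = method, round_to_five = round_to_five, seed = s
      )
    }
  )
  validate_ratings(dplyr::bind_rows(tabs))
}
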