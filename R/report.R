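#' Weighted sum of inter- and intra-observer reliability
#'
#' The pre-specified method-ranking criterion: inter-observer reliability is
#' weighted 0.6 and intra-observer reliability 0.4 by default (weights must
#' be nonnegative and sum to 1).
#'
#' @param rho_inter,rho_intra Reliability coefficients in \[0, 1\]
#'   (vectorised).
#' @param w_inter,w_intra Weights, defaults 0.6 and 0.4.
#' @return `w_inter * rho_inter + w_intra * rho_intra`.
#' @export
#' @examples
#' weighted_score(0.71, 0.88) # 0.778
weighted_score <- function(rho_inter, rho_intra, w_inter = 0.6, w_intra = 0.4) {
  if (w_inter < 0 || w_intra < 0 || abs(w_inter + w_intra - 1) > 1e-12) {
    abort_ki67(
      "Weights must be nonnegative and sum to 1.",
      "ki67agree_validation_error"
    )
  }
  if (any(rho_inter < 0 | rho_inter > 1 | rho_intra < 0 | rho_intra > 1)) {
    abort_ki67(
      "Reliability coefficients must lie in [0, 1].",
      "ki67agree_validation_error"
    )
  }
  w_inter * rho_inter + w_intra * rho_intra
}

#' Rank assessment methods by weighted reliability score
#'
#' Computes the weighted sum for each method, ranks descending (rank 1 =
#' best; ties broken by higher inter-observer reliability, then by method
#' code), and flags qualification: methods whose weighted sum strictly
#' exceeds `threshold` qualify for further validation.
#'
#' @param scores Data frame with columns `method`, `rho_inter`, `rho_intra`.
#' @param w_inter,w_intra Weights as in [weighted_score()].
#' @param threshold Qualification threshold, default 0.6 (strict `>`).
#' @return A tibble ordered by rank with added columns `weighted`, `rank`,
#'   `qualified`.
#' @export
#' @examples
#' rank_methods(study_presets())
rank_methods <- function(scores, w_inter = 0.6, w_intra = 0.4, threshold = 0.6) {
  stopifnot(all(c("method", "rho_inter", "rho_intra") %in% names(scores)))
  if (nrow(scores) < 1) {
    abort_ki67("Need at least one method to rank.", "ki67agree_validation_error")
  }
  out <- tibble::as_tibble(scores) %>%
    dplyr::mutate(
      weighted = weighted_score(.data$rho_inter, .data$rho_intra, w_inter, w_intra)
    ) %>%
    # round-off guard so algebraically tied scores break on rho_inter
    dplyr::arrange(
      dplyr::desc(round(.data$weighted, 10)), dplyr::desc(.data$rho_inter),
      .data$method
    ) %>%
    dplyr::mutate(
      rank = dplyr::row_number(),
      qualified = .data$weighted > threshold
    )
  out
}

#' Interpretation labels for ICC and kappa values
#'
#' Maps an agreement coefficient onto the conventional verbal scales: for
#' intraclass correlations (Rosner) `< 0.4` is "poor", `\[0.4, 0.76)` is
#' "fair good" and `\[0.76, 1\]` is "excellent"; for Fleiss' kappa
#' (Landis-Koch) `<= 0` "poor", then "slight" (to 0.20), "fair" (to 0.40),
#' "moderate" (to 0.60), "substantial" (to 0.80) and "almost perfect"
#' (to 1).
#'
#' @param value Numeric coefficient(s), each `<= 1`.
#' @param which `"icc"` or `"kappa"`.
#' @return Character label(s).
#' @export
#' @examples
#' interpret(0.74, "icc") # "fair good"
#' interpret(0.58, "kappa") # "moderate"
interpret <- function(value, which = c("icc", "kappa")) {
  which <- match.arg(which)
  if (any(value > 1)) {
    abort_ki67("Agreement coefficients cannot exceed 1.", "ki67agree_validation_error")
  }
  if (which == "icc") {
    ifelse(value < 0.4, "poor", ifelse(value < 0.76, "fair good", "excellent"))
  } else {
    as.character(cut(
      value,
      breaks = c(-Inf, 0, 0.20, 0.40, 0.60, 0.80, 1),
      labels = c(
        "poor", "slight", "fair", "moderate", "substantial", "almost perfect"
      )
    ))
  }
}

#' Bland-Altman agreement summary for paired measurements
#'
#' @param x,y Numeric vectors of equal length >= 2; differences are `x - y`.
#' @return One-row tibble: `bias` (mean difference), `sd_diff` (sample SD,
#'   n-1 denominator), limits of agreement `loa_low`/`loa_high`
#'   (bias -/+ 1.96 sd) and `n_pairs`.
#' @export
#' @examples
#' bland_altman(c(10, 12, 15), c(11, 12, 13))
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort_ki67(
      "x and y must have equal length >= 2.",
      "ki67agree_validation_error"
    )
  }
  d <- x - y
  bias <- mean(d)
  sd_diff <- sd(d)
  tibble::tibble(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    n_pairs = length(d)
  )
}

#' Bland-Altman summaries for every rater pair and repetition pair
#'
#' Two views of one balanced design: the inter-observer view compares every
#' pair of raters on their per-subject cell means (averaged over
#' repetitions); the intra-observer view compares every pair of repetitions
#' within each rater on the raw values.
#'
#' @param design A `balanced_design`.
#' @return Tibble with columns `view` ("inter"/"intra"), `unit` (rater for
#'   the intra view, `NA` for inter), `first`, `second`, and the
#'   [bland_altman()] summary columns.
#' @export
bland_altman_pairs <- function(design) {
  values <- design_values(design)
  n <- dim(values)[1]
  k <- dim(values)[2]
  m <- dim(values)[3]
  raters <- dimnames(values)[[2]] %||% as.character(seq_len(k))
  reps <- dimnames(values)[[3]] %||% as.character(seq_len(m))

  cell_means <- apply(values, c(1, 2), mean)
  inter <- purrr::map_dfr(utils::combn(k, 2, simplify = FALSE), function(pr) {
    dplyr::mutate(
      bland_altman(cell_means[, pr[1]], cell_means[, pr[2]]),
      view = "inter", unit = NA_character_,
      first = raters[pr[1]], second = raters[pr[2]],
      .before = 1
    )
  })
  intra <- purrr::map_dfr(seq_len(k), function(j) {
    purrr::map_dfr(utils::combn(m, 2, simplify = FALSE), function(pr) {
      dplyr::mutate(
        bland_altman(values[, j, pr[1]], values[, j, pr[2]]),
        view = "intra", unit = raters[j],
        first = reps[pr[1]], second = reps[pr[2]],
        .before = 1
      )
    })
  })
  dplyr::bind_rows(inter, intra)
}

#' Full multi-method agreement analysis
#'
#' Runs, for every assessment method in the ratings table: balanced-design
#' extraction with rater dropout, simultaneous inter-/intra-observer
#' reliability with bounds and tests, Fleiss' kappa with bias-corrected
#' bootstrap inference at each clinical cut-off, interpretation labels,
#' Bland-Altman summaries, and weighted-sum ranking across methods. Methods
#' whose design is degenerate or insufficient are recorded as failures and
#' the remaining methods are still analysed.
#'
#' @param ratings A ratings tibble covering one or more methods.
#' @param cutoffs Dichotomization cut-offs in percent, default `c(14, 20)`.
#' @param w_inter,w_intra Ranking weights, defaults 0.6 / 0.4.
#' @param alpha One-sided error level, default 0.05.
#' @param rho0 Null agreement threshold, default 0.6.
#' @param B Bootstrap resamples, default 2000.
#' @param seed Integer master seed (required); per-method sub-seeds are
#'   derived from it.
#' @param methods Methods to analyse; defaults to all present.
#' @return A `ki67_report` object: list with tibbles `scores` (ranked
#'   weighted sums with ICC interpretation labels), `reliability`, `kappa`
#'   (per method and cut-off, with Landis-Koch labels), `bland_altman`,
#'   `dropped_raters`, `failures`, and the echoed `config`.
#' @export
#' @examples
#' \donttest{
#' ratings <- simulate_study(n = 15, seed = 11)
#' report <- build_report(ratings, B = 500, seed = 5)
#' report$scores
#' }
build_report <- function(ratings, cutoffs = c(14, 20), w_inter = 0.6,
                         w_intra = 0.4, alpha = 0.05, rho0 = 0.6, B = 2000,
                         seed, methods = NULL) {
  if (missing(seed)) {
    abort_ki67("A seed is required for the bootstrap stages.", "ki67agree_validation_error")
  }
  ratings <- validate_ratings(ratings)
  if (is.null(methods)) methods <- sort(unique(ratings$method))
  if (length(methods) == 0) {
    abort_ki67("No methods present in the ratings table.", "ki67agree_validation_error")
  }
  seeds <- derive_seeds(seed, 2L * length(methods))

  rel_rows <- list()
  kap_rows <- list()
  ba_rows <- list()
  drop_rows <- list()
  failures <- list()

  for (ix in seq_along(methods)) {
    method <- methods[ix]
    res <- tryCatch(
      {
        design <- extract_balanced(ratings, method)
        fit <- estimate_reliability(design,
          alpha = alpha, rho0 = rho0, B = B,
          seed = seeds[2 * ix - 1]
        )
        kaps <- purrr::map_dfr(seq_along(cutoffs), function(ci) {
          kf <- kappa_with_bootstrap(design,
            cutoff = cutoffs[ci], alpha = alpha,
            rho0 = rho0, B = B, seed = seeds[2 * ix] + ci - 1L
          )
          dplyr::mutate(tidy(kf), method = method, .before = 1)
        })
        list(
          rel = dplyr::mutate(glance(fit), method = method),
          kap = kaps,
          ba = dplyr::mutate(bland_altman_pairs(design), method = method, .before = 1),
          dropped = tibble::tibble(
            method = method,
            rater_id = if (length(design$dropped_raters)) design$dropped_raters else character(0)
          )
        )
      },
      ki67agree_error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[method]] <- tibble::tibble(
        method = method, error = conditionMessage(res)
      )
    } else {
      rel_rows[[method]] <- res$rel
      kap_rows[[method]] <- res$kap
      ba_rows[[method]] <- res$ba
      drop_rows[[method]] <- res$dropped
    }
  }

  if (length(rel_rows) == 0) {
    abort_ki67(
      "No method yielded a valid balanced design.",
      "ki67agree_insufficient_design_error"
    )
  }

  reliability <- dplyr::bind_rows(rel_rows)
  scores <- rank_methods(
    reliability %>% dplyr::select("method", "rho_inter", "rho_intra"),
    w_inter = w_inter, w_intra = w_intra, threshold = rho0
  ) %>%
    dplyr::mutate(
      label_inter = interpret(.data$rho_inter, "icc"),
      label_intra = interpret(.data$rho_intra, "icc"),
      label_weighted = interpret(.data$weighted, "icc")
    )
  kappa <- dplyr::bind_rows(kap_rows) %>%
    dplyr::mutate(label = interpret(.data$kappa, "kappa"))

  structure(
    list(
      scores = scores,
      reliability = reliability,
      kappa = kappa,
      bland_altman = dplyr::bind_rows(ba_rows),
      dropped_raters = dplyr::bind_rows(drop_rows),
      failures = if (length(failures)) {
        dplyr::bind_rows(failures)
      } else {
        tibble::tibble(method = character(0), error = character(0))
      },
      config = list(
        cutoffs = cutoffs, w_inter = w_inter, w_intra = w_intra,
        alpha = alpha, rho0 = rho0, B = B, seed = seed, methods = methods
      )
    ),
    class = "ki67_report"
  )
}

#' @export
print.ki67_report <- function(x, ...) {
  cat(sprintf(
    "<ki67_report> %d method(s) analysed, %d failed\n",
    nrow(x$scores), nrow(x$failures)
  ))
  print(x$scores)
  invisible(x)
}

#' @export
tidy.ki67_report <- function(x, ...) {
  x$scores
}

#' @export
glance.ki67_report <- function(x, ...) {
  tibble::tibble(
    n_methods = nrow(x$scores),
    n_failed = nrow(x$failures),
    n_qualified = sum(x$scores$qualified),
    best_method = x$scores$method[x$scores$rank == 1],
    alpha = x$config$alpha, rho0 = x$config$rho0,
    B = x$config$B, seed = x$config$seed
  )
}

round_df <- function(df, digits) {
  if (is.na(digits)) {
    return(df)
  }
  df[] <- lapply(df, function(col) if (is.double(col)) round(col, digits) else col)
  df
}

#' Write an analysis report to JSON
#'
#' Serialises a [build_report()] result to machine-readable JSON with a
#' stable key order; numeric values are rounded to `digits` decimals
#' (default 3, `NA` for full precision). [read_report()] reproduces the
#' written report.
#'
#' @param report A `ki67_report`.
#' @param path Output path.
#' @param digits Decimals kept for numeric values; default 3.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, digits = 3) {
  stopifnot(inherits(report, "ki67_report"))
  if (nrow(report$scores) == 0) {
    abort_ki67("Report contains no analysed methods.", "ki67agree_validation_error")
  }
  payload <- list(
    scores = round_df(report$scores, digits),
    reliability = round_df(report$reliability, digits),
    kappa = round_df(report$kappa, digits),
    bland_altman = round_df(report$bland_altman, digits),
    dropped_raters = report$dropped_raters,
    failures = report$failures,
    config = report$config
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Read an analysis report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return A `ki67_report` with the same tibbles (values as rounded at
#'   write time).
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      scores = tibble::as_tibble(raw$scores),
      reliability = tibble::as_tibble(raw$reliability),
      kappa = tibble::as_tibble(raw$kappa),
      bland_altman = tibble::as_tibble(raw$bland_altman),
      dropped_raters = tibble::as_tibble(raw$dropped_raters),
      failures = tibble::as_tibble(raw$failures),
      config = raw$config
    ),
    class = "ki67_report"
  )
}

#' Export the summary table of a report as TSV
#'
#' Mirrors the familiar summary layout of multi-method agreement studies:
#' one row per method with both reliability coefficients, the weighted sum,
#' the rank, qualification, and Fleiss' kappa per cut-off.
#'
#' @param report A `ki67_report`.
#' @param path Output TSV path.
#' @param digits Rounding for the human-readable view, default 2.
#' @return The exported tibble, invisibly.
#' @export
write_summary_tsv <- function(report, path, digits = 2) {
  stopifnot(inherits(report, "ki67_report"))
  wide_kappa <- report$kappa %>%
    dplyr::select("method", "cutoff", "kappa") %>%
    tidyr::pivot_wider(
      names_from = "cutoff", values_from = "kappa",
      names_prefix = "kappa_le"
    )
  out <- report$scores %>%
    dplyr::select(
      "method", "rho_inter", "rho_intra", "weighted", "rank", "qualified"
    ) %>%
    dplyr::left_join(wide_kappa, by = "method") %>%
    round_df(digits)
  readr::write_tsv(out, path)
  invisible(out)
}
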