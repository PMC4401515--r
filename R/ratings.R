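#' Read a long-format ratings table from CSV
#'
#' A ratings table holds one row per (sample, rater, method, repetition) with
#' the Ki-67 labelling index in percent. The CSV must be comma-separated,
#' UTF-8, with header columns `sample_id, rater_id, method, repetition, value`.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble with columns `sample_id` (character),
#'   `rater_id` (character), `method` (character, one of A--G), `repetition`
#'   (integer >= 1) and `value` (percent in \[0, 100\]). Input row order is
#'   preserved and recorded in the `"metadata"` attribute.
#' @seealso [write_ratings()], [simulate_ratings()], [extract_balanced()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_ratings(simulate_ratings(n = 4, k = 2, m = 2, seed = 1), path)
#' read_ratings(path)
read_ratings <- function(path) {
  if (!file.exists(path)) {
    abort_ki67(paste0("File not found: ", path), "ki67agree_io_error")
  }
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      rater_id = readr::col_character(),
      method = readr::col_character(),
      repetition = readr::col_integer(),
      value = readr::col_double()
    )
  )
  validate_ratings(tbl, source = path)
}

#' Write a ratings table to CSV
#'
#' @param ratings A ratings tibble as returned by [read_ratings()] or
#'   [simulate_ratings()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  readr::write_csv(ratings, path)
  invisible(path)
}

#' Validate a ratings table
#'
#' Checks the five required columns, the \[0, 100\] range of `value`, method
#' codes A--G, repetition >= 1, and uniqueness of the
#' (sample, rater, method, repetition) key. Errors name the first offending
#' row.
#'
#' @param ratings A data frame of ratings.
#' @param source Optional label used in error messages.
#' @return The validated ratings tibble (unchanged values), with a
#'   `"metadata"` attribute recording provenance.
#' @export
validate_ratings <- function(ratings, source = NULL) {
  required <- c("sample_id", "rater_id", "method", "repetition", "value")
  missing_cols <- setdiff(required, names(ratings))
  if (length(missing_cols) > 0) {
    abort_ki67(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      "ki67agree_validation_error"
    )
  }
  tbl <- tibble::as_tibble(ratings)
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl$rater_id <- as.character(tbl$rater_id)
  tbl$method <- as.character(tbl$method)
  tbl$repetition <- as.integer(tbl$repetition)
  tbl$value <- as.double(tbl$value)

  bad <- which(!is.finite(tbl$value) | tbl$value < 0 | tbl$value > 100)
  if (length(bad) > 0) {
    abort_ki67(
      sprintf(
        "Row %d: value %s outside [0, 100].", bad[1],
        format(tbl$value[bad[1]])
      ),
      "ki67agree_validation_error"
    )
  }
  bad <- which(!tbl$method %in% LETTERS[1:7])
  if (length(bad) > 0) {
    abort_ki67(
      sprintf(
        "Row %d: unknown method code '%s' (expected A-G).", bad[1],
        tbl$method[bad[1]]
      ),
      "ki67agree_validation_error"
    )
  }
  bad <- which(is.na(tbl$repetition) | tbl$repetition < 1L)
  if (length(bad) > 0) {
    abort_ki67(
      sprintf("Row %d: repetition must be an integer >= 1.", bad[1]),
      "ki67agree_validation_error"
    )
  }
  key <- paste(tbl$sample_id, tbl$rater_id, tbl$method, tbl$repetition,
    sep = "\r"
  )
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort_ki67(
      sprintf(
        "Row %d duplicates the (sample, rater, method, repetition) key of an earlier row.",
        dup[1]
      ),
      "ki67agree_validation_error"
    )
  }

  meta <- attr(ratings, "metadata")
  if (is.null(meta)) meta <- list()
  if (!is.null(source)) meta$source <- source
  meta$n_records <- nrow(tbl)
  attr(tbl, "metadata") <- meta
  tbl
}

#' Extract the balanced crossed design for one assessment method
#'
#' Applies the study's dropout rule: for the chosen method, any rater with a
#' missing (sample, repetition) cell — relative to the full grid of samples
#' and repetitions observed for that method — is excluded wholesale, so the
#' retained design is fully crossed and balanced. Mirrors an agreement study
#' in which one of five pathologists had missing assessments and only four
#' were analysed.
#'
#' @param ratings A ratings tibble.
#' @param method Single method code (one of "A".."G").
#' @return A `balanced_design` object: a list with elements `method`, `n`
#'   (subjects), `k` (retained raters), `m` (repetitions), `values` (an
#'   n x k x m array of percentages with dimnames), `sample_ids`, `rater_ids`,
#'   `repetitions`, and `dropped_raters`.
#' @export
#' @examples
#' design <- extract_balanced(simulate_ratings(n = 6, k = 3, m = 2, seed = 1), "A")
#' design$n
extract_balanced <- function(ratings, method) {
  stopifnot(is.character(method), length(method) == 1)
  ratings <- validate_ratings(ratings)
  sub <- ratings[ratings$method == method, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort_ki67(
      paste0("No records for method '", method, "'."),
      "ki67agree_validation_error"
    )
  }

  samples <- sort(unique(sub$sample_id))
  reps <- sort(unique(sub$repetition))
  n <- length(samples)
  m <- length(reps)
  n_cells <- n * m

  complete <- sub %>%
    dplyr::distinct(.data$sample_id, .data$rater_id, .data$repetition) %>%
    dplyr::count(.data$rater_id, name = "n_cells") %>%
    dplyr::filter(.data$n_cells == !!n_cells) %>%
    dplyr::pull(.data$rater_id)
  raters <- sort(complete)
  dropped <- sort(setdiff(unique(sub$rater_id), raters))

  if (length(raters) < 2) {
    abort_ki67(
      "Fewer than 2 raters have a complete set of (sample, repetition) cells for this method.",
      "ki67agree_insufficient_design_error"
    )
  }
  if (n < 2 || m < 2) {
    abort_ki67(
      "A balanced design needs at least 2 subjects and 2 repetitions.",
      "ki67agree_insufficient_design_error"
    )
  }

  keep <- sub[sub$rater_id %in% raters, , drop = FALSE]
  # defensive: complete raters share the full grid by construction
  per_rater <- table(keep$rater_id)
  if (length(unique(as.integer(per_rater))) != 1) {
    abort_ki67(
      "Retained raters have unequal repetition counts; design is unbalanced.",
      "ki67agree_imbalance_error"
    )
  }

  k <- length(raters)
  values <- array(
    NA_real_, c(n, k, m),
    dimnames = list(samples, raters, as.character(reps))
  )
  values[cbind(
    match(keep$sample_id, samples),
    match(keep$rater_id, raters),
    match(keep$repetition, reps)
  )] <- keep$value

  structure(
    list(
      method = method, n = n, k = k, m = m, values = values,
      sample_ids = samples, rater_ids = raters, repetitions = reps,
      dropped_raters = dropped
    ),
    class = "balanced_design"
  )
}

#' Convert a balanced design back to a long ratings table
#'
#' @param design A `balanced_design` object.
#' @return A ratings tibble with one row per retained record.
#' @export
ratings_from_design <- function(design) {
  stopifnot(inherits(design, "balanced_design"))
  grid <- expand.grid(
    sample_id = design$sample_ids,
    rater_id = design$rater_ids,
    repetition = design$repetitions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tbl <- tibble::tibble(
    sample_id = grid$sample_id,
    rater_id = grid$rater_id,
    method = design$method,
    repetition = as.integer(grid$repetition),
    value = as.vector(design$values)
  )
  validate_ratings(tbl)
}

#' @export
print.balanced_design <- function(x, ...) {
  cat(sprintf(
    "<balanced_design> method %s: %d subjects x %d raters x %d repetitions\n",
    x$method, x$n, x$k, x$m
  ))
  if (length(x$dropped_raters) > 0) {
    cat("  dropped raters:", paste(x$dropped_raters, collapse = ", "), "\n")
  }
  invisible(x)
}
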