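# Independent oracles and shared fixtures.
#
# The oracles deliberately use a different computational route from the
# package (explicit two-pass loops over index sets instead of the grouped
# quadratic-form shortcuts) so agreement is evidence, not tautology.

# brute-force two-way-with-replicates sums of squares
brute_ss <- function(Y) {
  n <- dim(Y)[1]
  k <- dim(Y)[2]
  m <- dim(Y)[3]
  g <- mean(Y)
  ss_s <- 0
  ss_r <- 0
  ss_sr <- 0
  ss_e <- 0
  for (i in 1:n) ss_s <- ss_s + k * m * (mean(Y[i, , ]) - g)^2
  for (j in 1:k) ss_r <- ss_r + n * m * (mean(Y[, j, ]) - g)^2
  for (i in 1:n) {
    for (j in 1:k) {
      ss_sr <- ss_sr +
        m * (mean(Y[i, j, ]) - mean(Y[i, , ]) - mean(Y[, j, ]) + g)^2
      for (l in 1:m) ss_e <- ss_e + (Y[i, j, l] - mean(Y[i, j, ]))^2
    }
  }
  c(
    ss_subject = ss_s, ss_rater = ss_r, ss_interaction = ss_sr,
    ss_error = ss_e
  )
}

# expected-mean-squares inversion, coded from the definitions
brute_components <- function(Y) {
  n <- dim(Y)[1]
  k <- dim(Y)[2]
  m <- dim(Y)[3]
  ss <- brute_ss(Y)
  ms <- c(
    ss[1] / (n - 1), ss[2] / (k - 1), ss[3] / ((n - 1) * (k - 1)),
    ss[4] / (n * k * (m - 1))
  )
  c(
    sigma2_subject = max(0, (ms[1] - ms[3]) / (k * m)),
    sigma2_rater = max(0, (ms[2] - ms[3]) / (n * m)),
    sigma2_interaction = max(0, (ms[3] - ms[4]) / m),
    sigma2_error = unname(ms[4])
  )
}

# direct evaluation of the Fleiss' kappa definition over a count matrix
brute_fleiss <- function(counts) {
  r <- sum(counts[1, ])
  N <- nrow(counts)
  P_i <- numeric(N)
  for (i in 1:N) P_i[i] <- (sum(counts[i, ]^2) - r) / (r * (r - 1))
  p_c <- colSums(counts) / (N * r)
  (mean(P_i) - sum(p_c^2)) / (1 - sum(p_c^2))
}

# F1: 3 subjects x 2 raters x 2 repetitions, integer percentages
fixture_F1 <- function() {
  array(c(
    17, 10, 25, 21, 14, 30, # repetition 1
    19, 12, 24, 23, 18, 28 # repetition 2
  ), c(3, 2, 2))
}

# K1: 5 subjects, 12 rating occasions each, low/high counts
fixture_K1 <- function() {
  low <- c(12, 9, 6, 2, 0)
  cbind(low = low, high = 12 - low)
}

# random balanced fixture with comfortably positive variance components
random_design_array <- function(seed, n = 8, k = 3, m = 3) {
  withr::with_seed(seed, {
    array(
      50 + rep(rnorm(n, 0, 3), k * m) +
        rep(rep(rnorm(k, 0, 2), each = n), m) +
        rep(rnorm(n * k, 0, 1.5), m) +
        rnorm(n * k * m, 0, 2),
      c(n, k, m)
    )
  })
}

as_design <- function(values, method = "A") {
  n <- dim(values)[1]
  k <- dim(values)[2]
  m <- dim(values)[3]
  structure(
    list(
      method = method, n = n, k = k, m = m,
      values = values,
      sample_ids = sprintf("S%02d", seq_len(n)),
      rater_ids = sprintf("R%d", seq_len(k)),
      repetitions = seq_len(m),
      dropped_raters = character(0)
    ),
    class = "balanced_design"
  )
}
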