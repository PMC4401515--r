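# Internal numerical engine shared by the estimators, the parametric
# bootstrap and the Monte-Carlo power routine.  All functions here operate on
# a (n*k*m) x B matrix of ratings, column = one dataset, rows ordered subject
# fastest, then rater, then repetition, so that row (i, j, l) sits at
# i + (j-1)*n + (l-1)*n*k.

# Sums of squares of the balanced two-way crossed layout with replicates,
# computed simultaneously for B datasets.
ss_decompose_multi <- function(Y, n, k, m) {
  B <- ncol(Y)
  nk <- n * k
  cell_of_row <- rep.int(seq_len(nk), m)
  subj_of_cell <- rep.int(seq_len(n), k)
  rater_of_cell <- rep(seq_len(k), each = n)

  cell_mean <- rowsum(Y, cell_of_row, reorder = FALSE) / m # nk x B
  subj_mean <- rowsum(cell_mean, subj_of_cell, reorder = FALSE) / k # n x B
  rater_mean <- rowsum(cell_mean, rater_of_cell, reorder = FALSE) / n # k x B
  grand <- .colMeans(Y, nk * m, B)

  ss_subject <- k * m * (.colSums(subj_mean^2, n, B) - n * grand^2)
  ss_rater <- n * m * (.colSums(rater_mean^2, k, B) - k * grand^2)
  resid_cell <- cell_mean -
    subj_mean[subj_of_cell, , drop = FALSE] -
    rater_mean[rater_of_cell, , drop = FALSE] +
    matrix(grand, nk, B, byrow = TRUE)
  ss_interaction <- m * .colSums(resid_cell^2, nk, B)
  ss_error <- .colSums(Y^2, nk * m, B) - m * .colSums(cell_mean^2, nk, B)

  # guard tiny negative round-off on the quadratic-form shortcuts
  list(
    ss_subject = pmax(ss_subject, 0),
    ss_rater = pmax(ss_rater, 0),
    ss_interaction = pmax(ss_interaction, 0),
    ss_error = pmax(ss_error, 0)
  )
}

# Method-of-moments variance components (vectorised), negative estimates
# truncated at zero.
vc_from_ms_multi <- function(ms_subject, ms_rater, ms_interaction, ms_error,
                             n, k, m) {
  list(
    sigma2_subject = pmax(0, (ms_subject - ms_interaction) / (k * m)),
    sigma2_rater = pmax(0, (ms_rater - ms_interaction) / (n * m)),
    sigma2_interaction = pmax(0, (ms_interaction - ms_error) / m),
    sigma2_error = ms_error
  )
}

# rho_inter and rho_intra for each column of Y; NA where all components zero.
rho_multi <- function(Y, n, k, m) {
  ss <- ss_decompose_multi(Y, n, k, m)
  vc <- vc_from_ms_multi(
    ss$ss_subject / (n - 1),
    ss$ss_rater / (k - 1),
    ss$ss_interaction / ((n - 1) * (k - 1)),
    ss$ss_error / (n * k * (m - 1)),
    n, k, m
  )
  tot <- vc$sigma2_subject + vc$sigma2_rater + vc$sigma2_interaction +
    vc$sigma2_error
  tot[tot <= 0] <- NA_real_
  list(
    rho_inter = vc$sigma2_subject / tot,
    rho_intra = (vc$sigma2_subject + vc$sigma2_rater + vc$sigma2_interaction) / tot
  )
}

# Draw B datasets from the crossed random-effects model
#   Y_ijl = mu + s_i + r_j + sr_ij + e_ijl
# as an (n*k*m) x B matrix (row order as above).  Uses the current RNG
# stream; callers manage seeding.
sim_matrix <- function(n, k, m, B, mu, vc) {
  nk <- n * k
  i_of_row <- rep.int(seq_len(n), k * m)
  j_of_row <- rep.int(rep(seq_len(k), each = n), m)
  cell_of_row <- rep.int(seq_len(nk), m)

  s <- matrix(rnorm(n * B, 0, sqrt(vc$sigma2_subject)), n, B)
  r <- matrix(rnorm(k * B, 0, sqrt(vc$sigma2_rater)), k, B)
  sr <- matrix(rnorm(nk * B, 0, sqrt(vc$sigma2_interaction)), nk, B)
  e <- matrix(rnorm(nk * m * B, 0, sqrt(vc$sigma2_error)), nk * m, B)

  mu + s[i_of_row, , drop = FALSE] + r[j_of_row, , drop = FALSE] +
    sr[cell_of_row, , drop = FALSE] + e
}

# Independent sub-seeds derived from one master seed (kept below 2^31).
derive_seeds <- function(seed, n_streams) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_streams))
}

abort_ki67 <- function(message, class) {
  rlang::abort(message, class = c(class, "ki67agree_error"))
}
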