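# Independent oracles and small fixture builders shared across tests.

quiet_scores <- function(...) suppressMessages(score_table(...))

# Recompute a trajectory's movement flags from its emitted positions only:
# the 3-line displacement oracle.
flags_from_positions <- function(positions, threshold) {
  d <- sqrt(diff(positions$x)^2 + diff(positions$y)^2)
  d >= threshold
}

# Plain intensity-weighted centroid of a whole frame after background
# removal; independent of the package's detection path.
frame_centroid <- function(frame, background) {
  w <- abs(frame - background)
  xs <- matrix(rep(seq_len(ncol(frame)) - 1, each = nrow(frame)),
               nrow = nrow(frame))
  ys <- matrix(rep(seq_len(nrow(frame)) - 1, times = ncol(frame)),
               nrow = nrow(frame))
  c(x = sum(w * xs) / sum(w), y = sum(w * ys) / sum(w))
}

# Brute-force truncation selection: enumerate every subset of size
# min(cap, n) and keep the one with the extreme total score. Only used as an
# oracle on small pools.
brute_select <- function(scores, regime, cap = 10) {
  n <- length(scores)
  k <- min(cap, n)
  subsets <- utils::combn(n, k)
  totals <- colSums(matrix(scores[subsets], nrow = k))
  best <- if (regime == "susceptible") which.max(totals) else
    which.min(totals)
  idx <- subsets[, best]
  list(selected_scores = sort(scores[idx]),
       differential = mean(scores[idx]) - mean(scores))
}

# All multisets of size n drawn from `values`, via stars and bars.
multisets <- function(values, n) {
  combs <- utils::combn(length(values) + n - 1, n)
  idx <- combs - matrix(seq_len(n) - 1, nrow = n, ncol = ncol(combs))
  matrix(values[idx], nrow = n)
}

# Behaviour records built by hand for scoring tests: a named list mapping
# copepod id -> activities (in day order, truncated schedules allowed).
make_records <- function(acts_by_id, days = c(6, 7, 8, 13, 14, 15),
                         infected = TRUE) {
  purrr::imap(acts_by_id, function(acts, id) {
    tibble::tibble(copepod_id = id, replicate = 1L,
                   line = "control", generation = "F0", infected = infected,
                   exposed = TRUE, day = days[seq_along(acts)],
                   activity = acts)
  }) |> purrr::list_rbind()
}
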