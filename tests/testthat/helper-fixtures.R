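# fixtures are built in code; nothing is read from disk

# single-column matrix from a series of per-length values
col_matrix <- function(values, lengths = seq_along(values) + 39L, position = 1L) {
  reactivity_matrix(matrix(values, ncol = 1L), lengths, position)
}

# step series: low before `at`, high from `at` on
step_series <- function(lengths, at, low = 0.2, high = 1.5) {
  ifelse(lengths < at, low, high)
}

# random multi-column matrix with the untranscribed-triangle NA pattern
random_matrix <- function(seed, n_lengths = 15L, n_positions = 10L,
                          first_length = NULL) {
  set.seed(seed)
  if (is.null(first_length)) first_length <- n_positions + sample.int(5L, 1L)
  lengths <- first_length + seq_len(n_lengths) - 1L
  vals <- matrix(stats::rgamma(n_lengths * n_positions, shape = 1, rate = 1),
                 n_lengths, n_positions)
  # inject occasional step changes so flags actually occur
  for (j in sample.int(n_positions, max(1L, n_positions %/% 3L))) {
    at <- sample.int(n_lengths, 1L)
    vals[at:n_lengths, j] <- vals[at:n_lengths, j] * stats::runif(1, 2, 6)
  }
  reactivity_matrix(vals, lengths, seq_len(n_positions))
}

random_event_table <- function(seed, n = 6L) {
  set.seed(seed)
  start <- sample(30:120, n, replace = TRUE)
  dir <- sample(c("up", "down"), n, replace = TRUE)
  event_table(nucleotide = sample(1:40, n, replace = FALSE),
              class = sample(c("swing", "ramp"), n, replace = TRUE),
              direction = dir,
              start_length = start,
              end_length = start + sample(0:6, n, replace = TRUE),
              magnitude = ifelse(dir == "up", 1, -1) * stats::runif(n, 0.1, 2))
}

# thresholds tuned for the hand-checked step fixtures
step_ts <- function() threshold_set(p_up = 0.3, p_down = 0.3, i_up = 0.6,
                                    i_down = 0.6, r_up = 0.5, r_down = 0.5,
                                    m_floor = 0.2, w_smooth = 3, i_length = 5,
                                    min_duration = 2, merge_gap = 1)

# random small ground-truth trajectory for simulator property tests
random_trajectory <- function(seed, n_lengths = 10L, n_positions = 6L) {
  set.seed(seed)
  first_len <- n_positions + sample.int(4L, 1L)
  lengths <- first_len + seq_len(n_lengths) - 1L
  states <- matrix(sample(c("unpaired", "paired", "helix_end"),
                          n_lengths * n_positions, replace = TRUE),
                   n_lengths, n_positions)
  structure_trajectory(states, lengths, seq_len(n_positions),
                       footprint = sample(2:4, 1L))
}
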