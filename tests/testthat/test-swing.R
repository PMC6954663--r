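test_that("smooth_series matches hand-computed truncated-window means", {
  expect_equal(smooth_series(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  expect_equal(smooth_series(rep(2.5, 8), 5), rep(2.5, 8))
  x <- c(0.3, 1.2, 0.8, 2.0)
  expect_identical(smooth_series(x, 1), x)
  # NA-separated runs are smoothed independently, edges truncate per run
  x <- c(1, 1, NA, 0, 3, 0)
  expect_equal(smooth_series(x, 3), c(1, 1, NA, 1.5, 1, 1.5))
  expect_length(smooth_series(numeric(0), 3), 0L)
})

test_that("signals on a constant column are zero/one everywhere defined", {
  m <- col_matrix(rep(0.8, 20))
  sig <- compute_signals(m, threshold_set(w_smooth = 3, i_length = 5))
  def <- !is.na(sig$e)
  expect_true(any(def))
  expect_equal(unname(sig$e[def]), rep(0, sum(def)))
  expect_equal(unname(sig$g[!is.na(sig$g)]), rep(0, sum(!is.na(sig$g))))
  expect_equal(unname(sig$rel[def]), rep(1, sum(def)))
})

test_that("step column signals match brute-force evaluation of the definitions", {
  lengths <- 40:60
  m <- col_matrix(step_series(lengths, at = 50), lengths)
  ts <- threshold_set(w_smooth = 1, i_length = 5)
  sig <- compute_signals(m, ts)
  i50 <- which(lengths == 50)
  expect_equal(unname(sig$e[i50, 1]), 1.3)
  # g accumulates e over the i_length lengths after the step
  g_after <- sig$g[i50:(i50 + 4), 1]
  expect_true(all(diff(g_after) > 0))
  expect_equal(unname(sig$g[i50 + 4, 1]), sum(sig$e[i50:(i50 + 4), 1]))
  # before the step everything is flat
  expect_equal(unname(sig$e[i50 - 1, 1]), 0)
})

test_that("columns with too few preceding lengths yield no signal", {
  m <- col_matrix(c(0.5, 0.9, 0.7), lengths = 30:32)
  sig <- compute_signals(m, threshold_set(i_length = 5))
  expect_true(all(is.na(sig$e)))
  expect_true(all(is.na(sig$g)))
  fl <- swing_flags(m, threshold_set(i_length = 5))
  expect_false(any(fl$up | fl$down))
})

test_that("a single up step yields exactly one up event starting near the step", {
  lengths <- 40:60
  m <- col_matrix(step_series(lengths, at = 50), lengths)
  ev <- detect_swings(m, step_ts())
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$direction, "up")
  expect_true(ev$start_length >= 49 && ev$start_length <= 51)
  expect_gt(ev$magnitude, 0)
})

test_that("the mirrored down step yields exactly one down event on the same interval", {
  lengths <- 40:60
  up_m <- col_matrix(step_series(lengths, at = 50), lengths)
  down_m <- col_matrix(step_series(lengths, at = 50, low = 1.5, high = 0.2), lengths)
  up_ev <- detect_swings(up_m, step_ts())
  down_ev <- detect_swings(down_m, step_ts())
  expect_equal(nrow(down_ev), 1L)
  expect_identical(down_ev$direction, "down")
  expect_identical(down_ev$start_length, up_ev$start_length)
  expect_identical(down_ev$end_length, up_ev$end_length)
  expect_lt(down_ev$magnitude, 0)
})

test_that("an all-constant matrix yields zero events", {
  m <- reactivity_matrix(matrix(1, 20, 5), 20:39, 1:5)
  expect_equal(nrow(detect_swings(m, threshold_set())), 0L)
})

test_that("no event starts within the first i_length defined lengths of a column", {
  for (seed in 1:20) {
    m <- random_matrix(seed, n_lengths = 20L, n_positions = 8L)
    ts <- threshold_set(p_up = 0.05, p_down = 0.05, i_up = 0.1, i_down = 0.1,
                        r_up = 0.05, r_down = 0.05, m_floor = 0)
    ev <- detect_swings(m, ts)
    if (nrow(ev) == 0L) next
    first_len <- rm_lengths(m)[1L]
    expect_true(all(ev$start_length >= first_len + ts$i_length))
  }
})

test_that("adding a constant to a column leaves e and g unchanged", {
  for (seed in 1:8) {
    m <- random_matrix(seed)
    shifted <- reactivity_matrix(unclass(m) + 2.5, rm_lengths(m), rm_positions(m))
    ts <- threshold_set()
    s1 <- compute_signals(m, ts); s2 <- compute_signals(shifted, ts)
    expect_equal(s2$e, s1$e)
    expect_equal(s2$g, s1$g)
    expect_false(isTRUE(all.equal(s2$rel, s1$rel)))  # only rel shifts
  }
})

test_that("scaling a column by k scales e and g by k and leaves rel unchanged", {
  for (seed in 1:8) {
    m <- random_matrix(seed)
    k <- 3.7
    scaled <- reactivity_matrix(unclass(m) * k, rm_lengths(m), rm_positions(m))
    ts <- threshold_set()
    s1 <- compute_signals(m, ts); s2 <- compute_signals(scaled, ts)
    expect_equal(s2$e, s1$e * k)
    expect_equal(s2$g, s1$g * k)
    expect_equal(s2$rel, s1$rel)
  }
})

test_that("flagged cells shrink monotonically as PIR thresholds scale up", {
  grid <- c(0.5, 1, 2, 4)
  for (seed in 1:10) {
    m <- random_matrix(seed)
    base <- default_thresholds(m)
    sig <- compute_signals(m, base)
    prev <- NULL
    for (a in grid) {
      fl <- swing_flags(sig, scale_pir(base, a))
      if (!is.null(prev)) {
        expect_true(all(prev$up | !fl$up))
        expect_true(all(prev$down | !fl$down))
      }
      prev <- fl
    }
  }
})

test_that("elbow selection picks the point closest to the origin", {
  alpha <- 1:10
  n <- c(100, 40, 18, 10, 7, 5, 4, 3, 2, 1)
  # brute-force oracle over the normalized points
  an <- (alpha - min(alpha)) / diff(range(alpha))
  nn <- (n - min(n)) / diff(range(n))
  oracle <- which.min(sqrt(an^2 + nn^2))
  expect_identical(elbow_select(alpha, n), oracle)
  expect_identical(oracle, 3L)  # frozen from the brute-force evaluation
  # constant curve: tie broken toward the smallest factor
  expect_identical(elbow_select(1:5, rep(7, 5)), 1L)
  expect_error(elbow_select(c(1, 2), c(3, 2)), "at least 3")
  expect_error(elbow_select(c(2, 1, 3), c(3, 2, 1)), "strictly increasing")
})

test_that("autotune returns the base scaled by the elbow factor", {
  m <- random_matrix(3, n_lengths = 25L, n_positions = 10L)
  ts <- autotune_thresholds(m)
  a <- attr(ts, "alpha")
  curve <- attr(ts, "curve")
  expect_equal(nrow(curve), 21L)
  # counts must be non-increasing in the scale factor
  expect_true(all(diff(curve$n_cells) <= 0))
  base <- default_thresholds(m)
  expect_equal(ts$p_up, base$p_up * a)
  expect_equal(ts$m_floor, base$m_floor * a)
})

test_that("autotune warns and returns the smallest factor when nothing flags", {
  m <- reactivity_matrix(matrix(1, 20, 4), 20:39, 1:4)
  base <- threshold_set()
  expect_warning(ts <- autotune_thresholds(m, base = base, grid = c(1, 2, 3)),
                 "no cells flagged")
  expect_equal(ts$p_up, base$p_up * 1)
})

test_that("production flags agree with the naive oracle on small matrices", {
  for (seed in 1:12) {
    m <- random_matrix(seed, n_lengths = 12L, n_positions = 6L)
    ts <- threshold_set(p_up = 0.15, p_down = 0.12, i_up = 0.3, i_down = 0.25,
                        r_up = 0.2, r_down = 0.25, m_floor = 0.05,
                        w_smooth = 3, i_length = 3)
    fl <- swing_flags(m, ts)
    or <- oracle_swing_flags(m, ts)
    expect_identical(unname(fl$up), or$up)
    expect_identical(unname(fl$down), or$down)
  }
})
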