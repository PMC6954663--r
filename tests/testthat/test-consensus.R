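test_that("three identical replicate tables give identical consensus with support 3", {
  t <- random_event_table(1)
  cons <- consensus_events(list(t, t, t), tol = 3)
  expect_equal(nrow(cons), nrow(t))
  expect_true(all(cons$n_replicates_supporting == 3L))
  expect_equal(as.data.frame(cons)[c("nucleotide", "class", "direction",
                                     "start_length", "end_length")],
               as.data.frame(sort_events(t))[c("nucleotide", "class", "direction",
                                               "start_length", "end_length")])
})

test_that("events present in only 2 of 3 replicates are never emitted", {
  e <- function(nuc, start) event_table(nucleotide = nuc, class = "swing",
                                        direction = "up", start_length = start,
                                        end_length = start + 2L, magnitude = 1)
  shared <- e(5L, 100L)
  extra <- e(9L, 60L)
  cons <- consensus_events(list(rbind(shared, extra), rbind(shared, extra), shared),
                           tol = 3)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$nucleotide, 5L)
  # property over random tables: every consensus event must be matchable in
  # every replicate
  for (seed in 1:10) {
    tabs <- lapply(seed * 10 + 1:3, random_event_table)
    cons <- consensus_events(tabs, tol = 3)
    for (r in seq_len(nrow(cons))) {
      for (tab in tabs) {
        hit <- tab$nucleotide == cons$nucleotide[r] &
          tab$class == cons$class[r] & tab$direction == cons$direction[r] &
          (tab$start_length - 3) <= cons$end_length[r] + 3 &
          (cons$start_length[r] - 3) <= tab$end_length + 3
        expect_true(any(hit))
      }
    }
  }
})

test_that("consensus interval is the lower median of member coordinates", {
  e <- function(start) event_table(nucleotide = 5L, class = "swing",
                                   direction = "up", start_length = start,
                                   end_length = start + 4L, magnitude = 1)
  cons <- consensus_events(list(e(100L), e(102L), e(104L)), tol = 3)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start_length, 102L)
  expect_equal(cons$end_length, 106L)
  # even count: lower median
  cons2 <- consensus_events(list(e(100L), e(102L)), tol = 3)
  expect_equal(cons2$start_length, 100L)
  # magnitude is the mean of matched magnitudes
  a <- e(100L); a$magnitude <- 2
  cons3 <- consensus_events(list(a, e(102L)), tol = 3)
  expect_equal(cons3$magnitude, 1.5)
})

test_that("single-replicate consensus is the identity and order is irrelevant", {
  for (seed in 1:8) {
    t <- sort_events(random_event_table(seed))
    cons <- consensus_events(list(t), tol = 3)
    expect_equal(as.data.frame(cons)[c("nucleotide", "class", "direction",
                                       "start_length", "end_length", "magnitude")],
                 as.data.frame(t)[c("nucleotide", "class", "direction",
                                    "start_length", "end_length", "magnitude")])
    tabs <- lapply(seed * 100 + 1:3, random_event_table)
    c1 <- consensus_events(tabs, tol = 3)
    c2 <- consensus_events(tabs[c(3, 1, 2)], tol = 3)
    expect_equal(as.data.frame(c1), as.data.frame(c2))
  }
  # two nearby events of a lone replicate must not merge
  t <- event_table(nucleotide = c(4L, 4L), class = "swing", direction = "up",
                   start_length = c(50L, 53L), end_length = c(51L, 54L),
                   magnitude = 1)
  expect_equal(nrow(consensus_events(list(t), tol = 5)), 2L)
  expect_error(consensus_events(list()), "at least one")
})

test_that("swings are never confirmed by ramps", {
  sw <- event_table(nucleotide = 5L, class = "swing", direction = "up",
                    start_length = 100L, end_length = 102L, magnitude = 1)
  rp <- sw; rp$class <- "ramp"
  expect_equal(nrow(consensus_events(list(sw, rp), tol = 3)), 0L)
})

test_that("concurrent grouping follows direction and start-gap rules", {
  t <- event_table(nucleotide = c(3L, 8L), class = "swing", direction = "up",
                   start_length = c(100L, 101L), end_length = c(102L, 103L),
                   magnitude = 1)
  g <- group_concurrent(t, max_start_gap = 2)
  expect_true(!anyNA(g$group_id) && length(unique(g$group_id)) == 1L)

  t2 <- event_table(nucleotide = c(3L, 8L), class = "swing",
                    direction = c("up", "down"), start_length = 100L,
                    end_length = 102L, magnitude = c(1, -1))
  g2 <- group_concurrent(t2, max_start_gap = 2)
  expect_true(all(is.na(g2$group_id)))

  # chain 100, 102, 104 with gap 2 is one transitive component of 3
  t3 <- event_table(nucleotide = c(1L, 2L, 3L), class = "swing", direction = "up",
                    start_length = c(100L, 102L, 104L),
                    end_length = c(101L, 103L, 105L), magnitude = 1)
  g3 <- group_concurrent(t3, max_start_gap = 2)
  expect_equal(length(unique(g3$group_id)), 1L)
  expect_true(!anyNA(g3$group_id))
  # gap 0 groups only exact start ties
  g4 <- group_concurrent(t3, max_start_gap = 0)
  expect_true(all(is.na(g4$group_id)))
  # unbounded gap: one group per direction
  t5 <- rbind(t3, event_table(nucleotide = 9L, class = "swing",
                              direction = "down", start_length = 130L,
                              end_length = 131L, magnitude = -1))
  g5 <- group_concurrent(validate_event_table(t5), max_start_gap = 10000)
  expect_equal(length(unique(g5$group_id[g5$direction == "up"])), 1L)
  expect_true(is.na(g5$group_id[g5$direction == "down"]))  # singleton
})

test_that("lagged up-then-down pairs follow the nearest-up rule", {
  e <- function(dir, start) event_table(nucleotide = 7L, class = "swing",
                                        direction = dir, start_length = start,
                                        end_length = start + 1L,
                                        magnitude = if (dir == "up") 1 else -1)
  # the motif: upswing ~12 lengths before the downswing
  t <- validate_event_table(rbind(e("up", 75L), e("down", 87L)))
  p <- find_lagged_pairs(t, 8, 16)
  expect_equal(nrow(p), 1L)
  expect_equal(p$lag, 12L)
  # lag outside the window
  t2 <- validate_event_table(rbind(e("up", 75L), e("down", 120L)))
  expect_equal(nrow(find_lagged_pairs(t2, 8, 16)), 0L)
  # nearest up wins the contested downswing
  t3 <- validate_event_table(rbind(e("up", 70L), e("up", 80L), e("down", 88L)))
  p3 <- find_lagged_pairs(t3, 8, 16)
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$up_start, 80L)
  expect_equal(p3$down_start, 88L)
  expect_equal(p3$lag, 8L)
  # ramps never participate
  t4 <- validate_event_table(rbind(e("up", 75L), e("down", 87L)))
  t4$class <- "ramp"
  expect_equal(nrow(find_lagged_pairs(validate_event_table(t4), 8, 16)), 0L)
})
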