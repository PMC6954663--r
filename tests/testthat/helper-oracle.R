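# Naive reference implementation of the swing flag rules, evaluated cell by
# cell straight from the definitions.  Deliberately independent of the
# production code path (no smooth_series / compute_signals / swing_flags).

oracle_swing_flags <- function(m, ts) {
  vals <- unclass(m)
  nr <- nrow(vals); nc <- ncol(vals)
  up <- down <- matrix(FALSE, nr, nc)
  h <- (ts$w_smooth - 1) / 2
  L <- ts$i_length
  for (j in seq_len(nc)) {
    x <- vals[, j]
    # contiguous defined segment membership, recomputed the dumb way
    seg_of <- rep(NA_integer_, nr)
    seg <- 0L
    for (i in seq_len(nr)) {
      if (is.na(x[i])) next
      if (i == 1L || is.na(x[i - 1L])) seg <- seg + 1L
      seg_of[i] <- seg
    }
    sm <- function(i) {
      ks <- (i - h):(i + h)
      ks <- ks[ks >= 1 & ks <= nr]
      ks <- ks[!is.na(seg_of[ks]) & seg_of[ks] == seg_of[i]]
      mean(x[ks])
    }
    for (i in seq_len(nr)) {
      if (is.na(x[i])) next
      bw <- (i - L):(i - 1L)
      if (any(bw < 1) || any(is.na(seg_of[bw])) ||
          any(seg_of[bw] != seg_of[i])) next
      b_i <- mean(vapply(bw, sm, numeric(1)))
      e_i <- sm(i) - b_i
      rel_i <- sm(i) / max(b_i, 1e-6)
      # g needs e defined over the trailing i_length cells
      gw <- (i - L + 1L):i
      g_i <- 0; g_ok <- TRUE
      for (k in gw) {
        bwk <- (k - L):(k - 1L)
        if (any(bwk < 1) || any(is.na(seg_of[bwk])) ||
            any(seg_of[bwk] != seg_of[k]) || is.na(seg_of[k]) ||
            seg_of[k] != seg_of[i]) { g_ok <- FALSE; break }
        g_i <- g_i + (sm(k) - mean(vapply(bwk, sm, numeric(1))))
      }
      if (!g_ok) next
      if (e_i >= ts$p_up && g_i >= ts$i_up && rel_i >= 1 + ts$r_up)
        up[i, j] <- TRUE
      if (-e_i >= ts$p_down && -g_i >= ts$i_down && rel_i <= 1 / (1 + ts$r_down))
        down[i, j] <- TRUE
    }
  }
  list(up = up, down = down)
}

# Naive ramp reference: enumerate every window with lm(), apply the flag
# rules, and merge overlapping windows by hand.
oracle_ramps <- function(m, rt) {
  vals <- unclass(m)
  lens <- rm_lengths(m); pos <- rm_positions(m)
  w <- rt$w_ramp
  out <- list()
  for (j in seq_along(pos)) {
    y_all <- vals[, j]
    flagged <- list(up = integer(0), down = integer(0))
    for (t in seq_len(max(0L, nrow(vals) - w + 1L))) {
      y <- y_all[t:(t + w - 1L)]
      if (anyNA(y)) next
      x <- as.numeric(lens[t:(t + w - 1L)])
      if (stats::var(y) == 0) { slope <- 0; r2 <- 0 } else {
        fit <- stats::lm(y ~ x)
        slope <- unname(stats::coef(fit)[2L])
        # suppress the "essentially perfect fit" warning on exact lines
        r2 <- suppressWarnings(summary(fit)$r.squared)
      }
      if (slope >= rt$slope_min && r2 >= rt$fit_min &&
          slope * (w - 1) >= rt$net_min) flagged$up <- c(flagged$up, t)
      if (-slope >= rt$slope_min && r2 >= rt$fit_min &&
          -slope * (w - 1) >= rt$net_min) flagged$down <- c(flagged$down, t)
    }
    for (dir in c("up", "down")) {
      st <- flagged[[dir]]
      while (length(st) > 0L) {
        grp <- st[1L]; st <- st[-1L]
        repeat {
          grow <- which(st <= max(grp) + w - 1L)
          if (length(grow) == 0L) break
          grp <- c(grp, st[grow]); st <- st[-grow]
        }
        out[[length(out) + 1L]] <- data.frame(
          nucleotide = pos[j], direction = dir,
          start_length = lens[min(grp)], end_length = lens[max(grp) + w - 1L])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(nucleotide = integer(), direction = character(),
                      start_length = integer(), end_length = integer()))
  df <- do.call(rbind, out)
  df[order(df$nucleotide, df$start_length, df$direction), , drop = FALSE]
}
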