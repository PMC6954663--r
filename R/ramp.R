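#' Ramp-detection thresholds
#'
#' Ramps are gradual reactivity changes spanning many transcript lengths,
#' detected by ordinary least-squares regression of reactivity against
#' transcript length in a sliding window.  A window flags when the absolute
#' slope, the coefficient of determination and the implied net change across
#' the window all clear their thresholds.
#'
#' @param w_ramp regression window length (lengths, >= 3).
#' @param slope_min minimum absolute slope (reactivity per length, > 0).
#' @param fit_min minimum coefficient of determination R^2 (in `[0, 1]`).
#' @param net_min minimum `|slope| * (w_ramp - 1)` net change (>= 0).
#' @return object of class `ramp_thresholds`.
#' @export
ramp_thresholds <- function(w_ramp = 15L, slope_min = 0.01, fit_min = 0.5,
                            net_min = 0.15) {
  rt <- list(w_ramp = as.integer(w_ramp), slope_min = slope_min,
             fit_min = fit_min, net_min = net_min)
  if (rt$w_ramp < 3L) stop("w_ramp must be >= 3")
  if (slope_min <= 0) stop("slope_min must be > 0")
  if (fit_min < 0 || fit_min > 1) stop("fit_min must be in [0, 1]")
  if (net_min < 0) stop("net_min must be >= 0")
  class(rt) <- "ramp_thresholds"
  rt
}

ols_slope_r2 <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  if (syy == 0 || sxx == 0) return(c(slope = 0, r2 = 0))
  slope <- sxy / sxx
  c(slope = slope, r2 = sxy^2 / (sxx * syy))
}

#' Sliding-window OLS fit
#'
#' Ordinary least-squares slope of reactivity against transcript length over
#' the window starting at index `t` (length `w_ramp`), and its coefficient of
#' determination.  A zero-variance (constant) window returns slope 0 and R^2
#' defined as 0.  Windows containing any undefined cell yield no fit.
#'
#' @param series numeric reactivities (may contain `NA`).
#' @param lengths transcript lengths corresponding to `series`; defaults to
#'   the series index.
#' @param t window start index.
#' @param w_ramp window length.
#' @return named numeric `c(slope, r2)`, or `NULL` when the window has an
#'   undefined cell or runs off the series.
#' @export
window_fit <- function(series, lengths = seq_along(series), t, w_ramp) {
  idx <- t:(t + w_ramp - 1L)
  if (t < 1L || idx[length(idx)] > length(series)) return(NULL)
  y <- series[idx]
  if (anyNA(y)) return(NULL)
  ols_slope_r2(as.numeric(lengths[idx]), y)
}

#' Detect ramp events
#'
#' Slides a `w_ramp`-length OLS window down each nucleotide column; a window
#' flags up when `slope >= slope_min`, `r2 >= fit_min` and
#' `slope * (w_ramp - 1) >= net_min` (down symmetric with the slope sign
#' reversed).  Overlapping same-direction flagged windows merge into one
#' maximal ramp covering the union of their length spans; the merged event's
#' magnitude is the net change fitted over the merged span (single OLS slope
#' times the span in lengths).
#'
#' @param m a [reactivity_matrix].
#' @param rt a [ramp_thresholds].
#' @param mask_3prime optional integer `k`: windows touching cells within the
#'   last `k` positions of a transcript (the 3' terminal region, where
#'   upramps tend to be experimental artifacts) are skipped; 0 disables.
#' @return an [event_table] of ramp events.
#' @export
detect_ramps <- function(m, rt = ramp_thresholds(), mask_3prime = 0L) {
  validate_reactivity_matrix(m)
  lens <- rm_lengths(m)
  pos <- rm_positions(m)
  w <- rt$w_ramp
  rows <- list()
  for (j in seq_along(pos)) {
    y <- unclass(m)[, j]
    if (mask_3prime > 0L) {
      y[pos[j] > lens - mask_3prime] <- NA_real_  # 3'-terminal footprint zone
    }
    flags_up <- integer(0); flags_down <- integer(0)
    for (t in seq_len(max(0L, length(y) - w + 1L))) {
      fit <- window_fit(y, lens, t, w)
      if (is.null(fit)) next
      net <- fit[["slope"]] * (w - 1L)
      if (fit[["slope"]] >= rt$slope_min && fit[["r2"]] >= rt$fit_min &&
          net >= rt$net_min) flags_up <- c(flags_up, t)
      if (-fit[["slope"]] >= rt$slope_min && fit[["r2"]] >= rt$fit_min &&
          -net >= rt$net_min) flags_down <- c(flags_down, t)
    }
    for (dir in c("up", "down")) {
      starts <- if (dir == "up") flags_up else flags_down
      for (grp in merge_overlapping_windows(starts, w)) {
        i0 <- grp[1L]; i1 <- grp[length(grp)] + w - 1L
        fit <- ols_slope_r2(as.numeric(lens[i0:i1]), y[i0:i1])
        rows[[length(rows) + 1L]] <- data.frame(
          nucleotide = pos[j], class = "ramp", direction = dir,
          start_length = lens[i0], end_length = lens[i1],
          magnitude = fit[["slope"]] * (lens[i1] - lens[i0]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(event_table())
  df <- do.call(rbind, rows)
  # a merged fit can in principle disagree in sign with its windows; clamp to 0
  mag <- ifelse(df$direction == "up", pmax(df$magnitude, 0), pmin(df$magnitude, 0))
  sort_events(event_table(nucleotide = df$nucleotide, class = df$class,
                          direction = df$direction,
                          start_length = df$start_length,
                          end_length = df$end_length, magnitude = mag))
}

# group window start indices whose [t, t + w - 1] spans overlap (or abut
# within the window, i.e. consecutive starts differ by < w)
merge_overlapping_windows <- function(starts, w) {
  if (length(starts) == 0L) return(list())
  starts <- sort(starts)
  groups <- list()
  cur <- starts[1L]
  for (s in starts[-1L]) {
    if (s <= cur[length(cur)] + w - 1L) cur <- c(cur, s)
    else { groups[[length(groups) + 1L]] <- cur; cur <- s }
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}
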