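#' Swing-detection threshold set
#'
#' Holds the seven proportional-integral-relative (PIR) thresholds that govern
#' swing detection, plus the structural parameters of the detector.  A cell is
#' up-flagged only when the proportional term, the trailing integral term and
#' the relative (fold-change) term all clear their thresholds; `m_floor`
#' additionally rejects events whose absolute smoothed-reactivity change is
#' too small.  Structural parameters: `w_smooth` (centered smoothing window,
#' odd), `i_length` (baseline/integral window L_I), `min_duration` (minimum
#' flagged lengths per event), `merge_gap` (maximum unflagged gap merged into
#' one event).
#'
#' @param p_up,p_down proportional thresholds (reactivity units, > 0).
#' @param i_up,i_down integral thresholds (reactivity x lengths, > 0).
#' @param r_up,r_down relative-change thresholds (fold change, > 0).
#' @param m_floor minimum absolute smoothed change across an event (>= 0).
#' @param w_smooth odd smoothing window length (lengths).
#' @param i_length baseline/integral window length (lengths, >= 1).
#' @param min_duration minimum flagged lengths per event (>= 1).
#' @param merge_gap maximum unflagged gap merged into one event (>= 0).
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(p_up = 0.2, p_down = 0.2, i_up = 0.5, i_down = 0.5,
                          r_up = 0.3, r_down = 0.3, m_floor = 0.1,
                          w_smooth = 3L, i_length = 5L, min_duration = 2L,
                          merge_gap = 1L) {
  ts <- list(p_up = p_up, p_down = p_down, i_up = i_up, i_down = i_down,
             r_up = r_up, r_down = r_down, m_floor = m_floor,
             w_smooth = as.integer(w_smooth), i_length = as.integer(i_length),
             min_duration = as.integer(min_duration),
             merge_gap = as.integer(merge_gap))
  class(ts) <- "threshold_set"
  validate_threshold_set(ts)
}

PIR_NAMES <- c("p_up", "p_down", "i_up", "i_down", "r_up", "r_down", "m_floor")
STRUCTURAL_NAMES <- c("w_smooth", "i_length", "min_duration", "merge_gap")

#' @rdname threshold_set
#' @param ts object to validate.
#' @export
validate_threshold_set <- function(ts) {
  for (nm in setdiff(PIR_NAMES, "m_floor")) {
    if (!is.numeric(ts[[nm]]) || length(ts[[nm]]) != 1L || ts[[nm]] <= 0)
      stop("threshold ", nm, " must be a single positive number")
  }
  if (!is.numeric(ts$m_floor) || ts$m_floor < 0)
    stop("m_floor must be >= 0")
  if (ts$w_smooth < 1L || ts$w_smooth %% 2L == 0L)
    stop("w_smooth must be an odd integer >= 1")
  if (ts$i_length < 1L) stop("i_length must be >= 1")
  if (ts$min_duration < 1L) stop("min_duration must be >= 1")
  if (ts$merge_gap < 0L) stop("merge_gap must be >= 0")
  invisible(ts)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  for (nm in c(PIR_NAMES, STRUCTURAL_NAMES))
    cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Centered moving average with truncated edges
#'
#' Smooths a per-length reactivity series with a centered window of
#' `w_smooth` lengths.  The series may contain `NA` (undefined) cells; each
#' maximal contiguous defined run is smoothed independently, and at run edges
#' the window truncates to the available points, so output is defined exactly
#' where input is.
#'
#' @param x numeric vector (may contain `NA`).
#' @param w_smooth odd window length; `1` is the identity.
#' @return numeric vector of the same length.
#' @export
smooth_series <- function(x, w_smooth = 3L) {
  w_smooth <- as.integer(w_smooth)
  if (w_smooth < 1L || w_smooth %% 2L == 0L)
    stop("w_smooth must be an odd integer >= 1")
  if (length(x) == 0L) return(numeric(0))
  out <- rep(NA_real_, length(x))
  h <- (w_smooth - 1L) %/% 2L
  for (run in defined_runs(x)) {
    for (i in run) {
      lo <- max(run[1L], i - h)
      hi <- min(run[length(run)], i + h)
      out[i] <- mean(x[lo:hi])
    }
  }
  out
}

# maximal contiguous runs of defined (non-NA) indices
defined_runs <- function(x) {
  idx <- which(!is.na(x))
  if (length(idx) == 0L) return(list())
  splits <- cumsum(c(1L, diff(idx) > 1L))
  unname(split(idx, splits))
}

#' Compute swing-detection signals
#'
#' For each nucleotide column, with `s` the smoothed series
#' ([smooth_series()]): the baseline `b_t` is the mean of `s` over the
#' `i_length` lengths immediately preceding `t`; the proportional term is
#' `e_t = s_t - b_t`; the integral term is the trailing sum
#' `g_t = sum(e_k, k = t - i_length + 1 .. t)`, defined only when every
#' addend is; the relative term is `rel_t = s_t / max(b_t, 1e-6)`.  Windows
#' never span undefined cells, so the first `i_length` lengths of each
#' defined run carry no signal.
#'
#' @param m a [reactivity_matrix].
#' @param ts a [threshold_set] (only structural parameters are used).
#' @return a list of matrices `s_hat`, `b`, `e`, `g`, `rel`, each dimensioned
#'   like `m`, with class `swing_signals`.
#' @export
compute_signals <- function(m, ts = threshold_set()) {
  validate_reactivity_matrix(m)
  validate_threshold_set(ts)
  eps <- 1e-6
  L <- ts$i_length
  dims <- dim(m)
  dn <- dimnames(m)
  blank <- matrix(NA_real_, dims[1L], dims[2L], dimnames = dn)
  s_hat <- b <- e <- g <- rel <- blank
  for (j in seq_len(ncol(m))) {
    x <- unclass(m)[, j]
    s <- smooth_series(x, ts$w_smooth)
    s_hat[, j] <- s
    for (run in defined_runs(x)) {
      r0 <- run[1L]
      for (i in run) {
        if (i - r0 >= L) {
          b[i, j] <- mean(s[(i - L):(i - 1L)])
          e[i, j] <- s[i] - b[i, j]
          rel[i, j] <- s[i] / max(b[i, j], eps)
        }
      }
      for (i in run) {
        ks <- (i - L + 1L):i
        if (all(ks >= r0) && !anyNA(e[ks, j])) g[i, j] <- sum(e[ks, j])
      }
    }
  }
  structure(list(s_hat = s_hat, b = b, e = e, g = g, rel = rel,
                 lengths = rm_lengths(m), positions = rm_positions(m)),
            class = "swing_signals")
}

#' Per-cell swing flags
#'
#' Applies the PIR flag rules to precomputed signals: a cell is up-flagged
#' iff `e >= p_up` and `g >= i_up` and `rel >= 1 + r_up`; down-flagged iff
#' `-e >= p_down` and `-g >= i_down` and `rel <= 1 / (1 + r_down)`.
#' Undefined signal cells never flag.
#'
#' @param m a [reactivity_matrix], or a precomputed `swing_signals` object
#'   (from [compute_signals()]) to avoid recomputation when scanning many
#'   threshold sets.
#' @param ts a [threshold_set].
#' @return list with logical matrices `up` and `down`.
#' @export
swing_flags <- function(m, ts) {
  sig <- if (inherits(m, "swing_signals")) m else compute_signals(m, ts)
  validate_threshold_set(ts)
  e <- sig$e; g <- sig$g; rel <- sig$rel
  up <- !is.na(e) & !is.na(g) & !is.na(rel) &
    e >= ts$p_up & g >= ts$i_up & rel >= 1 + ts$r_up
  down <- !is.na(e) & !is.na(g) & !is.na(rel) &
    -e >= ts$p_down & -g >= ts$i_down & rel <= 1 / (1 + ts$r_down)
  list(up = up, down = down)
}

# merge flagged indices into candidate runs, allowing gaps of <= merge_gap
# defined-but-unflagged cells; undefined cells always break a run
merge_flag_runs <- function(flagged_idx, defined, merge_gap) {
  if (length(flagged_idx) == 0L) return(list())
  groups <- list()
  cur <- flagged_idx[1L]
  for (k in seq_along(flagged_idx)[-1L]) {
    a <- cur[length(cur)]
    bidx <- flagged_idx[k]
    gap <- bidx - a - 1L
    gap_ok <- gap <= merge_gap &&
      (gap == 0L || all(defined[(a + 1L):(bidx - 1L)]))
    if (gap_ok) cur <- c(cur, bidx)
    else { groups[[length(groups) + 1L]] <- cur; cur <- bidx }
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}

#' Detect swing events
#'
#' Flags cells with [swing_flags()], merges same-direction flag runs within
#' each nucleotide column (allowing gaps of at most `merge_gap` defined but
#' unflagged lengths), and discards candidates with fewer than `min_duration`
#' flagged lengths or whose maximum absolute smoothed change from the
#' event-start baseline is below `m_floor`.  Event magnitude is the signed
#' difference between the smoothed value at the event end and the baseline at
#' the event start.
#'
#' @param m a [reactivity_matrix].
#' @param ts a [threshold_set].
#' @param signals optional precomputed [compute_signals()] result.
#' @return an [event_table] of swing events.
#' @export
detect_swings <- function(m, ts = threshold_set(), signals = NULL) {
  sig <- if (is.null(signals)) compute_signals(m, ts) else signals
  fl <- swing_flags(sig, ts)
  lens <- sig$lengths
  pos <- sig$positions
  rows <- list()
  for (j in seq_along(pos)) {
    defined <- !is.na(sig$e[, j])
    for (dir in c("up", "down")) {
      flags <- fl[[dir]][, j]
      for (run in merge_flag_runs(which(flags), defined, ts$merge_gap)) {
        if (length(run) < ts$min_duration) next
        i0 <- run[1L]; i1 <- run[length(run)]
        b0 <- sig$b[i0, j]
        span <- i0:i1
        dev <- abs(sig$s_hat[span, j] - b0)
        if (max(dev, na.rm = TRUE) < ts$m_floor) next
        rows[[length(rows) + 1L]] <- data.frame(
          nucleotide = pos[j], class = "swing", direction = dir,
          start_length = lens[i0], end_length = lens[i1],
          magnitude = sig$s_hat[i1, j] - b0,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(event_table())
  df <- do.call(rbind, rows)
  # merged runs over non-monotone stretches can leave a residual magnitude of
  # the wrong sign; clamp to 0 so the sign always matches the direction
  mag <- ifelse(df$direction == "up", pmax(df$magnitude, 0), pmin(df$magnitude, 0))
  sort_events(event_table(nucleotide = df$nucleotide, class = df$class,
                          direction = df$direction,
                          start_length = df$start_length,
                          end_length = df$end_length,
                          magnitude = mag))
}

#' Data-derived base threshold set
#'
#' Derives a starting PIR threshold set from the data itself: the
#' proportional and integral thresholds are the 60th percentile of the
#' absolute proportional and integral signals pooled over all replicates;
#' the relative thresholds default to 0.3 and `m_floor` to 0.1.  Intended as
#' the base for [autotune_thresholds()], which rescales it.
#'
#' @param m_list a [reactivity_matrix] or list of replicate matrices.
#' @param ts structural parameters to use (PIR values in it are ignored).
#' @param probs quantile used for the p and i channels.
#' @return a [threshold_set].
#' @export
default_thresholds <- function(m_list, ts = threshold_set(), probs = 0.6) {
  if (inherits(m_list, "reactivity_matrix")) m_list <- list(m_list)
  abs_e <- abs_g <- numeric(0)
  for (m in m_list) {
    sig <- compute_signals(m, ts)
    abs_e <- c(abs_e, abs(sig$e[!is.na(sig$e)]))
    abs_g <- c(abs_g, abs(sig$g[!is.na(sig$g)]))
  }
  p <- stats::quantile(abs_e, probs, names = FALSE)
  i <- stats::quantile(abs_g, probs, names = FALSE)
  if (!length(abs_e) || p <= 0) p <- 1e-3
  if (!length(abs_g) || i <= 0) i <- 1e-3
  threshold_set(p_up = p, p_down = p, i_up = i, i_down = i,
                r_up = 0.3, r_down = 0.3, m_floor = 0.1,
                w_smooth = ts$w_smooth, i_length = ts$i_length,
                min_duration = ts$min_duration, merge_gap = ts$merge_gap)
}

#' Scale the seven PIR thresholds
#' @param ts a [threshold_set].
#' @param alpha positive scale factor applied to all seven PIR thresholds
#'   (structural parameters untouched).
#' @return the scaled [threshold_set].
#' @export
scale_pir <- function(ts, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  for (nm in PIR_NAMES) ts[[nm]] <- ts[[nm]] * alpha
  validate_threshold_set(ts)
  ts
}

#' Closest-to-origin elbow selection
#'
#' Given a grid of threshold scale factors and the corresponding detected
#' event-cell counts, min-max normalizes both axes to `[0, 1]` and returns the
#' index of the grid point closest to the origin (the elbow of the
#' rapidly-decreasing count curve).  Ties break toward the smaller scale
#' factor; a degenerate (constant) axis normalizes to all zeros.
#'
#' @param alpha strictly increasing positive scale factors (>= 3 of them).
#' @param n_cells event-cell counts, one per `alpha`.
#' @return integer index into `alpha`.
#' @export
elbow_select <- function(alpha, n_cells) {
  if (length(alpha) < 3L) stop("need at least 3 grid points")
  if (any(diff(alpha) <= 0) || any(alpha <= 0))
    stop("alpha grid must be strictly increasing and positive")
  if (length(n_cells) != length(alpha)) stop("alpha and n_cells lengths differ")
  norm01 <- function(v) {
    r <- range(v)
    if (r[2L] == r[1L]) return(rep(0, length(v)))
    (v - r[1L]) / (r[2L] - r[1L])
  }
  d <- sqrt(norm01(alpha)^2 + norm01(n_cells)^2)
  which.min(d)  # which.min takes the first (smallest alpha) on ties
}

# consensus flagged cells: a cell counts only if flagged in the same
# direction in every replicate
consensus_flag_count <- function(flag_list) {
  up <- Reduce(`&`, lapply(flag_list, `[[`, "up"))
  down <- Reduce(`&`, lapply(flag_list, `[[`, "down"))
  sum(up) + sum(down)
}

#' Automated threshold selection
#'
#' Scales the seven PIR thresholds of `base` by each factor of `grid`, counts
#' the consensus flagged (nucleotide, length) cells across replicates at each
#' scale, and returns `base` rescaled by the factor at the elbow of the
#' count-vs-scale curve, chosen as the point closest to the origin after
#' min-max normalization of both axes ([elbow_select()]).  Because every flag
#' condition is a one-sided comparison, the flagged-cell set shrinks
#' monotonically as the scale grows.
#'
#' @param m_list a [reactivity_matrix] or list of replicate matrices.
#' @param base base [threshold_set]; default derives one from the data with
#'   [default_thresholds()].
#' @param grid >= 3 strictly increasing positive scale factors; default 21
#'   log-spaced factors in `[0.25, 4]`.
#' @return the selected [threshold_set], with attributes `alpha` (the chosen
#'   factor) and `curve` (a data.frame of the grid and counts).
#' @export
autotune_thresholds <- function(m_list, base = NULL,
                                grid = exp(seq(log(0.25), log(4), length.out = 21))) {
  if (inherits(m_list, "reactivity_matrix")) m_list <- list(m_list)
  if (length(m_list) == 0L) stop("need at least one replicate matrix")
  if (is.null(base)) base <- default_thresholds(m_list)
  if (length(grid) < 3L || any(diff(grid) <= 0) || any(grid <= 0))
    stop("grid must be >= 3 strictly increasing positive scale factors")
  sigs <- lapply(m_list, compute_signals, ts = base)
  n_cells <- vapply(grid, function(a) {
    ts_a <- scale_pir(base, a)
    consensus_flag_count(lapply(sigs, swing_flags, ts = ts_a))
  }, numeric(1))
  if (all(n_cells == 0)) {
    warning("no cells flagged at any scale factor; returning the smallest")
    k <- 1L
  } else {
    k <- elbow_select(grid, n_cells)
  }
  out <- scale_pir(base, grid[k])
  attr(out, "alpha") <- grid[k]
  attr(out, "curve") <- data.frame(alpha = grid, n_cells = n_cells)
  out
}
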