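#' Perturb PIR thresholds
#'
#' The paper-style perturbation scenarios: `stringent` applies a 100%
#' increase (x2) to all seven PIR thresholds, `lenient` a 50% decrease
#' (x0.5); `single` multiplies one named threshold by `factor`; `pair`
#' applies x2 for an up-perturbation and x0.5 for a down-perturbation to two
#' named thresholds.  Only the seven PIR thresholds may be perturbed unless
#' `structural = TRUE`, which additionally allows the integer structural
#' parameters (`w_smooth`, `i_length`, `min_duration`, `merge_gap`; values
#' are rounded and clamped to legal values, with `w_smooth` forced odd).
#'
#' @param ts a [threshold_set].
#' @param what one of `"stringent"`, `"lenient"`, `"single"`, `"pair"`.
#' @param param threshold name for `what = "single"`.
#' @param factor multiplier for `what = "single"`.
#' @param params character pair of threshold names for `what = "pair"`.
#' @param dirs directions (`"up"` = x2, `"down"` = x0.5) for `what = "pair"`.
#' @param structural allow structural parameters in `single`.
#' @return the perturbed [threshold_set].
#' @export
perturb_thresholds <- function(ts, what = c("stringent", "lenient", "single", "pair"),
                               param = NULL, factor = NULL,
                               params = NULL, dirs = NULL,
                               structural = FALSE) {
  what <- match.arg(what)
  validate_threshold_set(ts)
  apply_one <- function(ts, nm, f) {
    if (nm %in% PIR_NAMES) {
      ts[[nm]] <- ts[[nm]] * f
    } else if (nm %in% STRUCTURAL_NAMES) {
      if (!structural)
        stop("'", nm, "' is not one of the seven PIR thresholds ",
             "(set structural = TRUE to perturb structural parameters)")
      v <- max(1L, as.integer(round(ts[[nm]] * f)))
      if (nm == "w_smooth" && v %% 2L == 0L) v <- v + 1L
      if (nm == "merge_gap") v <- max(0L, as.integer(round(ts[[nm]] * f)))
      ts[[nm]] <- v
    } else stop("unknown threshold parameter: ", nm)
    ts
  }
  if (what == "stringent") {
    for (nm in PIR_NAMES) ts <- apply_one(ts, nm, 2.0)
  } else if (what == "lenient") {
    for (nm in PIR_NAMES) ts <- apply_one(ts, nm, 0.5)
  } else if (what == "single") {
    if (is.null(param) || is.null(factor)) stop("single perturbation needs param and factor")
    ts <- apply_one(ts, param, factor)
  } else {
    if (is.null(params) || length(params) != 2L ||
        is.null(dirs) || length(dirs) != 2L)
      stop("pair perturbation needs two params and two dirs")
    if (!all(dirs %in% c("up", "down"))) stop("dirs must be 'up' or 'down'")
    for (k in 1:2) ts <- apply_one(ts, params[k], if (dirs[k] == "up") 2.0 else 0.5)
  }
  validate_threshold_set(ts)
  ts
}

#' Pairwise global sensitivity cohort
#'
#' Enumerates every unordered pair of the seven PIR thresholds (21 pairs)
#' under the four direction variants up-up, up-down, down-up, down-down
#' (x2 / x0.5), for a cohort of 84 perturbed runs.  Each run flags swing
#' cells per replicate, intersects the flags across replicates (consensus
#' cells), and detects + consensus-merges events.  Agreement maps report, per
#' (nucleotide, length, direction), the fraction of the 84 runs flagging that
#' cell; agreement is computed on flagged cells before event merging, since
#' disagreements cluster around the originals in transcript length rather
#' than at the nucleotide level.
#'
#' @param m_list a [reactivity_matrix] or list of replicate matrices.
#' @param ts the selected (baseline) [threshold_set] to perturb.
#' @param tol consensus length tolerance.
#' @return object of class `sensitivity_report`: list with `cohort`
#'   (data.frame: param_a, dir_a, param_b, dir_b, n_events, n_up_cells,
#'   n_down_cells), `events` (list of 84 consensus [event_table]s),
#'   `agreement` (list of `up`/`down` matrices in `[0, 1]`), and `baseline`
#'   (unperturbed consensus [event_table]).
#' @export
pairwise_cohort <- function(m_list, ts, tol = 3L) {
  if (inherits(m_list, "reactivity_matrix")) m_list <- list(m_list)
  validate_threshold_set(ts)
  sigs <- lapply(m_list, compute_signals, ts = ts)
  run_with <- function(ts_run) {
    fl <- lapply(sigs, swing_flags, ts = ts_run)
    tabs <- lapply(seq_along(m_list), function(r)
      detect_swings(m_list[[r]], ts_run, signals = sigs[[r]]))
    list(flags = fl, consensus = consensus_events(tabs, tol = tol))
  }
  pairs <- utils::combn(PIR_NAMES, 2L)
  variants <- list(c("up", "up"), c("up", "down"), c("down", "up"),
                   c("down", "down"))
  dims <- dim(sigs[[1L]]$e)
  agree_up <- matrix(0, dims[1L], dims[2L], dimnames = dimnames(sigs[[1L]]$e))
  agree_down <- agree_up
  cohort <- list(); events <- list()
  for (p in seq_len(ncol(pairs))) {
    for (v in variants) {
      ts_run <- perturb_thresholds(ts, "pair", params = pairs[, p], dirs = v)
      res <- run_with(ts_run)
      up_all <- Reduce(`&`, lapply(res$flags, `[[`, "up"))
      down_all <- Reduce(`&`, lapply(res$flags, `[[`, "down"))
      agree_up <- agree_up + up_all
      agree_down <- agree_down + down_all
      cohort[[length(cohort) + 1L]] <- data.frame(
        param_a = pairs[1L, p], dir_a = v[1L],
        param_b = pairs[2L, p], dir_b = v[2L],
        n_events = nrow(res$consensus),
        n_up_cells = sum(up_all), n_down_cells = sum(down_all),
        stringsAsFactors = FALSE)
      events[[length(events) + 1L]] <- res$consensus
    }
  }
  n_runs <- length(cohort)
  baseline <- run_with(ts)$consensus
  structure(list(cohort = do.call(rbind, cohort), events = events,
                 agreement = list(up = agree_up / n_runs,
                                  down = agree_down / n_runs),
                 baseline = baseline, n_runs = n_runs),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d perturbed runs, %d baseline events\n",
              x$n_runs, nrow(x$baseline)))
  invisible(x)
}

#' Write agreement maps as matrix-shaped TSVs
#' @param report a `sensitivity_report`.
#' @param dir output directory; files `agreement_up.tsv` and
#'   `agreement_down.tsv` are written.
#' @param provenance optional `# ` comment lines.
#' @return paths of the written files.
#' @export
write_agreement_maps <- function(report, dir, provenance = NULL) {
  paths <- character(0)
  for (d in c("up", "down")) {
    a <- report$agreement[[d]]
    m <- reactivity_matrix(a, as.integer(rownames(a)), as.integer(colnames(a)))
    p <- file.path(dir, sprintf("agreement_%s.tsv", d))
    write_reactivity_matrix(m, p, provenance = provenance)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Compare two event tables from the same matrix
#'
#' Partitions events into those matched between the runs (`kept`), those only
#' in `a` (`lost`) and those only in `b` (`gained`), using the consensus
#' matching rule: same nucleotide, class and direction with tol-padded
#' interval overlap, matched one-to-one greedily by start distance.
#'
#' @param a,b [event_table]s.
#' @param tol length tolerance.
#' @return list with event tables `kept` (from `a`), `lost`, `gained`.
#' @export
compare_runs <- function(a, b, tol = 3L) {
  a <- validate_event_table(a); b <- validate_event_table(b)
  na <- nrow(a); nb <- nrow(b)
  used_b <- logical(nb)
  matched_a <- logical(na)
  if (na > 0L && nb > 0L) {
    cand <- do.call(rbind, lapply(seq_len(na), function(i) {
      hit <- which(b$nucleotide == a$nucleotide[i] & b$class == a$class[i] &
                     b$direction == a$direction[i] &
                     intervals_overlap(a$start_length[i], a$end_length[i],
                                       b$start_length, b$end_length, tol))
      if (length(hit) == 0L) return(NULL)
      data.frame(i = i, k = hit, dist = abs(b$start_length[hit] - a$start_length[i]))
    }))
    if (!is.null(cand) && nrow(cand) > 0L) {
      cand <- cand[order(cand$dist, cand$i, cand$k), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        if (matched_a[cand$i[r]] || used_b[cand$k[r]]) next
        matched_a[cand$i[r]] <- TRUE
        used_b[cand$k[r]] <- TRUE
      }
    }
  }
  list(kept = a[matched_a, , drop = FALSE],
       lost = a[!matched_a, , drop = FALSE],
       gained = b[!used_b, , drop = FALSE])
}
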