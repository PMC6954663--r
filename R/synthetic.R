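TRAJ_STATES <- c("unpaired", "paired", "helix_end", "footprint", "absent")

#' Construct a structure trajectory
#'
#' A trajectory records the ground-truth pairing state of every nucleotide at
#' every transcript length.  The underlying pairing states (`unpaired`,
#' `paired`, `helix_end`) are overlaid with the RNA polymerase footprint: the
#' last `footprint` positions of every transcript (default 14) are forced to
#' the `footprint` state, emulating protection from SHAPE modification inside
#' the polymerase; positions not yet transcribed are `absent`.
#'
#' @param states character matrix (lengths x positions) of underlying pairing
#'   states in `unpaired`/`paired`/`helix_end` (cells beyond the transcript
#'   may hold anything; they are overwritten).
#' @param lengths strictly increasing transcript lengths (rows).
#' @param positions strictly increasing nucleotide positions (columns).
#' @param footprint footprint width F in nt.
#' @return object of class `structure_trajectory` with fields `states`,
#'   `lengths`, `positions`, `footprint`, and `truth` (the ground-truth
#'   [event_table], see [truth_events()]).
#' @export
structure_trajectory <- function(states, lengths, positions = seq_len(ncol(states)),
                                 footprint = 14L) {
  states <- as.matrix(states)
  lengths <- as.integer(lengths)
  positions <- as.integer(positions)
  footprint <- as.integer(footprint)
  if (nrow(states) != length(lengths) || ncol(states) != length(positions))
    stop("states dimensions do not match lengths/positions")
  if (length(lengths) > 1L && any(diff(lengths) <= 0L))
    stop("lengths must be strictly increasing")
  if (length(positions) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  if (footprint < 0L) stop("footprint must be >= 0")
  bad <- !states %in% c("unpaired", "paired", "helix_end")
  present <- outer(lengths, positions, FUN = function(l, n) n <= l)
  if (any(bad & present))
    stop("underlying states must be unpaired/paired/helix_end")
  out <- states
  out[!present] <- "absent"
  in_fp <- outer(lengths, positions, FUN = function(l, n) n <= l & n > l - footprint)
  out[in_fp] <- "footprint"
  dimnames(out) <- list(as.character(lengths), as.character(positions))
  traj <- structure(list(states = out, lengths = lengths, positions = positions,
                         footprint = footprint, truth = NULL),
                    class = "structure_trajectory")
  traj$truth <- truth_events(traj)
  traj
}

#' Ground-truth events of a trajectory
#'
#' Enumerates state changes down each position's column and converts them to
#' expected swing events in the three transition categories: a
#' `footprint -> unpaired` change is an expected upswing (`footprint_exit`),
#' `unpaired -> paired/helix_end` an expected downswing (`pairing`), and
#' `paired/helix_end -> unpaired` an expected upswing (`unpairing`).
#' Transitions between footprint and paired-like states produce no event
#' (their reactivities are indistinguishable), nor do paired/helix_end
#' interchanges.  The returned table carries extra columns `category` and
#' `helix_end` (whether the paired-like side of the transition is a helix
#' terminus, which has a smaller reactivity change).
#'
#' @param traj a [structure_trajectory].
#' @return an [event_table] with `category` and `helix_end` columns; each
#'   truth event is a single-length swing at the transition length with
#'   magnitude +-1 (sign only).
#' @export
truth_events <- function(traj) {
  st <- traj$states
  lens <- traj$lengths
  pos <- traj$positions
  rows <- list()
  paired_like <- c("paired", "helix_end")
  for (j in seq_along(pos)) {
    col <- st[, j]
    def <- which(col != "absent")
    if (length(def) < 2L) next
    for (i in def[-1L]) {
      prev <- col[i - 1L]; cur <- col[i]
      if (prev == "absent" || prev == cur) next
      dir <- NULL; categ <- NULL; he <- FALSE
      if (prev == "footprint" && cur == "unpaired") {
        dir <- "up"; categ <- "footprint_exit"
      } else if (prev == "unpaired" && cur %in% paired_like) {
        dir <- "down"; categ <- "pairing"; he <- cur == "helix_end"
      } else if (prev %in% paired_like && cur == "unpaired") {
        dir <- "up"; categ <- "unpairing"; he <- prev == "helix_end"
      }
      if (is.null(dir)) next
      rows[[length(rows) + 1L]] <- data.frame(
        nucleotide = pos[j], direction = dir, length = lens[i],
        category = categ, helix_end = he, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(event_table(category = character(), helix_end = logical()))
  }
  df <- do.call(rbind, rows)
  sort_events(event_table(
    nucleotide = df$nucleotide, class = "swing", direction = df$direction,
    start_length = df$length, end_length = df$length,
    magnitude = ifelse(df$direction == "up", 1, -1),
    category = df$category, helix_end = df$helix_end))
}

#' Scenario-template trajectories
#'
#' Builds a [structure_trajectory] from one of the scenario templates:
#' \describe{
#'   \item{static_unpaired}{every transcribed position unpaired once it
#'     clears the footprint; the only truth events are footprint-exit
#'     upswings.}
#'   \item{static_paired}{everything paired; no truth events.}
#'   \item{hairpin_formation}{all positions unpaired until
#'     `pairing_length`, when the two stem arms pair; the terminal and
#'     loop-closing base pairs become `helix_end`, the loop stays unpaired.}
#'   \item{hairpin_rearrangement}{the hairpin forms as above, then at
#'     `rearrange_length` the loop positions pair as well (the hairpin
#'     rearranges into a longer helix), yielding late downswings at former
#'     loop positions.}
#'   \item{custom}{caller supplies the underlying `states` matrix.}
#' }
#' Defaults describe a 100-nt RNA transcribed from length 21 to 120 carrying
#' a 6-bp hairpin (stem arms 30-35 and 42-47, loop 36-41) that folds at
#' length 75 — a geometry in the size range of bacterial regulatory RNAs
#' where the folding event changes only a modest fraction of the transcript.
#'
#' @param scenario template name.
#' @param n_positions number of nucleotides.
#' @param lengths transcript lengths simulated (defaults to
#'   `21:(n_positions + 20)`).
#' @param footprint RNAP footprint width (nt).
#' @param stem1,stem2 integer position vectors of the two stem arms
#'   (same length, `stem1` 5' of the loop).
#' @param loop integer positions of the hairpin loop.
#' @param pairing_length transcript length at which the hairpin folds.
#' @param rearrange_length length at which the loop pairs
#'   (`hairpin_rearrangement` only).
#' @param states underlying state matrix for `scenario = "custom"`.
#' @return a [structure_trajectory] with attached ground truth.
#' @export
make_trajectory <- function(scenario = c("hairpin_formation",
                                         "hairpin_rearrangement",
                                         "static_unpaired", "static_paired",
                                         "custom"),
                            n_positions = 100L,
                            lengths = 21:(n_positions + 20L),
                            footprint = 14L,
                            stem1 = 30:35, loop = 36:41, stem2 = 42:47,
                            pairing_length = 75L, rearrange_length = 105L,
                            states = NULL) {
  scenario <- match.arg(scenario)
  lengths <- as.integer(lengths)
  positions <- seq_len(n_positions)
  if (scenario == "custom") {
    if (is.null(states)) stop("custom scenario requires a states matrix")
    return(structure_trajectory(states, lengths, seq_len(ncol(states)),
                                footprint))
  }
  st <- matrix("unpaired", nrow = length(lengths), ncol = n_positions)
  if (scenario == "static_paired") {
    st[] <- "paired"
  } else if (scenario %in% c("hairpin_formation", "hairpin_rearrangement")) {
    if (length(stem1) != length(stem2)) stop("stem arms must have equal length")
    stem <- c(stem1, stem2)
    helix_ends <- c(min(stem1), max(stem1), min(stem2), max(stem2))
    late <- lengths >= pairing_length
    st[late, stem] <- "paired"
    st[late, helix_ends] <- "helix_end"
    if (scenario == "hairpin_rearrangement") {
      very_late <- lengths >= rearrange_length
      st[very_late, loop] <- "paired"
      # the former loop-closing pair is now internal to the long helix
      st[very_late, c(max(stem1), min(stem2))] <- "paired"
    }
  }
  structure_trajectory(st, lengths, positions, footprint)
}

#' Ternary reactivity model parameters
#'
#' Per-state gamma sampling distributions for raw SHAPE reactivities:
#' unpaired nucleotides are highly reactive, paired ones nearly unreactive
#' and helix-end (terminal base pair) nucleotides intermediate; footprint
#' positions sample from the paired distribution.  Each simulated cell is the
#' average of `n_reps` independent draws.
#'
#' @param mean_unpaired,mean_paired,mean_helix_end state means (must satisfy
#'   unpaired > helix_end > paired).
#' @param shape gamma shape parameter shared by all states.
#' @param n_reps draws averaged per cell.
#' @param seed top-level integer seed.
#' @return a list of class `ternary_model_params`.
#' @export
ternary_model_params <- function(mean_unpaired = 1.5, mean_paired = 0.05,
                                 mean_helix_end = 0.4, shape = 1.0,
                                 n_reps = 1000L, seed = 1L) {
  if (!(mean_unpaired > mean_helix_end && mean_helix_end > mean_paired))
    stop("state means must satisfy unpaired > helix_end > paired")
  if (any(c(mean_paired, shape) <= 0)) stop("means and shape must be > 0")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  structure(list(mean_unpaired = mean_unpaired, mean_paired = mean_paired,
                 mean_helix_end = mean_helix_end, shape = shape,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "ternary_model_params")
}

#' Simulate a reactivity matrix from a trajectory
#'
#' For every transcribed cell, averages `n_reps` gamma draws whose mean is set
#' by the cell's pairing state (footprint cells draw from the paired
#' distribution), then renormalizes each transcript length (row) to a mean of
#' 1 over its defined cells, mimicking the rho reactivity measure.  Each cell
#' uses its own RNG substream derived from the top-level seed, so results do
#' not depend on evaluation order and are reproducible.
#'
#' @param traj a [structure_trajectory].
#' @param params a [ternary_model_params].
#' @return a [reactivity_matrix] with rows renormalized to mean 1.
#' @export
simulate_reactivities <- function(traj, params = ternary_model_params()) {
  st <- traj$states
  nr <- nrow(st); nc <- ncol(st)
  means <- c(unpaired = params$mean_unpaired, paired = params$mean_paired,
             helix_end = params$mean_helix_end, footprint = params$mean_paired)
  # per-cell substreams: one integer seed per cell, drawn from the top seed
  withr_seed <- params$seed %% .Machine$integer.max
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max - 1L, nr * nc,
                                  replace = TRUE), nr, nc)
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      s <- st[i, j]
      if (s == "absent") next
      set.seed(cell_seeds[i, j])
      mu <- means[[s]]
      draws <- stats::rgamma(params$n_reps, shape = params$shape,
                             rate = params$shape / mu)
      vals[i, j] <- mean(draws)
    }
  }
  for (i in seq_len(nr)) {
    def <- !is.na(vals[i, ])
    if (!any(def)) next
    mu_row <- mean(vals[i, def])
    if (mu_row == 0) {
      warning("all-zero row at length ", traj$lengths[i], "; rescale skipped")
      next
    }
    vals[i, def] <- vals[i, def] / mu_row
  }
  reactivity_matrix(vals, traj$lengths, traj$positions,
                    replicate_id = sprintf("sim_seed%d", params$seed))
}

#' Score detected events against ground truth
#'
#' Greedy one-to-one matching of detected to truth events sharing nucleotide
#' and direction with `|start difference| <= tol`, closest pairs first (ties
#' to the earlier truth event).  Recall is matched truth over total truth;
#' precision matched detected over total detected (`NaN` with a warning when
#' nothing was detected).  When the truth table carries `category` /
#' `helix_end` columns (see [truth_events()]), per-category and
#' helix-end/stacked recalls are reported too.
#'
#' @param detected an [event_table] (typically swings).
#' @param truth ground-truth [event_table].
#' @param tol start-length matching tolerance (nt).
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`,
#'   `matches` (data.frame of matched index pairs), `unmatched_truth`,
#'   `unmatched_detected`, `category_recall`, `helix_end_recall`,
#'   `stacked_recall`.
#' @export
benchmark_events <- function(detected, truth, tol = 3L) {
  detected <- validate_event_table(detected)
  truth <- validate_event_table(truth)
  nd <- nrow(detected); nt <- nrow(truth)
  cand <- NULL
  if (nd > 0L && nt > 0L) {
    cand <- do.call(rbind, lapply(seq_len(nd), function(d) {
      hit <- which(truth$nucleotide == detected$nucleotide[d] &
                     truth$direction == detected$direction[d] &
                     abs(truth$start_length - detected$start_length[d]) <= tol)
      if (length(hit) == 0L) return(NULL)
      data.frame(d = d, t = hit,
                 dist = abs(truth$start_length[hit] - detected$start_length[d]),
                 t_start = truth$start_length[hit])
    }))
  }
  matches <- data.frame(d = integer(), t = integer())
  if (!is.null(cand) && nrow(cand) > 0L) {
    cand <- cand[order(cand$dist, cand$t_start, cand$d), , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    for (r in seq_len(nrow(cand))) {
      d <- cand$d[r]; t <- cand$t[r]
      if (used_d[d] || used_t[t]) next
      used_d[d] <- TRUE; used_t[t] <- TRUE
      matches <- rbind(matches, data.frame(d = d, t = t))
    }
  }
  matched_t <- logical(nt); matched_t[matches$t] <- TRUE
  matched_d <- logical(nd); matched_d[matches$d] <- TRUE
  recall <- if (nt == 0L) NaN else sum(matched_t) / nt
  precision <- if (nd == 0L) { warning("no detected events; precision undefined"); NaN
  } else sum(matched_d) / nd
  out <- list(recall = recall, precision = precision,
              n_truth = nt, n_detected = nd, matches = matches,
              unmatched_truth = truth[!matched_t, , drop = FALSE],
              unmatched_detected = detected[!matched_d, , drop = FALSE])
  if (nt > 0L && !is.null(truth$category)) {
    out$category_recall <- tapply(matched_t, truth$category, mean)
  }
  if (nt > 0L && !is.null(truth$helix_end)) {
    pl <- truth$category %in% c("pairing", "unpairing")
    out$helix_end_recall <- if (any(pl & truth$helix_end))
      mean(matched_t[pl & truth$helix_end]) else NaN
    out$stacked_recall <- if (any(pl & !truth$helix_end))
      mean(matched_t[pl & !truth$helix_end]) else NaN
  }
  out
}
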