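lower_median <- function(v) {
  v <- sort(v)
  v[floor((length(v) + 1) / 2)]
}

intervals_overlap <- function(s1, e1, s2, e2, tol) {
  (s1 - tol) <= e2 & (s2 - tol) <= e1
}

#' Consensus events across replicates
#'
#' Retains events conserved across all replicates: events of the same
#' nucleotide, class and direction from different replicates are linked when
#' their length intervals, padded by `tol`, overlap; connected components of
#' this cross-replicate graph that contain events from every replicate
#' become consensus events.  A consensus event's interval is the lower median
#' of the member start and end lengths, its magnitude the mean of member
#' magnitudes, and `n_replicates_supporting` the number of replicates in the
#' component.  With a single replicate the operation is the identity.
#'
#' @param tables list of [event_table]s, one per replicate.
#' @param tol length tolerance (nt) used to pad intervals before the overlap
#'   test.
#' @return consensus [event_table].
#' @export
consensus_events <- function(tables, tol = 3L) {
  if (!is.list(tables) || inherits(tables, "data.frame")) tables <- list(tables)
  if (length(tables) == 0L) stop("need at least one replicate event table")
  if (tol < 0) stop("tol must be >= 0")
  n_rep <- length(tables)
  ev <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    t <- validate_event_table(tables[[r]])
    if (nrow(t) == 0L) return(NULL)
    cbind(as.data.frame(t)[EVENT_COLUMNS], replicate = r)
  }))
  if (is.null(ev) || nrow(ev) == 0L) return(event_table())
  n <- nrow(ev)
  # union-find over cross-replicate matches within (nucleotide, class, direction)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, k) { ri <- find(i); rk <- find(k); if (ri != rk) parent[rk] <<- ri }
  key <- paste(ev$nucleotide, ev$class, ev$direction)
  for (grp in split(seq_len(n), key)) {
    if (length(grp) < 2L) next
    for (a in seq_along(grp)[-length(grp)]) {
      for (b in (a + 1L):length(grp)) {
        i <- grp[a]; k <- grp[b]
        if (ev$replicate[i] == ev$replicate[k]) next
        if (intervals_overlap(ev$start_length[i], ev$end_length[i],
                              ev$start_length[k], ev$end_length[k], tol))
          unite(i, k)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  rows <- lapply(split(seq_len(n), comp), function(idx) {
    reps <- unique(ev$replicate[idx])
    if (length(reps) != n_rep) return(NULL)
    data.frame(nucleotide = ev$nucleotide[idx[1L]],
               class = ev$class[idx[1L]],
               direction = ev$direction[idx[1L]],
               start_length = lower_median(ev$start_length[idx]),
               end_length = lower_median(ev$end_length[idx]),
               magnitude = mean(ev$magnitude[idx]),
               n_replicates_supporting = length(reps),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(event_table())
  df <- do.call(rbind, rows)
  sort_events(event_table(
    nucleotide = df$nucleotide, class = df$class, direction = df$direction,
    start_length = df$start_length, end_length = df$end_length,
    magnitude = df$magnitude,
    n_replicates_supporting = df$n_replicates_supporting))
}

#' Group concurrent events
#'
#' Events at different nucleotides whose onsets coincide in transcript length
#' suggest a shared structural transition.  Builds an undirected graph with
#' edges between events of the same direction (any nucleotide or class) whose
#' start lengths differ by at most `max_start_gap`; connected components of
#' two or more events receive a shared `group_id`; singletons keep `NA`.
#'
#' @param t an [event_table].
#' @param max_start_gap maximum onset difference (nt) for an edge.
#' @return the table with `group_id` filled in.
#' @export
group_concurrent <- function(t, max_start_gap = 2L) {
  t <- validate_event_table(t)
  n <- nrow(t)
  if (n == 0L) return(t)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      if (t$direction[i] == t$direction[k] &&
          abs(t$start_length[i] - t$start_length[k]) <= max_start_gap) {
        ri <- find(i); rk <- find(k); if (ri != rk) parent[rk] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sizes <- table(comp)
  # stable ids: number components by earliest start, then nucleotide
  multi <- names(sizes)[sizes > 1L]
  ord <- order(vapply(multi, function(cc) min(t$start_length[comp == as.integer(cc)]), numeric(1)),
               vapply(multi, function(cc) min(t$nucleotide[comp == as.integer(cc)]), numeric(1)))
  ids <- stats::setNames(paste0("g", seq_along(multi)), multi[ord])
  t$group_id <- ifelse(as.character(comp) %in% multi, ids[as.character(comp)],
                       NA_character_)
  t
}

#' Mine lagged up-then-down swing pairs
#'
#' Finds, per nucleotide, upswings followed by a downswing after a lag of
#' `min_lag` to `max_lag` transcript lengths — the signature of a transiently
#' hyper-reactive state that then pairs off.  Each upswing is paired with its
#' nearest later downswing inside the lag window; when two upswings claim the
#' same downswing the nearer one wins (ties to the earlier upswing), so each
#' downswing is matched at most once.
#'
#' @param t an [event_table].
#' @param min_lag,max_lag inclusive lag window (nt); default `[8, 16]`.
#' @return data.frame with columns nucleotide, up_start, down_start, lag.
#' @export
find_lagged_pairs <- function(t, min_lag = 8L, max_lag = 16L) {
  t <- validate_event_table(t)
  sw <- t[t$class == "swing", , drop = FALSE]
  out <- data.frame(nucleotide = integer(), up_start = integer(),
                    down_start = integer(), lag = integer())
  if (nrow(sw) == 0L) return(out)
  cand <- list()
  for (nuc in unique(sw$nucleotide)) {
    ups <- sort(sw$start_length[sw$nucleotide == nuc & sw$direction == "up"])
    downs <- sort(sw$start_length[sw$nucleotide == nuc & sw$direction == "down"])
    for (u in ups) {
      lags <- downs - u
      ok <- which(lags >= min_lag & lags <= max_lag)
      if (length(ok) == 0L) next
      d <- downs[ok[which.min(lags[ok])]]  # nearest later downswing
      cand[[length(cand) + 1L]] <- data.frame(nucleotide = nuc, up_start = u,
                                              down_start = d, lag = d - u)
    }
  }
  if (length(cand) == 0L) return(out)
  cand <- do.call(rbind, cand)
  keep <- lapply(split(seq_len(nrow(cand)),
                       paste(cand$nucleotide, cand$down_start)), function(idx) {
    sub <- cand[idx, , drop = FALSE]
    sub[order(sub$lag, sub$up_start), , drop = FALSE][1L, , drop = FALSE]
  })
  res <- do.call(rbind, keep)
  res <- res[order(res$nucleotide, res$up_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write lagged pairs as TSV
#' @param pairs result of [find_lagged_pairs()].
#' @param path output path.
#' @param provenance optional `# ` comment lines.
#' @export
write_lagged_pairs <- function(pairs, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines("nucleotide\tup_start\tdown_start\tlag", con)
  if (nrow(pairs)) {
    writeLines(paste(pairs$nucleotide, pairs$up_start, pairs$down_start,
                     pairs$lag, sep = "\t"), con)
  }
  invisible(path)
}
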