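EVENT_COLUMNS <- c("nucleotide", "class", "direction", "start_length",
                   "end_length", "magnitude", "n_replicates_supporting",
                   "group_id")

#' Construct an event table
#'
#' An event table records detected structural transitions: one row per event
#' with the nucleotide position, event class (`swing` or `ramp`), direction
#' (`up` for a reactivity increase, `down` for a decrease), the inclusive
#' interval of transcript lengths it spans, its signed magnitude, the number
#' of replicates supporting it (after consensus), and an optional
#' concurrency-group label.
#'
#' @param nucleotide integer nucleotide positions (1-based).
#' @param class `"swing"` or `"ramp"`.
#' @param direction `"up"` or `"down"`.
#' @param start_length,end_length inclusive transcript-length interval (nt).
#' @param magnitude signed reactivity change (positive for `up`).
#' @param n_replicates_supporting integer or `NA`.
#' @param group_id character or `NA`.
#' @param ... extra columns carried through (e.g. benchmark categories).
#' @return a `data.frame` with class `event_table`.
#' @export
event_table <- function(nucleotide = integer(), class = character(),
                        direction = character(), start_length = integer(),
                        end_length = integer(), magnitude = numeric(),
                        n_replicates_supporting = NA_integer_,
                        group_id = NA_character_, ...) {
  n <- max(length(nucleotide), length(class), length(direction),
           length(start_length), length(end_length), length(magnitude))
  if (length(nucleotide) == 0L) n <- 0L
  t <- data.frame(nucleotide = rep_len(as.integer(nucleotide), n),
                  class = rep_len(as.character(class), n),
                  direction = rep_len(as.character(direction), n),
                  start_length = rep_len(as.integer(start_length), n),
                  end_length = rep_len(as.integer(end_length), n),
                  magnitude = rep_len(as.numeric(magnitude), n),
                  n_replicates_supporting =
                    rep_len(as.integer(n_replicates_supporting), n),
                  group_id = rep_len(as.character(group_id), n),
                  stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) t[[nm]] <- extra[[nm]]
  class(t) <- c("event_table", "data.frame")
  validate_event_table(t)
}

#' Validate an event table
#' @param t an [event_table] (or plain data.frame with the same columns).
#' @return `t` invisibly (as an `event_table`); stops on invariant violation.
#' @export
validate_event_table <- function(t) {
  miss <- setdiff(EVENT_COLUMNS, names(t))
  if (length(miss)) stop("event table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(t)) {
    if (!all(t$class %in% c("swing", "ramp")))
      stop("event class must be 'swing' or 'ramp'")
    if (!all(t$direction %in% c("up", "down")))
      stop("event direction must be 'up' or 'down'")
    if (any(t$start_length > t$end_length))
      stop("event with start_length > end_length")
    sgn_ok <- ifelse(t$direction == "up", t$magnitude >= 0, t$magnitude <= 0)
    if (any(!sgn_ok & !is.na(t$magnitude)))
      stop("event magnitude sign must match direction")
  }
  if (!inherits(t, "event_table")) class(t) <- c("event_table", "data.frame")
  invisible(t)
}

#' Canonical event ordering
#'
#' Deterministic row order used on disk: nucleotide ascending, start_length
#' ascending, then class, then direction with `up` before `down`.
#'
#' @param t an [event_table].
#' @return the table with rows reordered.
#' @export
sort_events <- function(t) {
  if (nrow(t) == 0L) return(t)
  ord <- order(t$nucleotide, t$start_length, t$class,
               match(t$direction, c("up", "down")))
  out <- t[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an event table as TSV
#'
#' Columns are written in the fixed order nucleotide, class, direction,
#' start_length, end_length, magnitude, n_replicates_supporting, group_id,
#' with rows in the canonical order of [sort_events()].
#'
#' @param t an [event_table].
#' @param path output path.
#' @param provenance optional character vector of `# ` comment lines.
#' @export
write_events <- function(t, path, provenance = NULL) {
  t <- validate_event_table(t)
  t <- sort_events(t)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(EVENT_COLUMNS, collapse = "\t"), con)
  if (nrow(t)) {
    fmt <- function(v) {
      if (is.numeric(v) && !is.integer(v))
        ifelse(is.na(v), "NA", format(v, digits = 17, trim = TRUE, scientific = FALSE))
      else ifelse(is.na(v), "NA", as.character(v))
    }
    cells <- vapply(EVENT_COLUMNS, function(cn) fmt(t[[cn]]),
                    character(nrow(t)))
    if (nrow(t) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path path to the TSV.
#' @return an [event_table].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  tab <- read_table_skip_comments(path, "\t")
  header <- as.character(tab[1L, ])
  if (!identical(header[seq_along(EVENT_COLUMNS)], EVENT_COLUMNS))
    stop("format error: unexpected event table header in ", path)
  body <- tab[-1L, , drop = FALSE]
  if (nrow(body) == 0L) return(event_table())
  num <- function(j) suppressWarnings(as.numeric(replace(body[[j]], body[[j]] == "NA", NA)))
  chr <- function(j) replace(as.character(body[[j]]), body[[j]] == "NA", NA)
  event_table(nucleotide = num(1L), class = chr(2L), direction = chr(3L),
              start_length = num(4L), end_length = num(5L),
              magnitude = num(6L), n_replicates_supporting = num(7L),
              group_id = chr(8L))
}
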