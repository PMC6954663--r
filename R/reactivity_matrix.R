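#' Construct a reactivity matrix
#'
#' A reactivity matrix holds rho-normalized SHAPE-Seq reactivities indexed by
#' transcript length (rows) and nucleotide position (columns).  A cell
#' (length, position) may only be defined when the position has been
#' transcribed, i.e. `position <= length`; all other cells are undefined and
#' stored as `NA`.  `NA` is distinct from a reactivity of 0, which is legal.
#'
#' @param values numeric matrix, rows = transcript lengths, columns =
#'   nucleotide positions; `NA` marks undefined cells.
#' @param lengths strictly increasing integer vector of transcript lengths (nt).
#' @param positions strictly increasing integer vector of 1-based nucleotide
#'   positions.
#' @param replicate_id optional label for the experimental replicate.
#' @return an object of class `reactivity_matrix` (a numeric matrix with
#'   dimnames and a `replicate_id` attribute).
#' @export
reactivity_matrix <- function(values, lengths, positions,
                              replicate_id = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !(nrow(values) == 0L || ncol(values) == 0L)) {
    stop("values must be numeric")
  }
  storage.mode(values) <- "double"
  if (nrow(values) != length(lengths) || ncol(values) != length(positions)) {
    stop("dimensions of values do not match lengths/positions")
  }
  lengths <- as.integer(lengths)
  positions <- as.integer(positions)
  # untranscribed cells are undefined no matter what the caller supplied
  if (length(lengths) && length(positions)) {
    undef <- outer(lengths, positions, FUN = function(l, n) n > l)
    values[undef] <- NA_real_
  }
  dimnames(values) <- list(as.character(lengths), as.character(positions))
  structure(values,
            replicate_id = as.character(replicate_id),
            class = c("reactivity_matrix", "matrix", "array"))
}

#' @export
print.reactivity_matrix <- function(x, ...) {
  cat(sprintf("<reactivity_matrix> %d lengths x %d positions (replicate %s)\n",
              nrow(x), ncol(x), attr(x, "replicate_id")))
  cat(sprintf("  defined cells: %d\n", sum(!is.na(x))))
  invisible(x)
}

#' Transcript lengths / nucleotide positions of a reactivity matrix
#' @param m a `reactivity_matrix`.
#' @return integer vector.
#' @export
rm_lengths <- function(m) as.integer(rownames(m))

#' @rdname rm_lengths
#' @export
rm_positions <- function(m) as.integer(colnames(m))

#' Validate a reactivity matrix
#'
#' Checks the class invariants: strictly increasing lengths and positions,
#' all defined values finite and non-negative, and no defined cell at an
#' untranscribed position (`position > length`).
#'
#' @param m object to validate.
#' @return `m`, invisibly; stops with an informative error on violation.
#' @export
validate_reactivity_matrix <- function(m) {
  lens <- rm_lengths(m)
  pos <- rm_positions(m)
  if (anyNA(lens) || (length(lens) > 1L && any(diff(lens) <= 0L)))
    stop("format error: transcript lengths must be strictly increasing integers")
  if (anyNA(pos) || (length(pos) > 1L && any(diff(pos) <= 0L)))
    stop("format error: nucleotide positions must be strictly increasing integers")
  vals <- unclass(m)
  bad <- which(!is.na(vals) & (!is.finite(vals) | vals < 0), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "value error: negative or non-finite reactivity at length %s, position %s",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  if (length(lens) && length(pos)) {
    undef <- outer(lens, pos, FUN = function(l, n) n > l)
    if (any(!is.na(vals) & undef))
      stop("value error: defined cell at untranscribed position (position > length)")
  }
  invisible(m)
}

read_table_skip_comments <- function(path, sep) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error: empty file: ", path)
  utils::read.table(text = lines, sep = sep, header = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' Read a reactivity matrix from TSV/CSV
#'
#' Expected layout: a header row `length,<pos1>,<pos2>,...` followed by one
#' row per transcript length.  Blank or `NA` cells are undefined; any cell at
#' an untranscribed position (`position > length`) is forced to undefined
#' regardless of file content.  Lines starting with `#` are provenance
#' comments and are skipped.
#'
#' @param path path of the file to read.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param replicate_id replicate label to attach; defaults to the file name.
#' @return a validated [reactivity_matrix].
#' @export
read_reactivity_matrix <- function(path, dialect = c("tsv", "csv"),
                                   replicate_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input error: no such file: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  tab <- read_table_skip_comments(path, sep)
  header <- as.character(tab[1L, ])
  if (tolower(header[1L]) != "length")
    stop("format error: first header field must be 'length', got '", header[1L], "'")
  pos <- suppressWarnings(as.integer(header[-1L]))
  if (anyNA(pos)) stop("format error: non-integer position in header")
  if (length(pos) > 1L && any(diff(pos) <= 0L))
    stop("format error: nucleotide positions must be strictly increasing")
  body <- tab[-1L, , drop = FALSE]
  lens <- suppressWarnings(as.integer(body[[1L]]))
  if (anyNA(lens)) stop("format error: non-integer transcript length in first column")
  if (length(lens) > 1L && any(diff(lens) <= 0L))
    stop("format error: transcript lengths must be strictly increasing")
  vals <- matrix(NA_real_, nrow = length(lens), ncol = length(pos))
  for (j in seq_along(pos)) {
    raw <- if (ncol(body) > j) as.character(body[[j + 1L]]) else
      rep(NA_character_, length(lens))
    raw[is.na(raw) | raw == "" | toupper(raw) == "NA"] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("value error: non-numeric value '%s' at length %d, position %d",
                   raw[bad[1L]], lens[bad[1L]], pos[j]))
    }
    neg <- which(!is.na(num) & num < 0 & pos[j] <= lens)
    if (length(neg) > 0L) {
      stop(sprintf("value error: negative reactivity %s at length %d, position %d",
                   num[neg[1L]], lens[neg[1L]], pos[j]))
    }
    vals[, j] <- num
  }
  if (is.null(replicate_id)) replicate_id <- basename(path)
  m <- reactivity_matrix(vals, lens, pos, replicate_id = replicate_id)
  validate_reactivity_matrix(m)
  m
}

#' Write a reactivity matrix to TSV/CSV
#'
#' Inverse of [read_reactivity_matrix()]: undefined cells are written as
#' `NA`, and `read_reactivity_matrix(write_reactivity_matrix(m))` returns a
#' matrix equal to `m`.
#'
#' @param m a [reactivity_matrix].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param provenance optional character vector written as leading `# ` comment
#'   lines.
#' @export
write_reactivity_matrix <- function(m, path, dialect = c("tsv", "csv"),
                                    provenance = NULL) {
  dialect <- match.arg(dialect)
  validate_reactivity_matrix(m)
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  writeLines(paste(c("length", colnames(m)), collapse = sep), con)
  fmt_cell <- function(v) ifelse(is.na(v), "NA", format(v, digits = 17, trim = TRUE,
                                                        scientific = FALSE))
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], fmt_cell(unclass(m)[i, ])),
                     collapse = sep), con)
  }
  invisible(path)
}
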