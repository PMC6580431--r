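#' Encounter history sets
#'
#' The fundamental observed input: a binary daily detection matrix
#' `y[i, t]` for individually marked animals at a staging site, with one
#' row per observed individual and one column per sampling occasion
#' (calendar day).  Rows with no detections are not allowed: an
#' individual enters the data by being seen at least once.
#'
#' @param y 0/1 matrix, individuals x occasions.
#' @param id character vector of individual identifiers (default
#'   `"id1"`, `"id2"`, ...).
#' @param occasions occasion labels: an integer vector (1..K) or a
#'   `Date` vector of strictly increasing calendar days.
#' @param meta optional named list of metadata (site, year, window, ...).
#' @return an object of class `encounter_histories` with elements `y`,
#'   `id`, `occasions`, `meta` and `n_dropped` (all-zero rows removed at
#'   construction, normally 0).
#' @export
encounter_histories <- function(y, id = NULL, occasions = NULL, meta = list()) {
  y <- as.matrix(y)
  if (!all(y %in% c(0L, 1L)))
    stop("encounter histories must be binary (0/1)")
  storage.mode(y) <- "integer"
  n <- nrow(y); K <- ncol(y)
  if (is.null(id)) id <- paste0("id", seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(id) != n) stop("`id` length must match rows of `y`")
  if (is.null(occasions)) occasions <- seq_len(K)
  if (length(occasions) != K)
    stop("`occasions` length must match columns of `y`")
  if (is.unsorted(as.numeric(occasions), strictly = TRUE))
    stop("occasion labels must be strictly increasing")
  keep <- rowSums(y) > 0L
  n_dropped <- sum(!keep)
  y <- y[keep, , drop = FALSE]
  id <- id[keep]
  rownames(y) <- id
  structure(list(y = y, id = id, occasions = occasions, meta = meta,
                 n_dropped = n_dropped),
            class = "encounter_histories")
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat(sprintf("Encounter histories: %d individuals x %d occasions\n",
              nrow(x$y), ncol(x$y)))
  if (inherits(x$occasions, "Date"))
    cat(sprintf("  occasions: %s to %s\n", min(x$occasions), max(x$occasions)))
  cat(sprintf("  detections: %d (%.2f per individual)\n", sum(x$y),
              if (nrow(x$y)) sum(x$y) / nrow(x$y) else 0))
  if (x$n_dropped > 0)
    cat(sprintf("  dropped (never detected in window): %d\n", x$n_dropped))
  invisible(x)
}

#' @export
dim.encounter_histories <- function(x) dim(x$y)

#' Read and write encounter histories
#'
#' Two on-disk formats are supported.  `"csv"` has a leading
#' `individual_id` column followed by one 0/1 column per occasion; if the
#' occasion column names parse as ISO dates (`"2015-05-10"`, possibly
#' prefixed by a letter as in `"X2015.05.10"` from `read.csv`) the
#' occasions become dates.  `"inp"` is the classic capture-history
#' dialect: one record per line, a 0/1 history string, a frequency, and a
#' terminating `";"`, e.g. `"01100 1 ;"`.  Only single-group, frequency-1
#' records are accepted; anything else is rejected with the offending
#' line number.
#'
#' @param path file path.
#' @param format `"csv"` or `"inp"`; default guesses from the extension.
#' @param x an [encounter_histories()] object.
#' @return `read_histories()` returns an [encounter_histories()];
#'   writers return `path` invisibly.
#' @export
read_histories <- function(path, format = c("auto", "csv", "inp")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.inp$", path, ignore.case = TRUE)) "inp" else "csv"
  if (format == "inp") return(read_inp(path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("history CSV needs an id column plus occasions")
  idcol <- 1L
  y <- as.matrix(df[, -idcol, drop = FALSE])
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad))
    stop("non-binary cells in ", path, " (first at data row ",
         ((bad[1] - 1) %% nrow(y)) + 1, ")")
  occ <- parse_occasion_labels(colnames(df)[-idcol])
  encounter_histories(y, id = df[[idcol]], occasions = occ)
}

parse_occasion_labels <- function(labels) {
  iso <- gsub("^[A-Za-z]", "", labels)
  iso <- gsub("[._]", "-", iso)
  d <- as.Date(iso, format = "%Y-%m-%d")
  if (!anyNA(d)) return(d)
  num <- suppressWarnings(as.numeric(gsub("^[A-Za-z]+", "", labels)))
  if (!anyNA(num)) return(as.integer(num))
  seq_along(labels)
}

#' @rdname read_histories
#' @export
write_histories <- function(x, path, format = c("auto", "csv", "inp")) {
  stopifnot(inherits(x, "encounter_histories"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.inp$", path, ignore.case = TRUE)) "inp" else "csv"
  if (format == "inp") {
    lines <- paste0(apply(x$y, 1L, paste, collapse = ""), " 1 ;")
    writeLines(lines, path)
    return(invisible(path))
  }
  df <- data.frame(individual_id = x$id, x$y, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("individual_id", as.character(x$occasions))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_inp <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^/\\*", lines)]
  histories <- character(0)
  for (i in seq_along(lines)) {
    ln <- sub(";\\s*$", "", lines[i])
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L || !grepl("^[01]+$", parts[1L]))
      stop("cannot parse .inp record at line ", i, ": ", lines[i])
    if (parts[2L] != "1")
      stop(".inp line ", i, ": only frequency-1 records are supported ",
           "(got frequency ", parts[2L], ")")
    histories <- c(histories, parts[1L])
  }
  if (!length(histories)) stop("no records in ", path)
  if (length(unique(nchar(histories))) != 1L)
    stop("ragged .inp records: histories differ in length")
  y <- do.call(rbind, lapply(strsplit(histories, ""), as.integer))
  encounter_histories(y)
}

#' Restrict encounter histories to a date window
#'
#' Keeps the daily occasions between `start` and `end` (inclusive on both
#' sides, so 10-30 May gives K = 21).  With dated occasions, the retained
#' occasion grid is the full daily sequence of the window; window days on
#' which no occasion existed become all-zero columns.  Individuals with
#' no detections left inside the window are dropped and counted in
#' `n_dropped`.
#'
#' @param data an [encounter_histories()] with dated (or integer)
#'   occasions.
#' @param start,end window bounds, `Date` or `"YYYY-MM-DD"` strings
#'   (integers for integer occasions).
#' @return a windowed [encounter_histories()].
#' @export
filter_window <- function(data, start, end) {
  stopifnot(inherits(data, "encounter_histories"))
  occ <- data$occasions
  if (inherits(occ, "Date") || is.character(start)) {
    start <- as.Date(start); end <- as.Date(end)
    if (!inherits(occ, "Date"))
      stop("occasions are not dated; cannot apply a date window")
    grid <- seq(start, end, by = "day")
  } else {
    grid <- seq(as.integer(start), as.integer(end))
  }
  if (length(grid) < 1L) stop("empty window")
  idx <- match(grid, occ)
  y <- matrix(0L, nrow(data$y), length(grid))
  y[, !is.na(idx)] <- data$y[, idx[!is.na(idx)], drop = FALSE]
  keep <- rowSums(y) > 0L
  if (!any(keep)) stop("no data in window ", start, " to ", end)
  out <- encounter_histories(y[keep, , drop = FALSE], id = data$id[keep],
                             occasions = grid, meta = data$meta)
  out$n_dropped <- sum(!keep)
  out$meta$window <- c(as.character(start), as.character(end))
  out
}
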