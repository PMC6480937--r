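#' Read an abundance table
#'
#' Parses a plain-text abundance table in either of two dialects:
#' \describe{
#'   \item{`two_column`}{one `label<TAB>count` pair per line (comma also
#'     accepted as a separator), optional header line;}
#'   \item{`bare`}{one count per line.}
#' }
#' With `dialect = "auto"` (default) the dialect is detected from the first
#' data line.  Every count must be >= 1 and integer-valued unless
#' `allow_real = TRUE`.  Malformed or invalid rows are fatal by default and
#' name their line number; with `skip_bad = TRUE` they are dropped and the
#' number skipped is reported via the `n_skipped` attribute and a message.
#'
#' @param path Path to a readable file.
#' @param dialect `"auto"`, `"two_column"`, or `"bare"`.
#' @param allow_real Accept non-integer (real) counts >= 1?
#' @param skip_bad Skip malformed rows instead of failing?
#' @return An [abundance_sample()] with labels preserved in file order.
#' @export
read_abundances <- function(path, dialect = c("auto", "two_column", "bare"),
                            allow_real = FALSE, skip_bad = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L) stop(sprintf("empty abundance table: '%s'", path))

  split_row <- function(s) strsplit(s, "[\t,]")[[1]]
  first_fields <- split_row(trimws(lines[lines_keep[1]]))
  if (dialect == "auto") {
    dialect <- if (length(first_fields) >= 2L) "two_column" else "bare"
  }
  # header: a two-column first row whose count field is not numeric
  start <- 1L
  if (dialect == "two_column" && length(first_fields) >= 2L &&
      is.na(suppressWarnings(as.numeric(first_fields[2])))) {
    start <- 2L
  } else if (dialect == "bare" &&
             is.na(suppressWarnings(as.numeric(first_fields[1])))) {
    start <- 2L
  }
  rows <- lines_keep[seq.int(start, length(lines_keep))]
  if (length(rows) == 0L) stop(sprintf("no data rows in '%s'", path))

  labels <- character(0); counts <- numeric(0); bad <- integer(0)
  for (ln in rows) {
    f <- split_row(trimws(lines[ln]))
    if (dialect == "two_column") {
      val <- if (length(f) >= 2L) suppressWarnings(as.numeric(f[2])) else NA_real_
      lab <- if (length(f) >= 1L) f[1] else NA_character_
    } else {
      val <- if (length(f) == 1L) suppressWarnings(as.numeric(f[1])) else NA_real_
      lab <- NA_character_
    }
    problem <- is.na(val) || !is.finite(val) || val < 1 ||
      (!allow_real && val != floor(val))
    if (problem) {
      if (skip_bad) { bad <- c(bad, ln); next }
      stop(sprintf(
        "invalid abundance on line %d of '%s': '%s' (counts must be %s >= 1)",
        ln, path, trimws(lines[ln]),
        if (allow_real) "numbers" else "integers"))
    }
    counts <- c(counts, val)
    labels <- c(labels, lab)
  }
  if (length(bad) > 0L) {
    message(sprintf("read_abundances: skipped %d malformed row(s) in '%s'",
                    length(bad), path))
  }
  if (length(counts) == 0L) stop(sprintf("no valid rows in '%s'", path))
  out <- abundance_sample(counts,
                          labels = if (dialect == "two_column") labels else NULL)
  attr(out, "n_skipped") <- length(bad)
  out
}

#' Write an abundance table
#'
#' Writes a sample or synthetic community as a two-column TSV
#' (`species<TAB>abundance`, with header), the package's native interchange
#' format.  A write followed by [read_abundances()] is lossless.
#'
#' @param sample An [abundance_sample()], numeric vector, or synthetic
#'   community.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_abundances <- function(sample, path) {
  sample <- as_abundance_sample(sample)
  labels <- sample$labels
  if (is.null(labels)) labels <- sprintf("sp%05d", seq_along(sample$values))
  utils::write.table(
    data.frame(species = labels, abundance = sample$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
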