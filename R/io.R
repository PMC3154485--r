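# Reading and writing release tables.
#
# Format: delimited text (tab, comma or whitespace), mandatory header with
# columns `time` and `released` (optional `sd`).  Lines starting with '#' are
# comments and may carry `time_unit=<minute|hour|day>` metadata, keeping the
# files self-describing.

#' Read a cumulative-release table
#'
#' @param path Path to a delimited text file with header columns `time`,
#'   `released` and optionally `sd`.  Comment lines start with `#`; a comment
#'   of the form `# time_unit=day` declares the time unit (default `hour`,
#'   with a warning when missing).
#' @return A [release_curve()].
#' @details Malformed headers, non-finite values, negative times and
#'   duplicated/non-increasing times each raise a distinct error naming the
#'   offending file line.
#' @export
read_release_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  meta <- lines[is_comment]
  unit_match <- regmatches(meta, regexpr("time_unit\\s*=\\s*(minute|hour|day)", meta))
  if (length(unit_match) > 0) {
    time_unit <- sub("time_unit\\s*=\\s*", "", unit_match[1])
  } else {
    warning("no time_unit metadata in ", basename(path), "; assuming hours")
    time_unit <- "hour"
  }
  body_idx <- which(!is_comment & !is_blank)
  if (length(body_idx) < 2L) stop("no data rows in ", path, call. = FALSE)
  header_line <- lines[body_idx[1]]
  sep <- if (grepl(",", header_line)) "," else ""
  tab <- tryCatch(
    utils::read.table(text = lines[body_idx], header = TRUE, sep = sep,
                      strip.white = TRUE),
    error = function(e) stop("could not parse table in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  names(tab) <- tolower(names(tab))
  if (!all(c("time", "released") %in% names(tab))) {
    stop("malformed header in ", path,
         ": need columns 'time' and 'released', found: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  data_lines <- body_idx[-1]          # file line numbers of the data rows
  bad <- which(!is.finite(tab$time) | !is.finite(tab$released))
  if (length(bad) > 0) {
    stop("non-finite values at line(s) ", paste(data_lines[bad], collapse = ", "),
         " of ", path, call. = FALSE)
  }
  if (any(tab$time < 0)) {
    bad <- which(tab$time < 0)
    stop("negative time at line(s) ", paste(data_lines[bad], collapse = ", "),
         " of ", path, call. = FALSE)
  }
  if (is.unsorted(tab$time, strictly = TRUE)) {
    bad <- which(diff(tab$time) <= 0) + 1L
    stop("times not strictly increasing at line(s) ",
         paste(data_lines[bad], collapse = ", "), " of ", path, call. = FALSE)
  }
  release_curve(tab$time, tab$released,
                sd = if ("sd" %in% names(tab)) tab$sd else NULL,
                time_unit = time_unit,
                label = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a cumulative-release table
#'
#' Serializes a [release_curve()] as tab-separated text with a
#' `# time_unit=...` metadata comment.  Values are written with 15
#' significant digits so a read/write round trip preserves them well beyond
#' 12 digits.
#'
#' @param curve A [release_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_release_table <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  d <- as.data.frame(curve)
  d[] <- lapply(d, function(col) formatC(col, digits = 15, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cumulative release table",
               paste0("# time_unit=", curve$time_unit)), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
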