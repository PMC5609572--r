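#' Read / write two-column scan files
#'
#' Depth-dose and lateral-profile scans are stored as two numeric columns
#' (position mm, dose a.u.) with optional `#` comment headers. The position
#' column must be strictly increasing; malformed rows are rejected with
#' their line number. Writing uses full double precision, so a write/read
#' round trip preserves values bit-exactly.
#'
#' @param path File path.
#' @param x Two-column matrix, or any curve accepted by the QA module
#'   (e.g. a `pristine_peak` or `sobp_curve`) when writing.
#' @param header Character vector of metadata lines to place in the header
#'   (written with a `#` prefix).
#' @return `read_scan` returns a two-column matrix with the parsed header
#'   lines in attribute `"header"`; `write_scan` returns `path` invisibly.
#' @export
read_scan <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("%s: empty scan file", path))
  is_hdr <- grepl("^\\s*#", lines)
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (!length(body_idx)) stop(sprintf("%s: no data rows", path))
  parsed <- lapply(strsplit(trimws(lines[body_idx]), "[,;[:space:]]+"),
                   function(f) suppressWarnings(as.numeric(f)))
  bad <- which(vapply(parsed, function(p) length(p) != 2L || anyNA(p), logical(1)))
  if (length(bad))
    stop(sprintf("%s: malformed row at line %d (expected two numeric columns)",
                 path, body_idx[bad[1]]))
  m <- do.call(rbind, parsed)
  colnames(m) <- c("position_mm", "dose")
  if (any(diff(m[, 1]) <= 0))
    stop(sprintf("%s: position column is not strictly increasing", path))
  attr(m, "header") <- sub("^\\s*#\\s?", "", lines[is_hdr])
  m
}

#' @rdname read_scan
#' @export
write_scan <- function(x, path, header = character(0)) {
  if (is.list(x) && !is.null(x$depth_grid)) {
    m <- cbind(x$depth_grid, x$dose)
  } else m <- as.matrix(x)
  if (ncol(m) != 2L) stop("scan data must have two columns")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("%.17g %.17g", m[, 1], m[, 2]), con)
  invisible(path)
}

#' Read a key-value run configuration
#'
#' One `key: value` pair per line, `#` comments allowed. All units are
#' fixed by the toolkit's conventions (mm, MeV, Gy); no unit autodetection.
#'
#' @param path File path.
#' @return Named list of character values (callers coerce as needed).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  body <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  kv <- regmatches(body, regexec("^([^:]+):\\s*(.*)$", body))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) stop(sprintf("config line %d is not 'key: value'", bad[1]))
  stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
}
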