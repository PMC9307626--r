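# Plain-text dialect for 1D complex NMR records: '#'-prefixed key: value
# header lines followed by CSV rows. Unrecognised '#' lines are comments.

.readHeaderCsv <- function(path, required) {
  lines <- readLines(path)
  isHead <- startsWith(trimws(lines), "#")
  header <- list()
  for (ln in lines[isHead]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) header[[m[2]]] <- trimws(m[3])
  }
  missing <- setdiff(required, names(header))
  if (length(missing))
    stop("format error in '", path, "': missing header key(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  body <- which(!isHead & nzchar(trimws(lines)))
  if (!length(body)) stop("format error in '", path, "': no data rows",
                          call. = FALSE)
  first <- body[1]
  cols <- strsplit(trimws(lines[first]), ",")[[1]]
  rows <- lines[body[-1]]
  parts <- strsplit(rows, ",")
  bad <- which(lengths(parts) != length(cols))
  if (length(bad))
    stop("format error in '", path, "' at line ", body[-1][bad[1]],
         ": expected ", length(cols), " fields", call. = FALSE)
  num <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = length(cols), byrow = TRUE)
  nas <- which(rowSums(is.na(num)) > 0)
  if (length(nas))
    stop("format error in '", path, "' at line ", body[-1][nas[1]],
         ": non-numeric value", call. = FALSE)
  colnames(num) <- cols
  list(header = header, data = num)
}

#' Read and write FID files
#'
#' The on-disk dialect is a `#`-prefixed `key: value` header (`dwell`,
#' `sfo`, `carrier`, `nucleus`, `n_scans`) followed by CSV rows
#' `index,real,imag`. Additional `#` comment lines are ignored.
#' `writeFid()` followed by `readFid()` is the identity on values and
#' metadata.
#'
#' @param path file path.
#' @param fid a [Fid-class].
#' @return `readFid()` returns a [Fid-class]; `writeFid()` returns `path`
#'   invisibly.
#' @examples
#' truth <- groundTruthSpectrum(foldedFraction = 0.5)
#' f <- simulateFid(truth, seed = 1)
#' p <- tempfile(fileext = ".csv")
#' writeFid(f, p)
#' identical(readFid(p)@points, f@points)
#' @export
readFid <- function(path) {
  parsed <- .readHeaderCsv(path, c("dwell", "sfo", "carrier", "nucleus",
                                   "n_scans"))
  h <- parsed$header
  d <- parsed$data
  new("Fid", points = complex(real = d[, "real"], imaginary = d[, "imag"]),
      dwell = as.numeric(h$dwell), sfo = as.numeric(h$sfo),
      carrier = as.numeric(h$carrier), nucleus = h$nucleus,
      nScans = as.integer(h$n_scans))
}

#' @rdname readFid
#' @export
writeFid <- function(fid, path) {
  stopifnot(is(fid, "Fid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dwell: %.17g", fid@dwell),
               sprintf("# sfo: %.17g", fid@sfo),
               sprintf("# carrier: %.17g", fid@carrier),
               sprintf("# nucleus: %s", fid@nucleus),
               sprintf("# n_scans: %d", fid@nScans),
               "index,real,imag",
               sprintf("%d,%.17g,%.17g", seq_along(fid@points) - 1L,
                       Re(fid@points), Im(fid@points))), con)
  invisible(path)
}

#' Read and write 1D spectrum files
#'
#' Same dialect as [readFid()] with header keys `sfo` and `noise_sd`
#' (`noise_sd: NA` allowed) and CSV rows `ppm,real,imag`.
#'
#' @param path file path.
#' @param spec a [Spectrum1D-class].
#' @return `readSpectrum()` returns a [Spectrum1D-class]; `writeSpectrum()`
#'   returns `path` invisibly.
#' @export
readSpectrum <- function(path) {
  parsed <- .readHeaderCsv(path, "sfo")
  h <- parsed$header
  d <- parsed$data
  ns <- if (is.null(h$noise_sd)) NA_real_ else
    suppressWarnings(as.numeric(h$noise_sd))
  new("Spectrum1D",
      values = complex(real = d[, "real"], imaginary = d[, "imag"]),
      axis = d[, "ppm"], sfo = as.numeric(h$sfo), noiseSd = ns)
}

#' @rdname readSpectrum
#' @export
writeSpectrum <- function(spec, path) {
  stopifnot(is(spec, "Spectrum1D"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sfo: %.17g", spec@sfo),
               sprintf("# noise_sd: %.17g", spec@noiseSd),
               "ppm,real,imag",
               sprintf("%.17g,%.17g,%.17g", spec@axis, Re(spec@values),
                       Im(spec@values))), con)
  invisible(path)
}
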