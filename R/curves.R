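#' Scattering curve objects
#'
#' A `saxs_curve` holds a momentum-transfer grid q (1/A, strictly
#' increasing), intensities I(q) in arbitrary units and, optionally,
#' per-point errors sigma(q) (> 0). Experimental and theoretical curves use
#' the same container; q = 4 pi sin(theta) / lambda with theta half the
#' scattering angle.
#'
#' @param q numeric, strictly increasing, non-negative (1/A).
#' @param I numeric intensities, finite.
#' @param sigma optional numeric errors, all > 0.
#' @return object of class `saxs_curve`.
#' @export
saxs_curve <- function(q, I, sigma = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I))
    stop("q and I must have the same length")
  if (any(q < 0)) stop("q must be non-negative")
  if (is.unsorted(q, strictly = TRUE))
    stop("q must be strictly increasing")
  if (!all(is.finite(I))) stop("intensities must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("sigma must match q in length")
    if (!all(is.finite(sigma)) || any(sigma <= 0))
      stop("all sigma must be finite and > 0")
  }
  structure(list(q = q, I = I, sigma = sigma), class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("saxs_curve: %d points, q in [%g, %g] 1/A%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with errors"))
  invisible(x)
}

#' @export
length.saxs_curve <- function(x) length(x$q)

#' @export
as.data.frame.saxs_curve <- function(x, ...) {
  d <- data.frame(q = x$q, I = x$I)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' Write a scattering curve as 3-column ASCII
#'
#' The de-facto SAXS `.dat` dialect: whitespace-delimited columns q, I,
#' sigma (sigma column omitted when absent), '#' comment header. Values are
#' printed with 17 significant digits so a read/write round trip is exact
#' at double precision.
#'
#' @param curve a [saxs_curve].
#' @param path output path.
#' @param header optional character vector of comment lines (without '#').
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, header = NULL) {
  stopifnot(inherits(curve, "saxs_curve"))
  lines <- character(0)
  if (!is.null(header)) lines <- paste("#", header)
  fmt <- function(v) formatC(v, digits = 17, format = "g", width = -1)
  body <- if (is.null(curve$sigma))
    paste(fmt(curve$q), fmt(curve$I))
  else
    paste(fmt(curve$q), fmt(curve$I), fmt(curve$sigma))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a scattering curve from 3-column ASCII
#'
#' Skips '#'-prefixed comment lines and blank lines; accepts two columns
#' (q, I) or three (q, I, sigma). Non-monotone q or non-positive sigma is a
#' format error.
#'
#' @param path input path.
#' @return a [saxs_curve].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) == 0L) stop("no data lines in ", path)
  fields <- strsplit(ln, "[ \t,]+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !(ncol %in% c(2L, 3L)))
    stop("malformed curve file: expected 2 or 3 numeric columns")
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) stop("non-numeric value in curve file ", path)
  m <- matrix(vals, ncol = ncol, byrow = TRUE)
  saxs_curve(m[, 1], m[, 2], if (ncol == 3L) m[, 3] else NULL)
}
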