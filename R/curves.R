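#' Construct a scattering curve
#'
#' A scattering curve is a tibble with columns `q` (scattering-vector
#' magnitude, 1/Angstrom, strictly increasing), `I` (intensity, arbitrary
#' units) and optionally `sigma` (1-sigma errors, required positive). Both
#' theoretical and experimental curves use this container.
#'
#' @param q numeric vector of scattering-vector magnitudes (1/Angstrom),
#'   non-negative and strictly increasing.
#' @param I numeric vector of intensities, same length as `q`.
#' @param sigma optional numeric vector of 1-sigma errors, same length,
#'   strictly positive.
#' @param label short text label carried as an attribute.
#' @return a tibble of class `sans_curve`.
#' @export
sans_curve <- function(q, I, sigma = NULL, label = "") {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) < 2L) stop("a scattering curve needs at least 2 points", call. = FALSE)
  if (length(I) != length(q)) stop("q and I lengths differ", call. = FALSE)
  if (anyNA(q) || anyNA(I) || any(!is.finite(q)) || any(!is.finite(I)))
    stop("q and I must be finite", call. = FALSE)
  if (any(q < 0)) stop("q must be non-negative", call. = FALSE)
  if (any(diff(q) <= 0)) stop("q must be strictly increasing", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length differs from q", call. = FALSE)
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be finite and > 0", call. = FALSE)
    out <- tibble::tibble(q = q, I = I, sigma = sigma)
  } else {
    out <- tibble::tibble(q = q, I = I)
  }
  attr(out, "label") <- as.character(label)[1]
  class(out) <- c("sans_curve", class(out))
  out
}

#' @export
print.sans_curve <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<sans_curve> %s: %d points, q in [%g, %g] 1/A%s\n",
              if (nzchar(lab)) lab else "(unlabelled)", nrow(x),
              min(x$q), max(x$q),
              if ("sigma" %in% names(x)) ", with errors" else ""))
  NextMethod()
}

curve_label <- function(curve) {
  lab <- attr(curve, "label")
  if (is.null(lab)) "" else lab
}

has_sigma <- function(curve) "sigma" %in% names(curve)

#' Read a 3-column ASCII scattering curve
#'
#' Reads the common small-angle scattering `.dat` dialect: whitespace-delimited
#' numeric columns `q I [sigma ...]`, `#`-prefixed comment lines ignored.
#' Columns beyond the third are ignored with a message. Two-column files yield
#' a curve without errors.
#'
#' @param path file path.
#' @param label label for the curve; defaults to the file name.
#' @return a [sans_curve()].
#' @export
read_sans_curve <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("cannot read curve file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L)
    stop("ragged rows in ", path, call. = FALSE)
  ncols <- ncols[1]
  if (ncols < 2L) stop("need at least 2 numeric columns in ", path, call. = FALSE)
  if (ncols > 3L)
    message("note: ", path, " has ", ncols, " columns; columns beyond the third ignored")
  m <- matrix(as.numeric(unlist(fields)), nrow = length(fields), byrow = TRUE)
  if (anyNA(m[, 1:min(3L, ncols)]))
    stop("non-numeric values in ", path, call. = FALSE)
  q <- m[, 1]; I <- m[, 2]
  if (any(diff(q) <= 0)) stop("q not strictly increasing in ", path, call. = FALSE)
  sigma <- if (ncols >= 3L) m[, 3] else NULL
  if (!is.null(sigma) && any(sigma <= 0))
    stop("non-positive sigma in ", path, call. = FALSE)
  sans_curve(q, I, sigma, label = label)
}

#' Write a scattering curve as 3-column ASCII
#'
#' Writes `# q[1/A] I sigma` (or the 2-column variant) followed by one row per
#' point at 15 significant digits, so a write/read round trip preserves values.
#'
#' @param curve a [sans_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sans_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sans_curve"))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (has_sigma(curve)) {
    header <- "# q[1/A] I sigma"
    rows <- paste(fmt(curve$q), fmt(curve$I), fmt(curve$sigma))
  } else {
    header <- "# q[1/A] I"
    rows <- paste(fmt(curve$q), fmt(curve$I))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Plot one or more scattering curves
#'
#' @param ... `sans_curve` objects (named arguments become legend labels).
#' @param log_I plot intensity on a log scale (default TRUE).
#' @return a ggplot object.
#' @export
plot_curves <- function(..., log_I = TRUE) {
  curves <- list(...)
  nms <- names(curves)
  if (is.null(nms)) nms <- rep("", length(curves))
  dat <- purrr::imap_dfr(curves, function(cv, i) {
    lab <- if (nzchar(nms[[i]])) nms[[i]] else curve_label(cv)
    if (!nzchar(lab)) lab <- paste0("curve ", i)
    tibble::tibble(q = cv$q, I = cv$I, curve = lab)
  })
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$q, y = .data$I, colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q ~ ("Å"^-1)), y = "I(q)", colour = NULL)
  if (log_I) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.sans_curve <- function(object, ...) plot_curves(object, ...)
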