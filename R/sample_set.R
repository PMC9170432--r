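#' Weighted intensity sample set
#'
#' The object the mixture model is fitted to: intensity values with
#' nonnegative multiplicities. Raw pixel vectors have unit weights; a binned
#' histogram enters with bin centers as values and bin counts as weights, so
#' fitting a histogram is exact weighted maximum likelihood rather than an
#' approximation by resampling.
#'
#' @param values numeric vector of intensity values.
#' @param weights nonnegative numeric multiplicities, recycled if length 1.
#'   Defaults to 1 per value.
#' @return An object of class \code{sample_set}: a list with elements
#'   \code{values}, \code{weights} and \code{M} (total effective sample count,
#'   the sum of the weights).
#' @examples
#' s <- sample_set(c(1, 2, 3), weights = c(2, 1, 1))
#' s$M  # 4
#' @export
sample_set <- function(values, weights = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L || !all(is.finite(values)))
    abort_invalid_input("'values' must be a nonempty vector of finite numbers")
  if (is.null(weights)) weights <- rep(1, length(values))
  weights <- as.numeric(weights)
  if (length(weights) == 1L) weights <- rep(weights, length(values))
  if (length(weights) != length(values))
    abort_invalid_input("'weights' must match 'values' in length")
  if (any(!is.finite(weights)) || any(weights < 0))
    abort_invalid_input("'weights' must be finite and nonnegative")
  M <- sum(weights)
  if (M <= 0) abort_invalid_input("total weight must be positive")
  structure(list(values = values, weights = weights, M = M),
            class = "sample_set")
}

#' Coerce images, vectors or histograms to a sample set
#'
#' @param x a numeric vector, matrix/array (non-finite pixels dropped), an
#'   \code{intensity_histogram}, or an existing \code{sample_set}.
#' @param ... unused.
#' @return A \code{sample_set}.
#' @export
as_sample_set <- function(x, ...) UseMethod("as_sample_set")

#' @export
as_sample_set.sample_set <- function(x, ...) x

#' @export
as_sample_set.intensity_histogram <- function(x, ...) {
  keep <- x$counts > 0
  sample_set(x$mids[keep], weights = x$counts[keep])
}

#' @export
as_sample_set.default <- function(x, ...) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) abort_invalid_input("no finite values to form a sample set")
  sample_set(v)
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d distinct values, effective M = %g, range [%g, %g]\n",
              length(x$values), x$M, min(x$values), max(x$values)))
  invisible(x)
}

#' Bin image intensities into a histogram
#'
#' Bins are half-open \code{[lo, hi)} except the last, which is closed, so a
#' pixel equal to the upper range limit lands in the last bin. Non-finite
#' pixels are ignored; the counts always sum to the number of finite pixels.
#'
#' @param image numeric vector, matrix or 3-D array of intensities.
#' @param n_bins number of bins (>= 1). Default 256, the natural choice for
#'   8-bit-scaled MRI intensities.
#' @param range optional numeric \code{c(lo, hi)} with \code{lo < hi}; default
#'   is the range of the finite pixel values.
#' @return An object of class \code{intensity_histogram}: list with
#'   \code{bin_edges} (length \code{n_bins + 1}), \code{counts},
#'   \code{mids} (bin centers) and \code{total}.
#' @examples
#' h <- build_histogram(matrix(0:8, 3, 3), n_bins = 3, range = c(0, 9))
#' h$counts  # 3 3 3
#' @export
build_histogram <- function(image, n_bins = 256L, range = NULL) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) == 0L)
    abort_invalid_input("image has no finite pixels to histogram")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    abort_invalid_input("'n_bins' must be a positive integer")
  if (is.null(range)) range <- c(min(v), max(v))
  if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2]) {
    # degenerate case: constant image with no explicit range
    if (is.null(range) || range[1] == range[2]) {
      range <- c(range[1] - 0.5, range[2] + 0.5)
    } else {
      abort_invalid_input("'range' must be c(lo, hi) with lo < hi")
    }
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  inside <- v >= range[1] & v <= range[2]
  idx <- findInterval(v[inside], edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges,
                 counts = as.integer(counts),
                 mids = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                 total = sum(counts)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins on [%g, %g], %d pixels\n",
              length(x$counts), x$bin_edges[1], tail(x$bin_edges, 1), x$total))
  invisible(x)
}

#' Write / read a histogram as a two-column CSV (bin_center, count)
#'
#' @param h an \code{intensity_histogram}.
#' @param path file path.
#' @return \code{write_histogram_csv} returns \code{path} invisibly;
#'   \code{read_histogram_csv} returns a \code{sample_set} built from the
#'   stored centers and counts (bin edges are not recoverable from centers
#'   alone, so the round trip is through the fitting substrate, not the
#'   histogram object).
#' @export
write_histogram_csv <- function(h, path) {
  stopifnot(inherits(h, "intensity_histogram"))
  write.csv(data.frame(bin_center = h$mids, count = h$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  if (!file.exists(path)) abort_io(paste0("no such file: ", path))
  d <- read.csv(path)
  if (!all(c("bin_center", "count") %in% names(d)))
    abort_io("histogram CSV must have columns bin_center, count")
  keep <- d$count > 0
  sample_set(d$bin_center[keep], weights = d$count[keep])
}

# Otsu threshold from the package's own histogram: maximizes between-class
# variance over bin-edge thresholds.
otsu_threshold <- function(image, n_bins = 256L) {
  h <- build_histogram(image, n_bins = n_bins)
  p <- h$counts / h$total
  omega <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mu_t <- tail(mu, 1)
  denom <- omega * (1 - omega)
  sb2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(head(sb2, -1L))
  h$bin_edges[k + 1L]
}
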