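#' Plot a fitted mixture over the intensity histogram
#'
#' @param x a \code{gmm_fit}.
#' @param n_bins histogram bins for display.
#' @param ... passed to \code{hist}.
#' @return \code{x}, invisibly.
#' @export
plot.gmm_fit <- function(x, n_bins = 60, ...) {
  s <- x$samples
  # expand weighted values just for display binning
  br <- seq(min(s$values), max(s$values), length.out = n_bins + 1)
  h <- build_histogram(rep(s$values, times = pmax(round(s$weights), 1)),
                       n_bins = n_bins)
  dens <- h$counts / sum(h$counts) / diff(h$bin_edges[1:2])
  plot(h$mids, dens, type = "h", col = "gray70", lwd = 3,
       xlab = "intensity", ylab = "density",
       main = sprintf("GMM fit, L = %d", x$params$L), ...)
  xx <- seq(min(br), max(br), length.out = 400)
  lines(xx, mixture_density(xx, x$params), lwd = 2)
  for (l in seq_len(x$params$L))
    lines(xx, x$params$pi[l] *
            gaussian_pdf(xx, x$params$mu[l], x$params$sigma2[l]), lty = 2)
  invisible(x)
}

#' Display an image with the segmentation contour overlaid
#'
#' @param x a \code{segmentation_result}.
#' @param image optional background image (matrix); defaults to the mask.
#' @param ... passed to \code{image}.
#' @return \code{x}, invisibly.
#' @export
plot.segmentation_result <- function(x, image = NULL, ...) {
  bg <- if (is.null(image)) x$mask else image
  if (length(dim(bg)) == 3L) bg <- bg[, , 1]
  image(t(bg[nrow(bg):1, ]), col = gray(seq(0, 1, length.out = 128)),
        axes = FALSE, ...)
  m <- x$mask
  if (length(dim(m)) == 3L) m <- m[, , 1]
  contour(t(m[nrow(m):1, ]), levels = 0.5, add = TRUE, drawlabels = FALSE,
          col = "red", lwd = 2)
  invisible(x)
}

#' @export
plot.phantom_sample <- function(x, ...) {
  image(t(x$image[nrow(x$image):1, ]),
        col = gray(seq(0, 1, length.out = 128)), axes = FALSE, ...)
  contour(t(x$truth_mask[nrow(x$truth_mask):1, ]), levels = 0.5, add = TRUE,
          drawlabels = FALSE, col = "red", lwd = 2)
  invisible(x)
}
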