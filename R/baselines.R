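#' Gradient stopping function
#'
#' The classical edge-based stop term the posterior speed field replaces:
#' \eqn{g(x) = 1 / (1 + |\nabla G_\sigma * I|^2)}. It is 1 in flat regions
#' and approaches 0 at strong edges.
#'
#' @param image numeric matrix.
#' @param smoothing_sigma standard deviation (pixels) of the Gaussian
#'   presmoothing.
#' @param rescale if TRUE (default) the smoothed gradient magnitude is scaled
#'   to unit maximum first, so g's dynamic range is comparable across images
#'   with different intensity scales.
#' @return A \code{speed_field} with values in (0, 1].
#' @export
gradient_stopping_function <- function(image, smoothing_sigma = 1.5,
                                       rescale = TRUE) {
  if (length(image) == 0L) abort_invalid_input("empty image")
  if (!is.finite(smoothing_sigma) || smoothing_sigma <= 0)
    abort_invalid_param("'smoothing_sigma' must be positive")
  sm <- gaussian_blur(image, smoothing_sigma)
  gm <- grad_mag_central(sm)
  if (rescale && max(gm) > 0) gm <- gm / max(gm) * 4
  new_speed_field(1 / (1 + gm^2))
}

#' Geodesic active contour (geometric deformation baseline)
#'
#' Classical edge-driven geometric deformable model: the contour is advected
#' by a balloon force and curvature, both modulated by the gradient stopping
#' function g, plus the edge-attraction term \eqn{\nabla g \cdot \nabla\phi}:
#' \deqn{\partial_t\phi = g\,(-c\,|\nabla\phi|_{upwind} +
#'   \kappa |\nabla\phi|) + \nabla g\cdot\nabla\phi,}
#' with \code{c > 0} expanding the region (phi < 0 inside). With \code{g = 1}
#' this is pure balloon growth; near strong edges g vanishes and the contour
#' stops.
#'
#' @param image numeric matrix.
#' @param init a \code{level_set_state}; default Otsu-box initialization.
#' @param config a \code{\link{seg_config}}; \code{curvature_weight} plays
#'   the usual smoothing role.
#' @param balloon constant balloon speed c (positive = expand).
#' @param smoothing_sigma passed to
#'   \code{\link{gradient_stopping_function}}.
#' @param g optional precomputed stopping \code{speed_field}, overriding the
#'   one derived from the image.
#' @return A \code{segmentation_result}.
#' @export
geodesic_active_contour_segment <- function(image, init = NULL,
                                            config = seg_config(),
                                            balloon = 1,
                                            smoothing_sigma = 1.5,
                                            g = NULL) {
  if (is.null(init)) init <- initialize_contour(image, config)
  gf <- if (is.null(g)) gradient_stopping_function(image, smoothing_sigma) else g
  gv <- if (inherits(gf, "speed_field")) gf$values else gf
  if (!identical(dim(gv), dim(image)))
    abort_invalid_input("stopping function and image shapes differ")
  if (any(!is.finite(gv))) abort_invalid_input("stopping function must be finite")
  gx <- diff_xc(gv); gy <- diff_yc(gv)
  phi <- init$phi
  nu <- config$curvature_weight
  n_px <- length(phi)
  dt <- min(config$dt, 0.45 / max(abs(balloon) * max(gv), 1e-9))
  converged <- FALSE
  it <- 0L
  checkpoint_mask <- phi < 0
  for (it in seq_len(config$max_iter)) {
    band <- abs(phi) <= init$band_width
    uw <- upwind_grad(phi)
    # balloon advection, upwinded by the sign of c
    adv <- if (balloon >= 0) balloon * uw$plus else balloon * uw$minus
    dphi <- gv * (-adv + nu * curvature_2d(phi) * grad_mag_central(phi))
    # edge attraction: upwind advection by the vector field grad g
    dphi <- dphi +
      pmax(gx, 0) * diff_xm(phi) + pmin(gx, 0) * diff_xp(phi) +
      pmax(gy, 0) * diff_ym(phi) + pmin(gy, 0) * diff_yp(phi)
    phi[band] <- phi[band] + dt * dphi[band]
    if (it %% config$reinit_every == 0L) {
      phi <- signed_distance(phi < 0)
      changed <- sum((phi < 0) != checkpoint_mask)
      checkpoint_mask <- phi < 0
      if (changed / (n_px * config$reinit_every) < config$convergence_frac) {
        converged <- TRUE
        break
      }
    }
  }
  phi <- signed_distance(phi < 0)
  structure(list(mask = (phi < 0) * 1L, phi = phi, n_iter = it,
                 converged = converged, gmm = NULL, config = config),
            class = "segmentation_result")
}

#' Closed snake (control-point polygon) state
#'
#' @param control_points n x 2 matrix of (row, col) coordinates of a closed
#'   polygon, at least 8 points.
#' @param elasticity,rigidity,step nonnegative snake coefficients: tension
#'   (first-derivative penalty), bending (second-derivative penalty) and the
#'   gradient-descent step size.
#' @return An object of class \code{snake_state}.
#' @export
snake_state <- function(control_points, elasticity = 0.05, rigidity = 0.1,
                        step = 1) {
  control_points <- as.matrix(control_points)
  if (ncol(control_points) != 2L || nrow(control_points) < 8L)
    abort_invalid_input("snake needs >= 8 control points as an n x 2 matrix")
  if (elasticity < 0 || rigidity < 0 || step <= 0)
    abort_invalid_param("snake coefficients must be nonnegative, step > 0")
  structure(list(control_points = control_points, elasticity = elasticity,
                 rigidity = rigidity, step = step),
            class = "snake_state")
}

#' Circle initialization helper for the snake baseline
#'
#' @param center (row, col) center.
#' @param radius circle radius in pixels.
#' @param n number of control points.
#' @return A \code{snake_state}.
#' @export
snake_circle <- function(center, radius, n = 64L, ...) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  snake_state(cbind(center[1] + radius * cos(th),
                    center[2] + radius * sin(th)), ...)
}

# equal-arc-length resampling of a closed polygon
resample_polygon <- function(p, n = nrow(p)) {
  q <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(q)^2))
  s <- c(0, cumsum(seg))
  total <- tail(s, 1)
  at <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  idx <- findInterval(at, s, rightmost.closed = TRUE)
  frac <- (at - s[idx]) / pmax(seg[idx], 1e-12)
  q[idx, ] + frac * (q[idx + 1L, ] - q[idx, ])
}

# area via the shoelace formula (absolute value)
polygon_area <- function(p) {
  q <- rbind(p, p[1L, ])
  abs(sum(q[-nrow(q), 1] * q[-1L, 2] - q[-1L, 1] * q[-nrow(q), 2])) / 2
}

# even-odd scanline rasterization of a closed polygon onto an nr x nc grid
rasterize_polygon <- function(p, nr, nc) {
  mask <- matrix(0L, nr, nc)
  q <- rbind(p, p[1L, ])
  for (r in seq_len(nr)) {
    xs <- numeric(0)
    for (e in seq_len(nrow(q) - 1L)) {
      r1 <- q[e, 1]; r2 <- q[e + 1L, 1]
      if ((r1 <= r && r2 > r) || (r2 <= r && r1 > r)) {
        t <- (r - r1) / (r2 - r1)
        xs <- c(xs, q[e, 2] + t * (q[e + 1L, 2] - q[e, 2]))
      }
    }
    if (length(xs) >= 2L) {
      xs <- sort(xs)
      for (j in seq(1L, length(xs) - 1L, by = 2L)) {
        c1 <- max(1L, ceiling(xs[j])); c2 <- min(nc, floor(xs[j + 1L]))
        if (c1 <= c2) mask[r, c1:c2] <- 1L
      }
    }
  }
  mask
}

#' Parametric snake segmentation (parametric deformation baseline)
#'
#' Classical active-contour baseline: a closed control-point polygon evolves
#' under internal tension and bending forces plus an external force pulling
#' points toward intensity edges (the gradient of the squared smoothed
#' gradient magnitude). The implicit internal-energy update
#' \eqn{(I + \gamma A)\,x_{t+1} = x_t + \gamma f_{ext}(x_t)} is solved per
#' iteration; the polygon is resampled to equal arc length every few
#' iterations to stay simple.
#'
#' @param image numeric matrix.
#' @param init_polygon a \code{\link{snake_state}} (e.g. from
#'   \code{\link{snake_circle}}) inside the image bounds.
#' @param max_iter iterations.
#' @param smoothing_sigma Gaussian presmoothing of the edge map.
#' @param edge_weight scale of the external force.
#' @return A \code{segmentation_result} whose mask is the rasterized final
#'   polygon; the final \code{snake_state} is attached as \code{$snake}.
#' @export
parametric_snake_segment <- function(image, init_polygon, max_iter = 200L,
                                     smoothing_sigma = 1.5, edge_weight = 2) {
  stopifnot(inherits(init_polygon, "snake_state"))
  p <- init_polygon$control_points
  nr <- nrow(image); nc <- ncol(image)
  if (any(p[, 1] < 1) || any(p[, 1] > nr) || any(p[, 2] < 1) || any(p[, 2] > nc))
    abort_invalid_input("initial polygon lies outside the image bounds")
  alpha <- init_polygon$elasticity; beta <- init_polygon$rigidity
  gamma <- init_polygon$step
  n <- nrow(p)

  sm <- gaussian_blur(image, smoothing_sigma)
  edge <- diff_xc(sm)^2 + diff_yc(sm)^2
  if (max(edge) > 0) edge <- edge / max(edge)
  fx <- diff_xc(edge) * edge_weight
  fy <- diff_yc(edge) * edge_weight

  internal_solver <- function(n) {
    idx <- function(k) ((seq_len(n) - 1L + k) %% n) + 1L
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      A[i, i] <- 2 * alpha + 6 * beta
      A[i, idx(1)[i]] <- A[i, idx(-1)[i]] <- -alpha - 4 * beta
      A[i, idx(2)[i]] <- A[i, idx(-2)[i]] <- beta
    }
    solve(diag(n) + gamma * A)
  }
  Minv <- internal_solver(n)

  for (it in seq_len(max_iter)) {
    fr <- bilinear(fx, p[, 1], p[, 2])
    fc <- bilinear(fy, p[, 1], p[, 2])
    p <- Minv %*% (p + gamma * cbind(fr, fc))
    p[, 1] <- pmin(pmax(p[, 1], 1), nr)
    p[, 2] <- pmin(pmax(p[, 2], 1), nc)
    if (it %% 10L == 0L) {
      p <- resample_polygon(p, n)
      if (nrow(p) < 8L)
        abort_invalid_input("snake degenerated below 8 control points")
    }
  }
  mask <- rasterize_polygon(p, nr, nc)
  structure(list(mask = mask, phi = signed_distance(mask), n_iter = max_iter,
                 converged = TRUE, gmm = NULL,
                 snake = snake_state(p, alpha, beta, gamma),
                 config = NULL),
            class = "segmentation_result")
}
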