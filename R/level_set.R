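#' Segmentation (contour evolution) configuration
#'
#' @param max_iter maximum evolution iterations.
#' @param dt explicit Euler time step (grid units); checked against the CFL
#'   condition \code{dt * max|F| <= 0.5}.
#' @param curvature_weight nonnegative weight \code{nu} on the curvature
#'   smoothing term; larger values give smoother contours.
#' @param reinit_every iterations between reinitializations of the level-set
#'   field to a signed distance function.
#' @param convergence_frac evolution stops when the fraction of pixels whose
#'   sign changed in one iteration falls below this (resolution-independent).
#' @param init_shape initial contour: \code{"otsu-box"} (bounding box of
#'   above-Otsu pixels, dilated by 2), \code{"checkerboard"}, or
#'   \code{"user-mask"} (supply \code{init_mask}).
#' @param init_mask binary matrix used when \code{init_shape = "user-mask"}.
#' @param band_width half-width of the narrow band (grid units) within which
#'   the field is updated each iteration.
#' @param seed RNG seed recorded with results for provenance.
#' @return An object of class \code{seg_config}.
#' @export
seg_config <- function(max_iter = 500L, dt = 0.45, curvature_weight = 0.5,
                       reinit_every = 10L, convergence_frac = 1e-4,
                       init_shape = c("otsu-box", "checkerboard", "user-mask"),
                       init_mask = NULL, band_width = 6, seed = 1L) {
  init_shape <- match.arg(init_shape)
  if (!is.finite(dt) || dt <= 0) abort_config("'dt' must be positive")
  if (curvature_weight < 0) abort_config("'curvature_weight' must be >= 0")
  if (convergence_frac <= 0 || convergence_frac >= 1)
    abort_config("'convergence_frac' must lie in (0, 1)")
  structure(list(max_iter = as.integer(max_iter), dt = dt,
                 curvature_weight = curvature_weight,
                 reinit_every = as.integer(reinit_every),
                 convergence_frac = convergence_frac,
                 init_shape = init_shape, init_mask = init_mask,
                 band_width = band_width, seed = as.integer(seed)),
            class = "seg_config")
}

new_speed_field <- function(values, object_components = integer(0)) {
  if (any(!is.finite(values)))
    abort_invalid_input("speed field must be finite everywhere")
  structure(list(values = values, object_components = object_components),
            class = "speed_field")
}

#' Posterior log-odds speed field from a fitted mixture
#'
#' The stop term of the deformable model: instead of an image-gradient edge
#' map, the contour is driven by the fitted mixture's statistics. Per pixel
#' with intensity x,
#' \deqn{F(x) = \log\sum_{l \in obj} \pi_l N(x;\mu_l,\sigma^2_l) -
#'              \log\sum_{l \notin obj} \pi_l N(x;\mu_l,\sigma^2_l),}
#' clipped to \code{[-f_max, f_max]}. F is positive exactly where the object
#' posterior exceeds the background posterior, so under the level-set sign
#' convention positive speed expands the object region.
#'
#' @param image numeric matrix of intensities.
#' @param params \code{gmm_params} fitted to (a histogram of) this image.
#' @param object_components indices of components treated as object (lesion);
#'   must be a nonempty proper subset of \code{1:L}.
#' @param f_max clipping bound for the log-odds (default 10).
#' @return A \code{speed_field} (list with \code{values}, a matrix congruent
#'   with the image, and \code{object_components}).
#' @export
posterior_speed_field <- function(image, params, object_components,
                                  f_max = 10) {
  stopifnot(inherits(params, "gmm_params"))
  object_components <- sort(unique(as.integer(object_components)))
  if (length(object_components) == 0L ||
      length(object_components) >= params$L ||
      any(object_components < 1L) || any(object_components > params$L))
    abort_invalid_input(
      "'object_components' must be a nonempty proper subset of 1:L")
  x <- as.numeric(image)
  ld <- component_log_densities(x, params)
  obj <- log_sum_exp_rows(ld[, object_components, drop = FALSE])
  bg <- log_sum_exp_rows(ld[, -object_components, drop = FALSE])
  f <- pmin(pmax(obj - bg, -f_max), f_max)
  new_speed_field(matrix(f, nrow(image), ncol(image)), object_components)
}

#' Initialize the level-set contour
#'
#' Builds a signed distance function (negative inside) for one of three
#' initializations: the dilated bounding box of above-Otsu-threshold pixels,
#' a checkerboard of square seeds, or a user-supplied mask.
#'
#' @param image numeric matrix.
#' @param config a \code{\link{seg_config}}; its \code{init_shape} and
#'   \code{init_mask} fields are used.
#' @return An object of class \code{level_set_state}: list with \code{phi}
#'   (signed distance field), \code{iteration = 0}, \code{band_width}.
#' @export
initialize_contour <- function(image, config = seg_config()) {
  if (length(image) == 0L) abort_invalid_input("empty image")
  nr <- nrow(image); nc <- ncol(image)
  mask <- switch(config$init_shape,
    "otsu-box" = {
      thr <- otsu_threshold(image)
      hot <- which(image > thr, arr.ind = TRUE)
      if (nrow(hot) == 0L) hot <- cbind(round(nr / 2), round(nc / 2))
      r1 <- max(1L, min(hot[, 1]) - 2L); r2 <- min(nr, max(hot[, 1]) + 2L)
      c1 <- max(1L, min(hot[, 2]) - 2L); c2 <- min(nc, max(hot[, 2]) + 2L)
      m <- matrix(0, nr, nc); m[r1:r2, c1:c2] <- 1; m
    },
    "checkerboard" = {
      period <- 8L
      ri <- ((seq_len(nr) - 1L) %/% period) %% 2L
      ci <- ((seq_len(nc) - 1L) %/% period) %% 2L
      outer(ri, ci, function(a, b) as.numeric(a == b))
    },
    "user-mask" = {
      m <- config$init_mask
      if (is.null(m) || !identical(dim(m), dim(image)))
        abort_invalid_input("'init_mask' must be a mask with the image's shape")
      (m > 0) * 1
    })
  structure(list(phi = signed_distance(mask), iteration = 0L,
                 band_width = config$band_width),
            class = "level_set_state")
}

#' Evolve the level-set contour under a speed field
#'
#' Explicit upwind time stepping of
#' \deqn{\partial_t \phi = -F |\nabla\phi|_{upwind} + \nu \kappa |\nabla\phi|,}
#' with \code{phi < 0} inside the object, periodic reinitialization to a
#' signed distance function, and narrow-band updates. Evolution stops when
#' the per-iteration fraction of sign-changing pixels falls below
#' \code{config$convergence_frac}, or at \code{max_iter}.
#'
#' @param image numeric matrix (carried into the result; the dynamics use
#'   only \code{speed}).
#' @param speed a \code{speed_field} or numeric matrix congruent with the
#'   image; positive values expand the object.
#' @param init a \code{level_set_state} from \code{\link{initialize_contour}}.
#' @param config a \code{\link{seg_config}}. \code{dt * max|F| > 0.5} is a
#'   CFL violation and raises a configuration error.
#' @param gmm optional \code{gmm_params} echoed into the result.
#' @return An object of class \code{segmentation_result}: \code{mask} (binary
#'   matrix, 1 = object, the zero-sublevel set of the final field),
#'   \code{phi}, \code{n_iter}, \code{converged}, \code{gmm}, \code{config}.
#' @export
evolve_level_set <- function(image, speed, init, config = seg_config(),
                             gmm = NULL) {
  F <- if (inherits(speed, "speed_field")) speed$values else speed
  if (!identical(dim(F), dim(image)))
    abort_invalid_input("speed field and image shapes differ")
  if (any(!is.finite(F))) abort_invalid_input("speed field must be finite")
  if (config$dt * max(abs(F)) > 0.5 + 1e-12)
    abort_config(sprintf(
      "CFL violation: dt * max|F| = %.3f > 0.5; reduce dt or clip the speed",
      config$dt * max(abs(F))))
  phi <- init$phi
  nu <- config$curvature_weight
  n_px <- length(phi)
  converged <- FALSE
  it <- 0L
  # convergence is judged between reinitialization checkpoints: at sub-pixel
  # speeds a single iteration flips no signs even while the front is moving
  checkpoint_mask <- phi < 0
  for (it in seq_len(config$max_iter)) {
    band <- abs(phi) <= init$band_width
    uw <- upwind_grad(phi)
    adv <- pmax(F, 0) * uw$plus + pmin(F, 0) * uw$minus
    dphi <- -adv
    if (nu > 0) dphi <- dphi + nu * curvature_2d(phi) * grad_mag_central(phi)
    phi[band] <- phi[band] + config$dt * dphi[band]
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
                 converged = converged, gmm = gmm, config = config),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d x %d, object pixels = %d, %d iterations, %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

resolve_object_components <- function(params, object_rule) {
  if (is.numeric(object_rule)) return(as.integer(object_rule))
  switch(match.arg(object_rule, c("brightest", "darkest")),
         brightest = params$L,    # canonical order is ascending mean
         darkest = 1L)
}

segment_slice <- function(image, L, object_rule, config, em_config_) {
  h <- build_histogram(image)
  fit <- fit_gmm_em(h, L, em_config_)
  obj <- resolve_object_components(fit$params, object_rule)
  speed <- posterior_speed_field(image, fit$params, obj)
  # scale into the CFL-stable range rather than asking users to retune dt
  fmax <- max(abs(speed$values))
  if (config$dt * fmax > 0.5)
    speed$values <- speed$values * (0.5 / (config$dt * fmax))
  init <- initialize_contour(image, config)
  res <- evolve_level_set(image, speed, init, config, gmm = fit$params)
  res$object_components <- obj
  res
}

#' End-to-end histogram-analysis segmentation
#'
#' The full pipeline: build the intensity histogram, fit the Gaussian mixture
#' by EM, build the posterior log-odds speed field (object components chosen
#' by \code{object_rule}), initialize the contour, and evolve the level set.
#' Fully deterministic given the seeds in the two configs. A 3-D volume is
#' segmented slice by slice along its third dimension.
#'
#' @param image numeric matrix (2-D slice) or 3-D array.
#' @param L number of mixture components (e.g. 3 for
#'   background/parenchyma/lesion).
#' @param object_rule \code{"brightest"} (highest-mean component, e.g. a
#'   FLAIR-hyperintense lesion), \code{"darkest"}, or an integer vector of
#'   component indices.
#' @param config a \code{\link{seg_config}}.
#' @param em a \code{\link{em_config}}.
#' @return A \code{segmentation_result} (for 3-D input, \code{mask} and
#'   \code{phi} are 3-D arrays assembled slice-wise).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(48, 48), noise_sigma = 5,
#'                                     seed = 7))
#' res <- segment(ph$image, L = 3, object_rule = "brightest")
#' dice_coefficient(res$mask, ph$truth_mask)
#' @export
segment <- function(image, L = 3L, object_rule = "brightest",
                    config = seg_config(), em = em_config()) {
  nd <- length(dim(image))
  if (nd == 2L || is.null(dim(image))) {
    if (is.null(dim(image))) abort_invalid_input("image must be 2-D or 3-D")
    return(segment_slice(image, L, object_rule, config, em))
  }
  if (nd != 3L) abort_invalid_input("image must be 2-D or 3-D")
  mask <- array(0L, dim(image)); phi <- array(0, dim(image))
  iters <- 0L; conv <- TRUE; gmm <- NULL; obj <- NULL
  for (k in seq_len(dim(image)[3])) {
    r <- segment_slice(image[, , k], L, object_rule, config, em)
    mask[, , k] <- r$mask; phi[, , k] <- r$phi
    iters <- iters + r$n_iter; conv <- conv && r$converged
    gmm <- r$gmm; obj <- r$object_components
  }
  structure(list(mask = mask, phi = phi, n_iter = iters, converged = conv,
                 gmm = gmm, config = config, object_components = obj),
            class = "segmentation_result")
}
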