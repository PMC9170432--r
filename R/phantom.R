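#' Draw samples from a Gaussian mixture with known assignments
#'
#' Components are drawn from the mixing coefficients, then values from the
#' chosen component's normal; the true assignments are returned so parameter-
#' recovery tests can compare against the generator. Deterministic per seed.
#'
#' @param params a \code{gmm_params}.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return List with \code{samples} (a \code{sample_set}) and
#'   \code{assignments} (integer component indices, canonical order).
#' @export
simulate_gmm_samples <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "gmm_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort_invalid_input("'n' must be >= 1")
  set.seed(as.integer(seed))
  z <- sample.int(params$L, n, replace = TRUE, prob = params$pi)
  x <- rnorm(n, mean = params$mu[z], sd = sqrt(params$sigma2[z]))
  list(samples = sample_set(x), assignments = z)
}

#' Phantom specification
#'
#' Describes a brain-MRI-like synthetic slice: a dark background, an
#' elliptical "brain" of parenchyma intensity, and a hyperintense (or
#' hypointense) lesion inside it — piecewise near-constant tissue classes
#' corrupted by additive Gaussian noise and an optional smooth multiplicative
#' bias field. Intensities live on a [0, 255] scale by default, with class
#' means (20, 110, 200) so the default lesion resembles a FLAIR-hyperintense
#' stroke lesion.
#'
#' @param shape grid dimensions c(rows, cols).
#' @param class_means intensities of (background, parenchyma, lesion);
#'   pairwise distinct.
#' @param noise_sigma additive Gaussian noise standard deviation (intensity
#'   units), >= 0.
#' @param lesion_center (row, col) of the lesion, in pixels; default places
#'   it off-center inside the brain.
#' @param lesion_radii (row, col) semi-axes of the lesion, pixels.
#' @param lesion_shape \code{"ellipse"} or \code{"blob"} (ellipse with a
#'   smooth seeded radial perturbation).
#' @param bias_field_amplitude multiplicative bias amplitude as a fraction of
#'   1 (0 disables); the field is a smooth second-order polynomial surface
#'   with mean 1.
#' @param blur_sigma Gaussian blur (pixels) applied to the noise-free class
#'   image before noise, producing weak (partial-volume-like) edges; 0
#'   disables.
#' @param seed RNG seed.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(96L, 96L),
                         class_means = c(20, 110, 200),
                         noise_sigma = 5,
                         lesion_center = NULL,
                         lesion_radii = NULL,
                         lesion_shape = c("ellipse", "blob"),
                         bias_field_amplitude = 0,
                         blur_sigma = 0,
                         seed = 1L) {
  lesion_shape <- match.arg(lesion_shape)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L))
    abort_invalid_input("'shape' must be c(rows, cols), each >= 16")
  if (length(class_means) != 3L || anyDuplicated(class_means))
    abort_invalid_input("'class_means' must be 3 pairwise distinct intensities")
  if (noise_sigma < 0) abort_invalid_input("'noise_sigma' must be >= 0")
  if (bias_field_amplitude < 0)
    abort_invalid_input("'bias_field_amplitude' must be >= 0")
  if (is.null(lesion_center)) lesion_center <- round(shape * c(0.42, 0.58))
  if (is.null(lesion_radii)) lesion_radii <- round(shape * 0.12)
  structure(list(shape = shape, class_means = as.numeric(class_means),
                 noise_sigma = noise_sigma,
                 lesion_center = as.numeric(lesion_center),
                 lesion_radii = as.numeric(lesion_radii),
                 lesion_shape = lesion_shape,
                 bias_field_amplitude = bias_field_amplitude,
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipse_mask <- function(shape, center, radii, radial_pert = NULL) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- (r - center[1]); dc <- (c - center[2])
  if (is.null(radial_pert)) {
    (dr / radii[1])^2 + (dc / radii[2])^2 <= 1
  } else {
    th <- atan2(dc, dr)
    scale <- 1 + radial_pert(th)
    (dr / (radii[1] * scale))^2 + (dc / (radii[2] * scale))^2 <= 1
  }
}

#' Generate a synthetic brain-like phantom with exact ground truth
#'
#' Paints background, an elliptical parenchyma region and the lesion at the
#' spec's class means, optionally blurs the noise-free image (weak edges),
#' multiplies by the bias field, and adds Gaussian noise. The returned label
#' map and lesion mask are exact (pre-blur/pre-noise geometry), and the
#' output is a pure function of the spec (including its seed).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return An object of class \code{phantom_sample}: list with \code{image},
#'   \code{truth_mask} (binary lesion mask), \code{label_map} (1 =
#'   background, 2 = parenchyma, 3 = lesion) and the \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  brain_center <- shape / 2
  brain_radii <- shape * 0.42
  brain <- ellipse_mask(shape, brain_center, brain_radii)

  pert <- NULL
  if (spec$lesion_shape == "blob") {
    a <- runif(3, -0.15, 0.15); ph <- runif(3, 0, 2 * pi)
    pert <- function(th) a[1] * sin(2 * th + ph[1]) +
      a[2] * sin(3 * th + ph[2]) + a[3] * sin(5 * th + ph[3])
  }
  lesion <- ellipse_mask(shape, spec$lesion_center, spec$lesion_radii, pert)
  if (any(lesion & !brain))
    abort_invalid_input("lesion extends outside the brain region")

  label_map <- matrix(1L, shape[1], shape[2])
  label_map[brain] <- 2L
  label_map[lesion] <- 3L
  img <- matrix(spec$class_means[label_map], shape[1], shape[2])
  if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$bias_field_amplitude > 0) {
    u <- (matrix(seq_len(shape[1]), shape[1], shape[2]) / shape[1]) - 0.5
    v <- (matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) /
            shape[2]) - 0.5
    coef <- runif(5, -1, 1)
    surf <- coef[1] * u + coef[2] * v + coef[3] * u * v +
      coef[4] * (u^2 - mean(u^2)) + coef[5] * (v^2 - mean(v^2))
    surf <- surf / max(abs(surf))
    img <- img * (1 + spec$bias_field_amplitude * surf)
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(length(img), sd = spec$noise_sigma),
                        shape[1], shape[2])
  structure(list(image = img, truth_mask = lesion * 1L,
                 label_map = label_map, spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d x %d, lesion pixels = %d, noise sigma = %g, seed = %d\n",
              nrow(x$image), ncol(x$image), sum(x$truth_mask),
              x$spec$noise_sigma, x$spec$seed))
  invisible(x)
}

#' Seeded suites of phantoms at graded difficulty
#'
#' Draws per-image specs from difficulty-dependent ranges, with per-image
#' seeds derived deterministically from the master seed:
#' \itemize{
#'   \item \code{crisp}: sharp edges, light noise (sigma 2);
#'   \item \code{weak-edge}: the class image is Gaussian-blurred before noise
#'     (sigma 2.5-3.5 pixels), moderate noise — edges are shallow the way
#'     partial-volume lesion rims are;
#'   \item \code{noisy}: sharp edges, noise sigma equal to 20 percent of the
#'     smallest class contrast.
#' }
#'
#' @param n_images number of phantoms.
#' @param difficulty one of \code{"crisp"}, \code{"weak-edge"},
#'   \code{"noisy"}.
#' @param seed master seed.
#' @param shape per-image grid dimensions.
#' @return List of \code{phantom_sample}s.
#' @export
phantom_suite <- function(n_images, difficulty = c("crisp", "weak-edge", "noisy"),
                          seed = 1L, shape = c(64L, 64L)) {
  difficulty <- match.arg(difficulty)
  n_images <- as.integer(n_images)
  if (is.na(n_images) || n_images < 1L)
    abort_invalid_input("'n_images' must be >= 1")
  set.seed(as.integer(seed))
  child_seeds <- sample.int(.Machine$integer.max %/% 2L, n_images)
  lapply(seq_len(n_images), function(i) {
    set.seed(child_seeds[i])
    means <- c(runif(1, 10, 30), runif(1, 95, 125), runif(1, 185, 215))
    min_contrast <- min(diff(sort(means)))
    center <- round(shape * runif(2, 0.38, 0.62))
    radii <- round(pmax(shape * runif(2, 0.08, 0.16), 5))
    sp <- switch(difficulty,
      "crisp" = phantom_spec(shape, means, noise_sigma = 2,
                             lesion_center = center, lesion_radii = radii,
                             lesion_shape = "blob", seed = child_seeds[i]),
      "weak-edge" = phantom_spec(shape, means, noise_sigma = 6,
                                 lesion_center = center, lesion_radii = radii,
                                 lesion_shape = "blob",
                                 blur_sigma = runif(1, 2.5, 3.5),
                                 seed = child_seeds[i]),
      "noisy" = phantom_spec(shape, means, noise_sigma = 0.2 * min_contrast,
                             lesion_center = center, lesion_radii = radii,
                             lesion_shape = "blob", seed = child_seeds[i]))
    generate_phantom(sp)
  })
}
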