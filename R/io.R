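#' Read a grayscale image (NIfTI or PNG)
#'
#' NIfTI volumes keep their header so masks can be written back into the
#' source geometry; PNGs are loaded as grayscale with their integer intensity
#' range preserved exactly (8-bit values in [0, 255], 16-bit in [0, 65535]).
#' Multichannel PNGs are averaged to grayscale.
#'
#' @param path file ending in \code{.nii}, \code{.nii.gz} or \code{.png}.
#' @return Numeric matrix or array with attributes \code{format}
#'   (\code{"nifti"}/\code{"png"}) and, for NIfTI, \code{nifti_header}.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_io(paste0("no such file: ", path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    out <- array(as.numeric(img), dim = dim(img))
    attr(out, "format") <- "nifti"
    attr(out, "nifti_header") <- RNifti::niftiHeader(img)
    return(out)
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (length(dim(raw)) == 3L) raw <- apply(raw, c(1, 2), mean)
    out <- round(raw * (2^depth - 1))
    attr(out, "format") <- "png"
    attr(out, "bit_depth") <- depth
    return(out)
  }
  abort_io(paste0("unsupported image format (need .nii/.nii.gz/.png): ", path))
}

#' Write a grayscale image or binary mask (NIfTI or PNG)
#'
#' Masks are stored as {0, 1}; NIfTI output inherits the header of
#' \code{like} (typically the image returned by \code{\link{read_image}})
#' when given.
#'
#' @param data numeric matrix/array; for \code{write_mask} a binary mask.
#' @param path output path ending in \code{.nii}, \code{.nii.gz} or
#'   \code{.png}.
#' @param like optional reference image carrying geometry (NIfTI header).
#' @param bit_depth PNG bit depth, 8 or 16.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(data, path, like = NULL, bit_depth = 8L) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    hdr <- if (!is.null(like)) attr(like, "nifti_header") else NULL
    img <- if (!is.null(hdr))
      RNifti::asNifti(array(data, dim = dim(data)), reference = hdr)
    else RNifti::asNifti(array(data, dim = dim(data)))
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (length(dim(data)) != 2L) abort_io("PNG output requires a 2-D image")
    maxv <- 2^bit_depth - 1
    png::writePNG(pmin(pmax(unclass(data) / maxv, 0), 1), path)
    return(invisible(path))
  }
  abort_io(paste0("unsupported output format: ", path))
}

#' @rdname write_image
#' @export
write_mask <- function(data, path, like = NULL, bit_depth = 8L) {
  m <- (unclass(data) != 0) * 1
  dim(m) <- dim(data)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    # {0,1} stored at full scale so the mask is visible, read back as 0/max
    return(write_image(m * (2^bit_depth - 1), path, like, bit_depth))
  }
  write_image(m, path, like, bit_depth)
}

run_config_defaults <- function() {
  list(seed = 1L, n_bins = 256L, components = 3L, object_rule = "brightest",
       em = list(max_iter = 500L, tol = 1e-6, init_method = "quantile"),
       segmentation = list(max_iter = 500L, dt = 0.45, curvature_weight = 0.5,
                           reinit_every = 10L, convergence_frac = 1e-4,
                           init_shape = "otsu-box", band_width = 6),
       phantom = list(shape = c(96L, 96L), class_means = c(20, 110, 200),
                      noise_sigma = 5, bias_field_amplitude = 0))
}

#' Read / write the merged run configuration (YAML)
#'
#' The run configuration bundles EM, segmentation and phantom defaults plus
#' the seed; unknown keys are rejected so typos fail loudly instead of being
#' silently ignored.
#'
#' @param path YAML file path.
#' @param config a named list as returned by \code{read_run_config}.
#' @return \code{read_run_config} returns the merged configuration (defaults
#'   overridden by the file); \code{write_run_config} returns \code{path}
#'   invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(paste0("no such file: ", path))
  user <- yaml::read_yaml(path)
  defaults <- run_config_defaults()
  check_keys <- function(u, d, prefix = "") {
    bad <- setdiff(names(u), names(d))
    if (length(bad))
      abort_config(paste0("unknown config key(s): ",
                          paste0(prefix, bad, collapse = ", ")))
    for (k in names(u)) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]])))
        check_keys(u[[k]], d[[k]], paste0(prefix, k, "."))
    }
  }
  if (!is.null(user)) check_keys(user, defaults)
  merged <- modifyList(defaults, if (is.null(user)) list() else user)
  merged
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a segmentation result's metadata sidecar (JSON)
#'
#' Records seed, component count, iterations, convergence and the fitted
#' mixture so a run is auditable from its outputs.
#'
#' @param result a \code{segmentation_result}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "segmentation_result"))
  meta <- list(
    n_iter = result$n_iter,
    converged = result$converged,
    object_pixels = sum(result$mask),
    object_components = result$object_components,
    seed = if (!is.null(result$config)) result$config$seed else NULL,
    gmm = if (!is.null(result$gmm))
      lapply(seq_len(result$gmm$L), function(l)
        list(pi = result$gmm$pi[l], mu = result$gmm$mu[l],
             sigma2 = result$gmm$sigma2[l]))
    else NULL)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
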