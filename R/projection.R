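#' Parallel-beam scan geometry
#'
#' View angles are uniformly spaced over `[0, 180)` degrees; detector bins
#' are centred on the rotation axis, bin `d` (1-based) at signed offset
#' `(d - (n_detectors + 1)/2) * detector_spacing`. Rays are indexed
#' `c = (a - 1) * n_detectors + d` for view `a`, bin `d` (both 1-based);
#' this ordering is fixed and shared with [build_system_matrix()].
#'
#' @param n_angles number of view angles (>= 1).
#' @param n_detectors detector bins per view (>= 1).
#' @param detector_spacing bin spacing in mm.
#' @param field_of_view nominal field of view in mm; a warning is issued if
#'   the detector array does not span its diagonal.
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_angles, n_detectors, detector_spacing,
                          field_of_view = n_detectors * detector_spacing / sqrt(2)) {
  if (n_angles < 1 || n_detectors < 1 || detector_spacing <= 0 ||
      field_of_view <= 0) {
    stop("scan_geometry: invalid geometry parameters", call. = FALSE)
  }
  if (n_detectors * detector_spacing < sqrt(2) * field_of_view - 1e-9) {
    warning("scan_geometry: detector array does not span the field-of-view diagonal; peripheral structures will be truncated",
            call. = FALSE)
  }
  structure(
    list(n_angles = as.integer(n_angles),
         n_detectors = as.integer(n_detectors),
         detector_spacing = detector_spacing,
         field_of_view = field_of_view),
    class = "scan_geometry"
  )
}

#' Default scan geometry for a given reconstruction grid
#'
#' Detector spacing matches the pixel spacing of the target grid and the
#' (odd) detector count covers the field-of-view diagonal.
#'
#' @param size reconstruction grid size in pixels.
#' @param n_angles number of views (default 180).
#' @param field_of_view field of view in mm (default 220).
#' @return a [scan_geometry()].
#' @export
default_geometry <- function(size = 256, n_angles = 180, field_of_view = 220) {
  spacing <- field_of_view / size
  n_det <- 2L * as.integer(ceiling(size * sqrt(2) / 2)) + 1L
  scan_geometry(n_angles, n_det, spacing, field_of_view)
}

#' Sinogram: projection data on a scan geometry
#'
#' @param values numeric `n_angles x n_detectors` matrix of line integrals
#'   of the attenuation map (dimensionless: 1/mm times mm).
#' @param geometry the [scan_geometry()] the data were measured on.
#' @return object of class `sinogram`.
#' @export
sinogram <- function(values, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_angles ||
      ncol(values) != geometry$n_detectors) {
    stop("sinogram: 'values' must be n_angles x n_detectors", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("sinogram: values must be finite", call. = FALSE)
  }
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d detectors, %.4g mm bins\n",
              x$geometry$n_angles, x$geometry$n_detectors,
              x$geometry$detector_spacing))
  invisible(x)
}

# sinogram matrix <-> ray-ordered vector (c = (a-1)*n_det + d)
sino_to_vec <- function(values) as.vector(t(values))
vec_to_sino <- function(v, geometry) {
  matrix(v, nrow = geometry$n_angles, byrow = TRUE)
}

#' Build the sparse ray--pixel system matrix
#'
#' Entry `(c, k)` is the exact intersection length in mm of ray `c` with
#' pixel `k`, computed by Siddon-style incremental ray traversal. Rays that
#' miss the grid have empty rows. Pixel indices follow the column-major
#' order of the image matrix (`k = (col - 1) * size + row`).
#'
#' @param geometry a [scan_geometry()].
#' @param size image grid size in pixels.
#' @param pixel_spacing pixel size in mm (default `field_of_view / size`).
#' @return object of class `system_matrix` with fields `A` (a
#'   `Matrix::dgCMatrix`, `n_rays x n_pixels`), cached `row_sums` /
#'   `col_sums`, and the grid/geometry metadata.
#' @export
build_system_matrix <- function(geometry, size,
                                pixel_spacing = geometry$field_of_view / size) {
  stopifnot(inherits(geometry, "scan_geometry"))
  size <- as.integer(size)
  trip <- siddon_weights(geometry$n_angles, geometry$n_detectors,
                         geometry$detector_spacing, size, pixel_spacing)
  n_rays <- geometry$n_angles * geometry$n_detectors
  A <- Matrix::sparseMatrix(i = trip$ray + 1L, j = trip$pixel + 1L,
                            x = trip$weight,
                            dims = c(n_rays, size^2L))
  new_system_matrix(A, geometry = geometry, size = size,
                    pixel_spacing = pixel_spacing)
}

new_system_matrix <- function(A, geometry = NULL, size = NULL,
                              pixel_spacing = 1) {
  structure(
    list(A = A,
         At = Matrix::t(A),
         row_sums = Matrix::rowSums(A),
         col_sums = Matrix::colSums(A),
         n_rays = nrow(A), n_pixels = ncol(A),
         geometry = geometry, size = size, pixel_spacing = pixel_spacing),
    class = "system_matrix"
  )
}

#' Wrap an explicit weight matrix as a system matrix
#'
#' Mainly for small hand-built systems: any non-negative dense or sparse
#' `n_rays x n_pixels` matrix can drive the projector and the iterative
#' reconstructor.
#'
#' @param A numeric matrix (or `Matrix` sparse matrix) of ray weights.
#' @param geometry optional [scan_geometry()] metadata.
#' @param size optional image side length (pixels); defaults to
#'   `sqrt(ncol(A))` when that is an integer.
#' @param pixel_spacing pixel size in mm.
#' @return a `system_matrix`.
#' @export
as_system_matrix <- function(A, geometry = NULL, size = NULL,
                             pixel_spacing = 1) {
  A <- methods::as(methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (any(A@x < 0)) {
    stop("as_system_matrix: weights must be non-negative", call. = FALSE)
  }
  if (is.null(size)) {
    s <- sqrt(ncol(A))
    if (abs(s - round(s)) < 1e-9) size <- as.integer(round(s))
  }
  new_system_matrix(A, geometry = geometry, size = size,
                    pixel_spacing = pixel_spacing)
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> %d rays x %d pixels, %d non-zero weights\n",
              x$n_rays, x$n_pixels, length(x$A@x)))
  invisible(x)
}

#' Forward projection: image to sinogram
#'
#' Computes the line integrals `Y_c = sum_k Z_kc R_k` of an attenuation
#' image through the system matrix. The operation is exactly linear in the
#' image.
#'
#' @param image an [image_grid()] with `value_kind = "MU"`.
#' @param matrix a [build_system_matrix()] result whose grid matches the
#'   image.
#' @return a [sinogram()].
#' @export
forward_project <- function(image, matrix) {
  stopifnot(inherits(image, "image_grid"), inherits(matrix, "system_matrix"))
  if (image$value_kind != "MU") {
    stop("forward_project: image must carry MU values (see hu_to_mu)",
         call. = FALSE)
  }
  if (image$size^2 != matrix$n_pixels) {
    stop("forward_project: image size does not match the system matrix",
         call. = FALSE)
  }
  if (is.null(matrix$geometry)) {
    stop("forward_project: system matrix carries no scan geometry",
         call. = FALSE)
  }
  y <- as.numeric(matrix$A %*% as.vector(image$pixels))
  sinogram(vec_to_sino(y, matrix$geometry), matrix$geometry)
}

#' Photon-noise model parameterised by a noise index
#'
#' The noise index (NI) is interpreted as the target noise SD, in HU, of a
#' water-equivalent background region in the filtered-back-projection
#' reconstruction -- the way the dose-control knob behaves on clinical
#' scanners. `incident_counts` (photons per detector bin) is the physical
#' parameter actually used by [add_noise()]; [calibrate_counts()] derives it
#' from the noise index for a given geometry.
#'
#' @param noise_index target background SD in HU (>= 0; 0 disables noise).
#' @param seed integer seed driving the Poisson draws.
#' @param incident_counts photons per detector bin; may be left `NULL` and
#'   filled in later by calibration.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(noise_index, seed = 1L, incident_counts = NULL) {
  if (noise_index < 0) {
    stop("noise_model: noise_index must be >= 0", call. = FALSE)
  }
  if (noise_index > 0 && !is.null(incident_counts) && incident_counts <= 0) {
    stop("noise_model: incident_counts must be positive", call. = FALSE)
  }
  structure(
    list(noise_index = noise_index, incident_counts = incident_counts,
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

# run expr with a private RNG stream, restoring the caller's state
with_private_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add Poisson photon noise to a sinogram
#'
#' Transmission counts `N_c ~ Poisson(I0 * exp(-Y_c))` are drawn with the
#' model seed and the noisy projection recomputed as
#' `-log(max(N_c, 1) / I0)`; zero-count bins are clamped to one count before
#' the log, the standard guard against infinities. A model with
#' `noise_index = 0` returns the input unchanged. Identical seeds give
#' bit-identical output; the caller's RNG state is untouched.
#'
#' @param sino a [sinogram()] of noiseless line integrals.
#' @param model a [noise_model()] with `incident_counts` set (see
#'   [calibrate_counts()]).
#' @return a [sinogram()] of noisy line integrals.
#' @export
add_noise <- function(sino, model) {
  stopifnot(inherits(sino, "sinogram"), inherits(model, "noise_model"))
  if (model$noise_index == 0) return(sino)
  if (is.null(model$incident_counts) || model$incident_counts <= 0) {
    stop("add_noise: model has no incident_counts; calibrate it first",
         call. = FALSE)
  }
  I0 <- model$incident_counts
  lambda <- I0 * exp(-sino$values)
  if (any(lambda < 10)) {
    warning("add_noise: expected counts below 10 in some bins (photon starvation)",
            call. = FALSE)
  }
  counts <- with_private_rng(model$seed, {
    matrix(stats::rpois(length(lambda), lambda),
           nrow(lambda), ncol(lambda))
  })
  sinogram(-log(pmax(counts, 1) / I0), sino$geometry)
}

#' Analytic parallel-beam sinogram of a uniform disk
#'
#' The line integral of a uniform disk of attenuation `mu` and radius `R`
#' along a ray at signed distance `t'` from its centre is
#' `2 mu sqrt(R^2 - t'^2)` -- an exact closed form, useful as a
#' reconstruction oracle and for noise calibration.
#'
#' @param geometry a [scan_geometry()].
#' @param radius disk radius in mm.
#' @param hu disk contrast in HU (converted internally to attenuation).
#' @param mu_water water attenuation in 1/mm.
#' @param center disk centre `c(x, y)` in mm.
#' @return a [sinogram()].
#' @export
disk_sinogram <- function(geometry, radius, hu = 0, mu_water = 0.02,
                          center = c(0, 0)) {
  stopifnot(inherits(geometry, "scan_geometry"))
  mu <- mu_water * (1 + hu / 1000)
  theta <- pi * (seq_len(geometry$n_angles) - 1) / geometry$n_angles
  t <- (seq_len(geometry$n_detectors) - (geometry$n_detectors + 1) / 2) *
    geometry$detector_spacing
  vals <- matrix(0, geometry$n_angles, geometry$n_detectors)
  for (a in seq_len(geometry$n_angles)) {
    tc <- t - (center[1] * cos(theta[a]) + center[2] * sin(theta[a]))
    inside <- abs(tc) < radius
    vals[a, inside] <- 2 * mu * sqrt(radius^2 - tc[inside]^2)
  }
  sinogram(vals, geometry)
}

#' Calibrate incident counts against a noise index
#'
#' Finds the incident photon count per detector bin at which the
#' filtered-back-projection reconstruction of a noisy water-cylinder
#' (flat-field) acquisition has a central-region HU standard deviation equal
#' to the requested noise index. The search brackets the answer with the
#' `SD ~ 1/sqrt(I0)` power law and then bisects on `log(I0)`, averaging the
#' measured SD over `n_seeds` seeded realisations at each step.
#'
#' @param noise_index target background SD in HU (> 0).
#' @param geometry a [scan_geometry()].
#' @param size reconstruction grid size in pixels.
#' @param seed base seed for the calibration draws.
#' @param n_seeds realisations averaged per bisection step.
#' @param filter_window FBP window used for the calibration
#'   reconstructions (must match the comparison's FBP configuration).
#' @param mu_water water attenuation in 1/mm.
#' @param tol relative SD tolerance at which bisection stops.
#' @return incident counts per detector bin (a single number).
#' @export
calibrate_counts <- function(noise_index, geometry, size, seed = 1L,
                             n_seeds = 3L, filter_window = "hann",
                             mu_water = 0.02, tol = 0.02) {
  if (noise_index <= 0) {
    stop("calibrate_counts: noise_index must be positive", call. = FALSE)
  }
  radius <- 0.40 * geometry$field_of_view
  clean <- disk_sinogram(geometry, radius, hu = 0, mu_water = mu_water)
  cfg <- fbp_config(filter_window = filter_window, output_size = size,
                    pixel_spacing = geometry$field_of_view / size)
  cc <- pixel_centres(size, geometry$field_of_view / size)
  r2 <- outer(cc$y^2, cc$x^2, `+`)
  roi <- r2 < (0.15 * geometry$field_of_view)^2

  measure_sd <- function(I0) {
    sds <- vapply(seq_len(n_seeds), function(s) {
      nm <- noise_model(noise_index, seed = seed + 7919L * s,
                        incident_counts = I0)
      noisy <- suppressWarnings(add_noise(clean, nm))
      rec <- fbp_reconstruct(noisy, cfg, mu_water = mu_water)
      stats::sd(rec$pixels[roi])
    }, numeric(1))
    mean(sds)
  }

  I0 <- 1e5
  sd0 <- measure_sd(I0)
  I0 <- I0 * (sd0 / noise_index)^2          # power-law warm start
  lo <- log(I0 / 8); hi <- log(I0 * 8)
  for (it in seq_len(12L)) {
    mid <- (lo + hi) / 2
    s <- measure_sd(exp(mid))
    if (abs(s - noise_index) / noise_index < tol) return(exp(mid))
    if (s > noise_index) lo <- mid else hi <- mid   # SD decreases with I0
  }
  exp((lo + hi) / 2)
}
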