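#' Square 2-D image grid
#'
#' The basic image container used throughout the package: a square pixel
#' array together with its physical pixel spacing and the kind of value it
#' carries -- Hounsfield units (`"HU"`) or linear attenuation coefficients
#' in 1/mm (`"MU"`).
#'
#' Geometric conventions, shared by every module: the physical origin is at
#' the grid centre, x points right and y points up; array element
#' `pixels[1, 1]` is the top-left pixel; `pixel_spacing = field_of_view /
#' size`. The centre of pixel `[i, j]` (row i, column j, 1-based) sits at
#' `x = (j - 1/2 - size/2) * pixel_spacing`,
#' `y = (size/2 - i + 1/2) * pixel_spacing`.
#'
#' @param pixels square numeric matrix of pixel values.
#' @param pixel_spacing physical size of one pixel in mm.
#' @param value_kind `"HU"` (Hounsfield units) or `"MU"` (attenuation, 1/mm).
#' @return An object of class `image_grid` with fields `pixels`, `size`,
#'   `pixel_spacing`, `value_kind`.
#' @export
image_grid <- function(pixels, pixel_spacing, value_kind = c("HU", "MU")) {
  value_kind <- match.arg(value_kind)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) {
    stop("image_grid: 'pixels' must be a square matrix", call. = FALSE)
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0) {
    stop("image_grid: 'pixel_spacing' must be a single positive number",
         call. = FALSE)
  }
  structure(
    list(pixels = pixels, size = nrow(pixels),
         pixel_spacing = pixel_spacing, value_kind = value_kind),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels, %.4g mm/pixel, values in %s\n",
              x$size, x$size, x$pixel_spacing, x$value_kind))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.image_grid <- function(x, ...) x$pixels

#' Physical coordinates of pixel centres
#'
#' @param size pixels per side.
#' @param pixel_spacing mm per pixel.
#' @return list with `x` (length-`size` vector of column-centre x
#'   coordinates) and `y` (row-centre y coordinates, top row first).
#' @keywords internal
pixel_centres <- function(size, pixel_spacing) {
  j <- seq_len(size)
  list(x = (j - 0.5 - size / 2) * pixel_spacing,
       y = (size / 2 - j + 0.5) * pixel_spacing)
}

#' Convert between Hounsfield units and linear attenuation
#'
#' The HU scale is defined by `HU = 1000 * (mu - mu_water) / mu_water`, so
#' water maps to 0 HU and air (mu = 0) to -1000 HU. `hu_to_mu()` applies the
#' inverse, `mu = mu_water * (1 + HU/1000)`; `mu_to_hu()` recovers HU
#' exactly.
#'
#' @param image an [image_grid()] in HU (for `hu_to_mu`) or MU
#'   (for `mu_to_hu`).
#' @param mu_water linear attenuation coefficient of water in 1/mm; the
#'   default 0.02/mm corresponds to the effective energy of a ~120 kVp
#'   abdominal beam.
#' @return An [image_grid()] with the converted `value_kind`.
#' @export
hu_to_mu <- function(image, mu_water = 0.02) {
  stopifnot(inherits(image, "image_grid"))
  if (image$value_kind != "HU") {
    stop("hu_to_mu: image must carry HU values", call. = FALSE)
  }
  image_grid(mu_water * (1 + image$pixels / 1000),
             image$pixel_spacing, value_kind = "MU")
}

#' @rdname hu_to_mu
#' @export
mu_to_hu <- function(image, mu_water = 0.02) {
  stopifnot(inherits(image, "image_grid"))
  if (image$value_kind != "MU") {
    stop("mu_to_hu: image must carry MU values", call. = FALSE)
  }
  image_grid(1000 * (image$pixels / mu_water - 1),
             image$pixel_spacing, value_kind = "HU")
}
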