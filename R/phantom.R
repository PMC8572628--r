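#' Ellipse primitive for phantom construction
#'
#' @param center_x,center_y centre in physical mm (origin at grid centre).
#' @param semi_axis_a,semi_axis_b semi-axes in mm, both positive;
#'   `semi_axis_a` lies along the ellipse's own x axis before rotation.
#' @param rotation counter-clockwise rotation in degrees, normalised to
#'   `[0, 360)`.
#' @param hu_value Hounsfield value assigned inside the ellipse.
#' @param label free-text region name (e.g. `"liver"`).
#' @return object of class `ct_ellipse`.
#' @export
ellipse <- function(center_x, center_y, semi_axis_a, semi_axis_b,
                    rotation = 0, hu_value = 0, label = "") {
  if (!is.numeric(semi_axis_a) || semi_axis_a <= 0 ||
      !is.numeric(semi_axis_b) || semi_axis_b <= 0) {
    stop("ellipse: semi-axes must be positive", call. = FALSE)
  }
  rotation <- rotation %% 360
  structure(
    list(center_x = center_x, center_y = center_y,
         semi_axis_a = semi_axis_a, semi_axis_b = semi_axis_b,
         rotation = rotation, hu_value = hu_value,
         label = as.character(label)),
    class = "ct_ellipse"
  )
}

# axis-aligned half-extents of a rotated ellipse (for fit checks)
ellipse_extents <- function(e) {
  phi <- e$rotation * pi / 180
  wx <- sqrt((e$semi_axis_a * cos(phi))^2 + (e$semi_axis_b * sin(phi))^2)
  wy <- sqrt((e$semi_axis_a * sin(phi))^2 + (e$semi_axis_b * cos(phi))^2)
  c(wx, wy)
}

#' Phantom specification: layered ellipses on a uniform background
#'
#' A phantom is an ordered list of ellipses drawn on a square field of view;
#' where ellipses overlap, later entries overwrite earlier ones (the usual
#' layered-anatomy convention of Shepp--Logan-style phantoms).
#'
#' @param ellipses list of [ellipse()] objects, drawn in order.
#' @param field_of_view side length of the square field of view in mm
#'   (default 220 mm, a typical abdominal CT field of view).
#' @param background_hu Hounsfield value outside every ellipse; default
#'   -1000 (air).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(ellipses = list(), field_of_view = 220,
                         background_hu = -1000) {
  if (!is.numeric(field_of_view) || length(field_of_view) != 1L ||
      field_of_view <= 0) {
    stop("phantom_spec: field_of_view must be positive", call. = FALSE)
  }
  if (inherits(ellipses, "ct_ellipse")) ellipses <- list(ellipses)
  for (e in ellipses) {
    if (!inherits(e, "ct_ellipse")) {
      stop("phantom_spec: every element of 'ellipses' must be an ellipse()",
           call. = FALSE)
    }
    w <- ellipse_extents(e)
    if (abs(e$center_x) + w[1] > field_of_view / 2 + 1e-9 ||
        abs(e$center_y) + w[2] > field_of_view / 2 + 1e-9) {
      stop(sprintf(
        "phantom_spec: ellipse '%s' does not fit inside the %g mm field of view",
        e$label, field_of_view), call. = FALSE)
    }
  }
  structure(
    list(ellipses = ellipses, field_of_view = field_of_view,
         background_hu = background_hu),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d ellipse(s), FOV %g mm, background %g HU\n",
              length(x$ellipses), x$field_of_view, x$background_hu))
  for (e in x$ellipses) {
    cat(sprintf("  %-12s %7.4g HU  centre (%g, %g)  axes (%g, %g)  rot %g\n",
                e$label, e$hu_value, e$center_x, e$center_y,
                e$semi_axis_a, e$semi_axis_b, e$rotation))
  }
  invisible(x)
}

#' Default synthetic abdomen phantom
#'
#' A four-region abdominal slice standing in for a clinical scan: an outer
#' subcutaneous-fat oval (-90 HU), a soft-tissue body oval (40 HU) layered
#' on top of it so the visible fat forms an 18 mm annulus, a liver ellipse
#' (77 HU) and a gallbladder ellipse (55 HU). Organ values are chosen so that
#' region-of-interest means on noiseless reconstructions land near typical
#' portal-phase abdominal CT values (liver about 77 HU, gallbladder in the
#' 50s). Background outside the body is air (-1000 HU).
#'
#' @param field_of_view field of view in mm (default 220).
#' @return a [phantom_spec()] with labels `"fat"`, `"body"`, `"liver"`,
#'   `"gallbladder"`, each present exactly once.
#' @export
default_abdomen_spec <- function(field_of_view = 220) {
  phantom_spec(
    ellipses = list(
      ellipse(0, 0, 104, 84, 0, -90, "fat"),
      ellipse(0, 0, 86, 66, 0, 40, "body"),
      ellipse(-32, 14, 44, 30, 15, 77, "liver"),
      ellipse(-6, -22, 15, 11, 340, 55, "gallbladder")
    ),
    field_of_view = field_of_view,
    background_hu = -1000
  )
}

# index of the last ellipse covering each pixel centre (0 = background)
phantom_owner <- function(spec, size) {
  h <- spec$field_of_view / size
  cc <- pixel_centres(size, h)
  X <- matrix(cc$x, nrow = size, ncol = size, byrow = TRUE)
  Y <- matrix(cc$y, nrow = size, ncol = size)
  owner <- matrix(0L, size, size)
  for (m in seq_along(spec$ellipses)) {
    e <- spec$ellipses[[m]]
    phi <- e$rotation * pi / 180
    dx <- X - e$center_x
    dy <- Y - e$center_y
    u <- cos(phi) * dx + sin(phi) * dy
    v <- -sin(phi) * dx + cos(phi) * dy
    inside <- (u / e$semi_axis_a)^2 + (v / e$semi_axis_b)^2 <= 1
    owner[inside] <- m
  }
  owner
}

#' Rasterise a phantom specification to an image grid
#'
#' Membership is decided by pixel-centre containment (a pixel takes the HU
#' value of the last ellipse whose closed interior contains its centre),
#' with no anti-aliasing, so rendering is exact and deterministic.
#'
#' @param spec a [phantom_spec()].
#' @param size pixels per side (>= 8); defaults to the 512 matrix of a
#'   clinical abdominal acquisition.
#' @return an [image_grid()] in HU with
#'   `pixel_spacing = field_of_view / size`.
#' @export
render_phantom <- function(spec, size = 512) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(size) || length(size) != 1L || size < 8) {
    stop("render_phantom: 'size' must be at least 8", call. = FALSE)
  }
  size <- as.integer(size)
  owner <- phantom_owner(spec, size)
  hu <- c(spec$background_hu,
          vapply(spec$ellipses, function(e) e$hu_value, numeric(1)))
  pixels <- matrix(hu[owner + 1L], size, size)
  image_grid(pixels, spec$field_of_view / size, value_kind = "HU")
}

#' Boolean mask of one labelled phantom region
#'
#' The mask is true exactly where [render_phantom()] assigns that region's
#' value, i.e. where the labelled ellipse is the topmost (last) ellipse
#' covering the pixel centre. A region completely hidden by later ellipses
#' yields an empty mask.
#'
#' @param spec a [phantom_spec()].
#' @param label region label to extract; must exist in the spec.
#' @param size pixels per side.
#' @return logical `size x size` matrix.
#' @export
region_mask <- function(spec, label, size = 512) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- vapply(spec$ellipses, function(e) e$label, character(1))
  hits <- which(labels == label)
  if (length(hits) == 0) {
    stop(sprintf("region_mask: no ellipse labelled '%s' in this spec", label),
         call. = FALSE)
  }
  owner <- phantom_owner(spec, as.integer(size))
  matrix(owner %in% hits, nrow(owner), ncol(owner))
}
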