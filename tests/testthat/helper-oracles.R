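# Shared oracles and fixture builders. Everything here is independent of
# the code paths it checks: chord lengths come from Liang-Barsky clipping,
# least-squares solutions from an explicit pseudoinverse, areas from the
# analytic ellipse formula.

# chord length of the ray (angle theta, detector offset t) inside the
# centred L x L square, by line-box clipping
chord_length_oracle <- function(theta, t, L) {
  px <- t * cos(theta); py <- t * sin(theta)
  dx <- -sin(theta); dy <- cos(theta)
  s0 <- -1e30; s1 <- 1e30
  if (abs(dx) > 1e-14) {
    sa <- (-L / 2 - px) / dx; sb <- (L / 2 - px) / dx
    s0 <- max(s0, min(sa, sb)); s1 <- min(s1, max(sa, sb))
  } else if (abs(px) >= L / 2) return(0)
  if (abs(dy) > 1e-14) {
    sa <- (-L / 2 - py) / dy; sb <- (L / 2 - py) / dy
    s0 <- max(s0, min(sa, sb)); s1 <- min(s1, max(sa, sb))
  } else if (abs(py) >= L / 2) return(0)
  max(0, s1 - s0)
}

# random consistent full-column-rank system with a non-negative solution;
# the condition cap keeps the iteration counts of the convergence tests
# bounded without changing what is being asserted
random_consistent_system <- function() {
  repeat {
    np <- sample(4:9, 1)
    nr <- sample((np + 2):16, 1)
    A <- matrix(stats::rexp(nr * np), nr, np) *
      matrix(stats::rbinom(nr * np, 1, 0.7), nr, np)
    zero_rows <- rowSums(A) == 0
    A[zero_rows, 1] <- 1
    if (qr(A)$rank == np && kappa(A) < 100) break
  }
  x_true <- stats::runif(np, 0, 2)
  list(A = A, x_true = x_true, y = as.numeric(A %*% x_true))
}

# solution vector of an iter_result regardless of output container
solution_vector <- function(res) {
  if (inherits(res$image, "image_grid")) {
    as.vector(hu_to_mu(res$image)$pixels)
  } else {
    res$image
  }
}

# interior masks for disk-recovery checks
disk_masks <- function(size, fov, r_roi, r_interior) {
  cc <- ctrecon:::pixel_centres(size, fov / size)
  r2 <- outer(cc$y^2, cc$x^2, `+`)
  list(roi = r2 < r_roi^2, interior = r2 < r_interior^2)
}

# ---- study-scale fixtures, built once per test session --------------------

.study <- new.env(parent = emptyenv())

study_size <- function() 256L

study_geometry <- function() {
  if (is.null(.study$geometry)) {
    .study$geometry <- default_geometry(study_size(), n_angles = 180)
  }
  .study$geometry
}

study_matrix <- function() {
  if (is.null(.study$matrix)) {
    .study$matrix <- build_system_matrix(study_geometry(), study_size())
  }
  .study$matrix
}

study_phantom <- function() {
  if (is.null(.study$phantom)) {
    .study$phantom <- list(
      spec = default_abdomen_spec(),
      truth = render_phantom(default_abdomen_spec(), study_size()))
  }
  .study$phantom
}

study_clean_sinogram <- function() {
  if (is.null(.study$clean)) {
    .study$clean <- forward_project(hu_to_mu(study_phantom()$truth),
                                    study_matrix())
  }
  .study$clean
}

study_counts_ni24 <- function() {
  if (is.null(.study$counts24)) {
    .study$counts24 <- calibrate_counts(24, study_geometry(), study_size(),
                                        seed = 20240601L)
  }
  .study$counts24
}

study_rois <- function(margin_px = 5) {
  spec <- study_phantom()$spec
  labs <- c("liver", "gallbladder", "fat")
  out <- lapply(labs, function(l) {
    roi(erode_mask(region_mask(spec, l, study_size()), margin_px), l)
  })
  names(out) <- labs
  out
}

# ---- minimal explicit-VR little-endian DICOM writer (test fixture) --------

dcm_bytes_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
dcm_bytes_u32 <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256,
           (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0x20))
  head <- c(dcm_bytes_u16(group), dcm_bytes_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_bytes_u32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_bytes_u16(length(value_raw)), value_raw)
  }
}

# writes a single-frame unsigned 16-bit CT slice; `stored` is a matrix of
# stored pixel values (row 1 = top of image)
write_synthetic_dicom <- function(path, stored, pixel_spacing = 1,
                                  slope = 1, intercept = -1024) {
  rows <- nrow(stored); cols <- ncol(stored)
  pix <- as.integer(t(stored))  # DICOM pixel data is row-major
  pix_raw <- writeBin(pix, raw(), size = 2, endian = "little")
  body <- c(
    dcm_element(0x0028, 0x0010, "US", dcm_bytes_u16(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_bytes_u16(cols)),
    dcm_element(0x0028, 0x0030, "DS",
                charToRaw(sprintf("%g\\%g", pixel_spacing, pixel_spacing))),
    dcm_element(0x0028, 0x0100, "US", dcm_bytes_u16(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_bytes_u16(0)),
    dcm_element(0x0028, 0x1052, "DS", charToRaw(sprintf("%g", intercept))),
    dcm_element(0x0028, 0x1053, "DS", charToRaw(sprintf("%g", slope))),
    dcm_element(0x7FE0, 0x0010, "OW", pix_raw))
  con <- file(path, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  close(con)
  invisible(path)
}
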