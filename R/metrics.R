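#' Region of interest on an image grid
#'
#' @param mask logical matrix, `TRUE` inside the region; must contain at
#'   least 4 pixels so that the noise SD is meaningful.
#' @param label region name used in reports.
#' @return object of class `ct_roi`.
#' @export
roi <- function(mask, label = "roi") {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (sum(mask) < 4) {
    stop("roi: mask must contain at least 4 pixels", call. = FALSE)
  }
  structure(list(mask = mask, label = as.character(label)), class = "ct_roi")
}

#' Erode a binary mask
#'
#' Peels `px` one-pixel layers off a logical mask (4-neighbour erosion).
#' Used to place measurement ROIs a safe margin inside a region, the way a
#' radiologist positions an ROI away from organ boundaries so that edge
#' gradients and Gibbs ringing do not contaminate the noise estimate.
#'
#' @param mask logical matrix.
#' @param px number of layers to remove (>= 0).
#' @return logical matrix of the same shape.
#' @export
erode_mask <- function(mask, px) {
  m <- as.matrix(mask)
  storage.mode(m) <- "logical"
  for (i in seq_len(max(0, px))) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    m <- m & up & dn & lf & rt
  }
  m
}

check_roi_image <- function(image, r) {
  stopifnot(inherits(image, "image_grid"), inherits(r, "ct_roi"))
  if (!all(dim(r$mask) == dim(image$pixels))) {
    stop("ROI mask shape does not match the image", call. = FALSE)
  }
  if (image$value_kind != "HU") {
    stop("ROI statistics are defined on HU images", call. = FALSE)
  }
}

#' CT value (mean HU) of a region of interest
#'
#' @param image an [image_grid()] in HU.
#' @param r a [roi()].
#' @return arithmetic mean of the HU values inside the ROI.
#' @export
roi_ct_value <- function(image, r) {
  check_roi_image(image, r)
  vals <- image$pixels[r$mask]
  if (length(vals) == 0) stop("roi_ct_value: empty ROI", call. = FALSE)
  mean(vals)
}

#' SD value (noise) of a region of interest
#'
#' Sample standard deviation (n - 1 denominator, the scanner-console
#' convention) of the HU values inside the ROI.
#'
#' @inheritParams roi_ct_value
#' @return standard deviation in HU.
#' @export
roi_sd_value <- function(image, r) {
  check_roi_image(image, r)
  vals <- image$pixels[r$mask]
  if (length(vals) < 2) {
    stop("roi_sd_value: ROI too small for a standard deviation", call. = FALSE)
  }
  stats::sd(vals)
}

#' Signal-to-noise ratio of an ROI measurement
#'
#' `SNR = CT value / SD value`. Full precision is returned; reports round
#' to 2 decimals.
#'
#' @param ct_value mean HU of the region.
#' @param sd_value noise SD in HU (> 0).
#' @return unitless SNR.
#' @export
snr <- function(ct_value, sd_value) {
  if (any(sd_value <= 0)) {
    stop("snr: sd_value must be positive", call. = FALSE)
  }
  ct_value / sd_value
}

shift_mask <- function(mask, dy, dx) {
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  rows <- which(mask, arr.ind = TRUE)
  rr <- rows[, 1] + dy
  cc <- rows[, 2] + dx
  if (any(rr < 1 | rr > n | cc < 1 | cc > m)) {
    stop("measure_roi_repeated: jittered ROI falls outside the image",
         call. = FALSE)
  }
  out[cbind(rr, cc)] <- TRUE
  out
}

#' Repeated (jittered) ROI measurement
#'
#' Emulates the clinical practice of measuring each ROI several times and
#' averaging: the ROI is re-placed `repeats` times with seeded integer-pixel
#' jitter, CT and SD are computed for each placement, their means are
#' reported, and the SNR is recomputed as mean-CT / mean-SD.
#'
#' @param image an [image_grid()] in HU.
#' @param r a [roi()].
#' @param repeats number of placements (default 3, the usual triplicate).
#' @param jitter maximum absolute shift in pixels per axis (0 reproduces a
#'   single measurement exactly).
#' @param seed seed for the jitter draws.
#' @return object of class `roi_stats`: list with `ct_value`, `sd_value`,
#'   `snr`, `label`, `repeats`.
#' @export
measure_roi_repeated <- function(image, r, repeats = 3, jitter = 1,
                                 seed = 1L) {
  check_roi_image(image, r)
  if (repeats < 1) stop("measure_roi_repeated: repeats must be >= 1",
                        call. = FALSE)
  offsets <- if (jitter > 0) {
    with_private_rng(seed, {
      cbind(sample(-jitter:jitter, repeats, replace = TRUE),
            sample(-jitter:jitter, repeats, replace = TRUE))
    })
  } else {
    matrix(0L, repeats, 2)
  }
  cts <- numeric(repeats)
  sds <- numeric(repeats)
  for (i in seq_len(repeats)) {
    m <- if (all(offsets[i, ] == 0)) r$mask else
      shift_mask(r$mask, offsets[i, 1], offsets[i, 2])
    ri <- roi(m, r$label)
    cts[i] <- roi_ct_value(image, ri)
    sds[i] <- roi_sd_value(image, ri)
  }
  ct <- mean(cts); sd_ <- mean(sds)
  structure(
    list(ct_value = ct, sd_value = sd_, snr = snr(ct, sd_),
         label = r$label, repeats = repeats),
    class = "roi_stats"
  )
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> %s: CT %.2f HU, SD %.2f HU, SNR %.2f (%d repeat(s))\n",
              x$label, x$ct_value, x$sd_value, x$snr, x$repeats))
  invisible(x)
}

#' Tabulated ROI statistics for several reconstructions
#'
#' Measures every supplied ROI on every reconstruction and returns one row
#' per (method, ROI) pair, the layout used to compare reconstruction
#' algorithms on the same scan.
#'
#' @param images named list of [image_grid()] objects (all the same shape),
#'   e.g. `list(fbp = ..., asir = ...)`.
#' @param rois named list of [roi()] objects.
#' @param repeats,jitter,seed passed to [measure_roi_repeated()]; with the
#'   default `jitter = 0` each ROI is measured once in place.
#' @return data frame with columns `method`, `roi`, `ct_hu`, `sd_hu`, `snr`
#'   (full precision; [write_comparison_csv()] rounds for reporting).
#' @export
compare_reconstructions <- function(images, rois, repeats = 1, jitter = 0,
                                    seed = 1L) {
  stopifnot(length(images) >= 1, length(rois) >= 1)
  dims <- lapply(images, function(im) dim(im$pixels))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("compare_reconstructions: images must share one shape", call. = FALSE)
  }
  rows <- list()
  for (m in names(images)) {
    for (rn in names(rois)) {
      st <- measure_roi_repeated(images[[m]], rois[[rn]],
                                 repeats = repeats, jitter = jitter,
                                 seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, roi = rn, ct_hu = st$ct_value, sd_hu = st$sd_value,
        snr = st$snr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a comparison table as CSV
#'
#' Values are rounded to 2 decimals (the reporting precision); an optional
#' provenance comment line (config hash, seed) is prepended. Read back with
#' `read.csv(..., comment.char = "#")`.
#'
#' @param table data frame from [compare_reconstructions()].
#' @param path output file.
#' @param provenance optional single comment string.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(table, path, provenance = NULL) {
  out <- table
  for (col in c("ct_hu", "sd_hu", "snr")) {
    if (col %in% names(out)) out[[col]] <- round(out[[col]], 2)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
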