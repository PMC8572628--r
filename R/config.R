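# Plain-text (YAML) run configuration for the comparison pipeline.

default_run_config_list <- function() {
  list(
    phantom = "default",
    size = 256L,
    geometry = list(n_angles = 180L, n_detectors = NULL,
                    detector_spacing = NULL, field_of_view = 220),
    noise = list(noise_index = 24, seed = 1L, incident_counts = NULL),
    fbp = list(filter_window = "hann"),
    iter = list(max_iterations = 50L, tolerance = 1e-4, relaxation = 1,
                blend_fraction = 1, init_mode = "zero"),
    rois = c("liver", "gallbladder", "fat"),
    roi_margin_mm = 4,
    repeats = 3L,
    jitter = 1L,
    mu_water = 0.02,
    scanner = list(kv = 120, mas = 150, matrix = 512L,
                   slice_thickness_mm = 0.625),
    output_dir = NULL
  )
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults)) {
      stop(sprintf("load_config: unknown key '%s'", here), call. = FALSE)
    }
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k != "phantom") {
      if (!is.list(user[[k]])) {
        stop(sprintf("load_config: '%s' must be a mapping", here),
             call. = FALSE)
      }
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], here)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

phantom_from_config <- function(ph) {
  if (identical(ph, "default") || is.null(ph)) {
    return(default_abdomen_spec())
  }
  if (inherits(ph, "phantom_spec")) return(ph)
  if (is.character(ph) && length(ph) == 1 && file.exists(ph)) {
    return(read_phantom_spec(ph))
  }
  if (is.list(ph)) {
    ells <- lapply(ph$ellipses, function(e) {
      do.call(ellipse, e)
    })
    return(phantom_spec(
      ells,
      field_of_view = if (is.null(ph$field_of_view)) 220 else ph$field_of_view,
      background_hu = if (is.null(ph$background_hu)) -1000 else ph$background_hu))
  }
  stop("load_config: 'phantom' must be \"default\", a file path, or an ellipse list",
       call. = FALSE)
}

validate_run_config <- function(cfg) {
  if (cfg$size < 8) {
    stop("load_config: 'size' must be at least 8", call. = FALSE)
  }
  g <- cfg$geometry
  if (!is.null(g$field_of_view) && g$field_of_view <= 0) {
    stop("load_config: 'geometry.field_of_view' must be positive",
         call. = FALSE)
  }
  if (g$n_angles < 1) {
    stop("load_config: 'geometry.n_angles' must be >= 1", call. = FALSE)
  }
  if (cfg$noise$noise_index < 0) {
    stop("load_config: 'noise.noise_index' must be >= 0", call. = FALSE)
  }
  if (!cfg$fbp$filter_window %in% c("ramp", "hann", "hamming")) {
    stop("load_config: 'fbp.filter_window' must be ramp, hann or hamming",
         call. = FALSE)
  }
  # constructing the sub-configs applies their own invariants
  do.call(iter_config, cfg$iter)
  invisible(cfg)
}

#' Build a validated run configuration
#'
#' Programmatic equivalent of [load_config()]: any subset of the
#' configuration keys may be supplied and the rest are filled with
#' defaults. Defaults encode the simulated acquisition: a 220 mm field of
#' view, 180 views on a 256-pixel grid, noise index 24, Hann-filtered FBP,
#' a 50-iteration cold-start iterative reconstruction with relaxation 1 and
#' blend fraction 1, and ROIs measured 3 times with 1-pixel jitter on
#' region masks eroded by a 4 mm margin (`roi_margin_mm`). Scanner metadata (120 kV, 150 mAs, 512 matrix,
#' 0.625 mm slices) is carried for provenance only; no dose physics is
#' attached to it.
#'
#' @param ... configuration keys overriding the defaults (see
#'   [load_config()] for the schema).
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_run_config_list(), user)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a plain-text (YAML) file
#'
#' An empty file yields the full default configuration. Unknown keys are
#' rejected with the offending key path named. The schema mirrors
#' [run_config()]:
#'
#' ```yaml
#' phantom: default            # or a spec file path, or an inline spec:
#' #  phantom:
#' #    field_of_view: 220
#' #    background_hu: -1000
#' #    ellipses:
#' #      - {center_x: 0, center_y: 0, semi_axis_a: 80, semi_axis_b: 60,
#' #         rotation: 0, hu_value: 40, label: body}
#' size: 256
#' geometry: {n_angles: 180, field_of_view: 220}
#' noise: {noise_index: 24, seed: 1}
#' fbp: {filter_window: hann}
#' iter: {max_iterations: 50, tolerance: 1.0e-4, relaxation: 1.0,
#'        blend_fraction: 1.0, init_mode: zero}
#' rois: [liver, gallbladder, fat]
#' roi_margin_mm: 4
#' repeats: 3
#' jitter: 1
#' output_dir: out
#' ```
#'
#' @param path YAML file.
#' @return object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("load_config: no such file '%s'", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config_list(), user)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Round-trip a phantom specification through a plain-text file
#'
#' The on-disk form is YAML with `field_of_view`, `background_hu` and an
#' `ellipses` list whose entries carry the [ellipse()] fields.
#'
#' @param spec a [phantom_spec()].
#' @param path file to write / read.
#' @return `path` (write) or a [phantom_spec()] (read).
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  obj <- list(
    field_of_view = spec$field_of_view,
    background_hu = spec$background_hu,
    ellipses = lapply(spec$ellipses, function(e) {
      list(center_x = e$center_x, center_y = e$center_y,
           semi_axis_a = e$semi_axis_a, semi_axis_b = e$semi_axis_b,
           rotation = e$rotation, hu_value = e$hu_value, label = e$label)
    }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  phantom_spec(
    lapply(obj$ellipses, function(e) do.call(ellipse, e)),
    field_of_view = obj$field_of_view,
    background_hu = obj$background_hu)
}

# deterministic FNV-1a hash of a configuration (provenance stamping);
# output_dir is excluded: it does not affect what is computed
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$output_dir <- NULL
  s <- paste(deparse(cfg), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
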