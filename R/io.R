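#' Read a 3D/4D NIfTI volume as a concentration image
#'
#' Voxel spacing (mm) and the frame interval (s) are taken from the NIfTI
#' pixdim field unless overridden.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param frame_interval Optional frame-interval override in seconds.
#' @param spacing Optional length-3 spacing override in mm.
#' @return A [conc_image()].
#' @export
read_image_4d <- function(path, frame_interval = NULL, spacing = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 3L || length(d) > 4L)
    stop(sprintf("expected a 3D or 4D volume, got %d dimensions", length(d)))
  pd <- RNifti::pixdim(img)
  if (is.null(spacing)) {
    spacing <- pd[1:3]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("voxel spacing missing from the NIfTI header; pass `spacing`")
  }
  if (is.null(frame_interval)) {
    frame_interval <- if (length(d) == 4L && length(pd) >= 4L) pd[4] else 1
    if (!is.finite(frame_interval) || frame_interval <= 0)
      stop("frame interval missing from the NIfTI header; pass `frame_interval`")
  }
  a <- array(as.numeric(img), dim = d)
  conc_image(a, spacing = spacing, frame_interval = frame_interval)
}

#' Write a concentration image (or plain array) as NIfTI
#'
#' @param img A [conc_image()] or numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing,frame_interval Used when `img` is a plain array.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, spacing = c(1, 1, 1), frame_interval = 1) {
  if (inherits(img, "conc_image")) {
    spacing <- img$spacing
    frame_interval <- img$frame_interval
    img <- img$data
  }
  nii <- RNifti::asNifti(img)
  pd <- if (length(dim(img)) == 4L) c(spacing, frame_interval) else spacing
  RNifti::pixdim(nii) <- pd
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write coefficient / physical maps as per-channel NIfTI volumes
#'
#' One 3D file per channel (`<prefix><channel>.nii.gz`), plus
#' `<prefix>valid.nii.gz`, and residual/condition maps where present.
#'
#' @param maps A [fit_volume()] or [coefficients_to_physical()] result.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the written file paths.
#' @export
write_maps <- function(maps, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- maps$maps
  channels$valid <- maps$valid * 1
  if (!is.null(maps$residual)) channels$residual <- maps$residual
  if (!is.null(maps$cond)) channels$cond <- maps$cond
  spacing <- if (!is.null(maps$spacing)) maps$spacing else c(1, 1, 1)
  paths <- vapply(names(channels), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".nii.gz"))
    write_image(channels[[nm]], p, spacing = spacing)
    p
  }, character(1))
  invisible(paths)
}

#' Write a vascular input function as a two-column CSV
#'
#' @param vif A [vif_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vif <- function(vif, path) {
  utils::write.csv(data.frame(time_s = vif$times, concentration = vif$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a vascular input function from a two-column CSV
#' @param path CSV with time (s) and concentration columns.
#' @return A [vif_series()].
#' @export
read_vif <- function(path) {
  df <- utils::read.csv(path)
  vif_series(df[[1]], df[[2]])
}

#' Default run configuration
#'
#' Nested list of every tunable the pipeline uses, suitable for YAML
#' round-tripping: grid geometry, phantom scenarios, noise sweep, basis
#' hyperparameters, fitting options and acquisition constants.
#'
#' @return A named list (class `lcfr_config`).
#' @export
default_config <- function() {
  structure(list(
    grid = list(nx = 64L, ny = 64L, dx = 1, dy = 1, dt = 0.125,
                n_steps = 192L, save_stride = 4L, z_slices = 5L),
    scenarios = list(
      divergent = list(D = 0.75, speed = sqrt(2) / 2, bolus_radius = 8),
      poiseuille = list(D = 0.75, u_max = 2.5, half_width = 32,
                        bolus_radius = 8),
      tofts = list(ktrans = c(0.1, 0.2, 0.4, 1), ve = 0.5, vp = 0.05,
                   dt = 3.75, n_frames = 50L,
                   vif = list(t0 = 20, alpha = 3, beta = 10, recirc = 0.25))
    ),
    noise = list(levels = 10^seq(-5, -1, length.out = 5), n_instantiations = 10L,
                 base_seed = 1L),
    basis = list(spatial_half_width = 4L, temporal_half_width = 3L,
                 degrees = c(4L, 4L, 3L, 3L)),
    fit = list(trim = 0L, rcond_tol = 1e-10, ridge = 0,
               enhance_frac = 0.05),   # trim 0 = automatic (half-support + 1)
    acquisition = list(r1 = 3.7, tr = 0.0093, flip_angle = 15,
                       frame_interval = 6, hematocrit = 0.45,
                       n_baseline = 6L),
    output_dir = "lcfr-results"
  ), class = "lcfr_config")
}

#' Save / load a run configuration as YAML
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg`; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param cfg A configuration list (see [default_config()]).
#' @param path YAML file path.
#' @return `save_config` invisibly returns `path`; `load_config` returns the
#'   configuration merged over the defaults.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- unclass(default_config())
  merge_into <- function(base, new, where = "") {
    for (nm in names(new)) {
      if (!nm %in% names(base))
        stop(sprintf("unknown configuration key '%s%s'", where, nm))
      if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge_into(base[[nm]], new[[nm]],
                                 paste0(where, nm, "."))
      else base[[nm]] <- new[[nm]]
    }
    base
  }
  structure(merge_into(base, raw), class = "lcfr_config")
}

config_hash <- function(cfg) {
  # stable content hash without extra dependencies
  txt <- yaml::as.yaml(unclass(cfg))
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997)) %% .Machine$integer.max)
}
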