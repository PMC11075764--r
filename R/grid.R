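#' Simulation grid specification
#'
#' Defines the regular 2D spatial grid and explicit time stepping used by the
#' forward phantom simulators. Physical coordinates are cell-centred with the
#' origin mid-domain, so a 64 x 64 grid at 1 mm spacing spans x, y in
#' (-31.5, 31.5) mm.
#'
#' @param nx,ny Number of voxels along x and y (>= 8).
#' @param dx,dy Voxel spacing in mm (> 0).
#' @param dt Simulation time step in seconds (> 0).
#' @param n_steps Number of explicit time steps (>= 2).
#' @param save_stride Keep every `save_stride`-th step in the saved output
#'   (the initial condition is always frame 1).
#' @return An object of class `lcfr_grid`.
#' @examples
#' g <- lcfr_grid(nx = 64, ny = 64, dt = 0.125, n_steps = 192)
#' range(grid_coords(g)$x)
#' @export
lcfr_grid <- function(nx = 64L, ny = 64L, dx = 1, dy = 1, dt = 0.125,
                      n_steps = 192L, save_stride = 1L) {
  stopifnot(dx > 0, dy > 0, dt > 0)
  if (nx < 8 || ny < 8) stop("grid must be at least 8 x 8 voxels")
  if (n_steps < 2) stop("n_steps must be >= 2")
  save_stride <- as.integer(save_stride)
  stopifnot(save_stride >= 1)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy,
                 dt = dt, n_steps = as.integer(n_steps),
                 save_stride = save_stride),
            class = "lcfr_grid")
}

#' Physical cell-centre coordinates of a grid
#'
#' @param grid An [lcfr_grid()].
#' @return A list with numeric vectors `x` and `y` (mm), centred on zero.
#' @export
grid_coords <- function(grid) {
  list(x = (seq_len(grid$nx) - (grid$nx + 1) / 2) * grid$dx,
       y = (seq_len(grid$ny) - (grid$ny + 1) / 2) * grid$dy)
}

#' @export
print.lcfr_grid <- function(x, ...) {
  cat(sprintf("<lcfr_grid> %d x %d voxels, dx = %g mm, dy = %g mm, dt = %g s, %d steps (stride %d)\n",
              x$nx, x$ny, x$dx, x$dy, x$dt, x$n_steps, x$save_stride))
  invisible(x)
}

#' 4D concentration image container
#'
#' The central data object: a contrast-concentration field c(x, y, z, t) with
#' physical voxel spacing (mm) and a frame interval (s).
#'
#' @param data A 4D numeric array ordered (x, y, z, t). 3D arrays are promoted
#'   to a single time frame.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param frame_interval Time between saved frames in seconds.
#' @param time_origin Acquisition time of the first frame in seconds.
#' @return An object of class `conc_image`.
#' @export
conc_image <- function(data, spacing = c(1, 1, 1), frame_interval = 1,
                       time_origin = 0) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must be a 3D or 4D array")
  stopifnot(length(spacing) == 3L, all(spacing > 0), frame_interval > 0)
  structure(list(data = data, spacing = as.numeric(spacing),
                 frame_interval = as.numeric(frame_interval),
                 time_origin = as.numeric(time_origin)),
            class = "conc_image")
}

#' @export
print.conc_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<conc_image> %d x %d x %d voxels, %d frames | spacing %s mm, frame interval %g s\n",
              d[1], d[2], d[3], d[4], paste(signif(x$spacing, 4), collapse = " x "),
              x$frame_interval))
  invisible(x)
}

#' Frame acquisition times of a concentration image
#' @param img A [conc_image()].
#' @return Numeric vector of frame times in seconds.
#' @export
frame_times <- function(img) {
  img$time_origin + (seq_len(dim(img$data)[4]) - 1L) * img$frame_interval
}

as_image_data <- function(x) {
  if (inherits(x, "conc_image")) x$data
  else if (is.array(x) && length(dim(x)) == 4L) x
  else stop("expected a conc_image or 4D array")
}

#' Vascular input function time course
#'
#' @param times Sample times in seconds.
#' @param values Concentration values (mM or a.u.), same length as `times`.
#' @param bat Bolus-arrival time in seconds (may be `NA` before estimation).
#' @param n_voxels Number of voxels averaged into the curve (provenance).
#' @return An object of class `vif_series`.
#' @export
vif_series <- function(times, values, bat = NA_real_, n_voxels = NA_integer_) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (!is.na(bat) && (bat < min(times) || bat > max(times)))
    stop("bolus-arrival time lies outside the sampled time range")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 bat = bat, n_voxels = n_voxels),
            class = "vif_series")
}

#' @export
print.vif_series <- function(x, ...) {
  cat(sprintf("<vif_series> %d samples over %g s, peak %.4g, BAT %s s\n",
              length(x$times), diff(range(x$times)), max(x$values),
              ifelse(is.na(x$bat), "unknown", format(x$bat))))
  invisible(x)
}
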