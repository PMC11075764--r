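#' Acquisition parameters for DCE-MRI conversion
#'
#' @param r1 Contrast-agent relaxivity in 1/s/mM (> 0). Named presets are
#'   available via [relaxivity_presets()].
#' @param tr Repetition time in seconds.
#' @param flip_angle Dynamic-series flip angle in degrees.
#' @param frame_interval Dynamic frame interval in seconds.
#' @param hematocrit Hematocrit fraction used for the vascular-input
#'   partial-volume scaling (scale factor `1 / (1 - hematocrit)`).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(r1 = 3.7, tr = 0.0093, flip_angle = 15,
                               frame_interval = 6, hematocrit = 0.45) {
  stopifnot(r1 > 0, tr > 0, flip_angle > 0, frame_interval > 0,
            hematocrit >= 0, hematocrit < 1)
  structure(list(r1 = r1, tr = tr, flip_angle = flip_angle,
                 frame_interval = frame_interval, hematocrit = hematocrit),
            class = "acquisition_params")
}

#' Gadolinium relaxivity presets
#'
#' Field-strength-specific longitudinal relaxivities for gadobutrol
#' (Gadovist): 3.7 1/s/mM at 3 T and 3.3 1/s/mM at 7 T.
#'
#' @return A named numeric vector (1/s/mM).
#' @export
relaxivity_presets <- function() c(gadovist_3T = 3.7, gadovist_7T = 3.3)

#' Spoiled gradient-echo steady-state signal
#'
#' `S = S0 (1 - E) sin(a) / (1 - cos(a) E)` with `E = exp(-TR / T1)`: the
#' forward signal model inverted by both the T1 mapping and the
#' concentration conversion.
#'
#' @param s0 Equilibrium signal (a.u.).
#' @param t1 Longitudinal relaxation time (s).
#' @param flip_angle Flip angle in degrees.
#' @param tr Repetition time (s).
#' @return Signal intensity, recycled over the inputs.
#' @export
spgr_signal <- function(s0, t1, flip_angle, tr) {
  a <- flip_angle * pi / 180
  E <- exp(-tr / t1)
  s0 * (1 - E) * sin(a) / (1 - cos(a) * E)
}

#' Variable-flip-angle stack
#'
#' @param signals List of 3D arrays (one per flip angle), or a 4D array with
#'   the flip-angle index last.
#' @param flip_angles Flip angles in degrees (>= 2 distinct values).
#' @param tr Repetition time in seconds.
#' @return An object of class `vfa_stack`.
#' @export
vfa_stack <- function(signals, flip_angles, tr) {
  if (is.array(signals) && length(dim(signals)) == 4L)
    signals <- lapply(seq_len(dim(signals)[4]), function(i) signals[, , , i])
  signals <- lapply(signals, function(s) {
    if (is.matrix(s)) dim(s) <- c(dim(s), 1L)
    s
  })
  stopifnot(length(signals) == length(flip_angles), tr > 0)
  if (length(unique(flip_angles)) < 2)
    stop("at least two distinct flip angles are required")
  dm <- dim(signals[[1]])
  for (s in signals)
    if (!identical(dim(s), dm)) stop("all flip-angle volumes must share one shape")
  if (any(vapply(signals, function(s) any(s < 0), logical(1))))
    stop("signals must be nonnegative")
  structure(list(signals = signals, flip_angles = as.numeric(flip_angles),
                 tr = tr, dim = dm),
            class = "vfa_stack")
}

#' Variable-flip-angle T1 mapping
#'
#' Fits the spoiled gradient-echo signal equation per voxel across flip
#' angles. The linearized form regresses `S / sin(a)` on `S / tan(a)`: the
#' slope is `E = exp(-TR / T10)` and the intercept `S0 (1 - E)`. With
#' `method = "nls"` the nonlinear model is refined per voxel starting from the
#' linearized estimate.
#'
#' @param stack A [vfa_stack()].
#' @param method `"linearized"` (default, fully vectorized) or `"nls"`.
#' @return An object of class `relaxation_maps`: `t10` (s), `s0` (a.u.),
#'   `quality` (linearized-fit R^2) and a logical `flag` array marking voxels
#'   where the fit failed (returned as `NA`).
#' @export
fit_t10_vfa <- function(stack, method = c("linearized", "nls")) {
  method <- match.arg(method)
  a <- stack$flip_angles * pi / 180
  n <- length(a)
  dm <- stack$dim
  S <- vapply(stack$signals, as.vector, numeric(prod(dm)))   # nvox x n
  Yv <- sweep(S, 2, sin(a), `/`)
  Xv <- sweep(S, 2, tan(a), `/`)
  xbar <- rowMeans(Xv); ybar <- rowMeans(Yv)
  sxx <- rowSums((Xv - xbar)^2)
  sxy <- rowSums((Xv - xbar) * (Yv - ybar))
  syy <- rowSums((Yv - ybar)^2)
  slope <- sxy / sxx
  bad <- !is.finite(slope) | slope <= 0 | slope >= 1 | sxx == 0
  E <- ifelse(bad, NA_real_, slope)
  t10 <- -stack$tr / log(E)
  s0 <- (ybar - slope * xbar) / (1 - E)
  quality <- ifelse(syy > 0, sxy^2 / (sxx * syy), NA_real_)
  if (method == "nls") {
    # per-voxel nonlinear least-squares refinement of the SPGR model,
    # started from the linearized estimate
    tr <- stack$tr
    angles <- stack$flip_angles
    for (v in which(!bad)) {
      sv <- S[v, ]
      sse <- function(par) {
        if (par[1] <= 0 || par[2] <= 0) return(Inf)
        sum((sv - spgr_signal(par[1], par[2], angles, tr))^2)
      }
      o <- tryCatch(stats::optim(c(s0[v], t10[v]), sse), error = function(e) NULL)
      if (!is.null(o) && all(is.finite(o$par)) &&
          o$value <= sse(c(s0[v], t10[v])) + 1e-12) {
        s0[v] <- o$par[1]; t10[v] <- o$par[2]
      }
    }
    t10[bad] <- NA_real_; s0[bad] <- NA_real_
  }
  shape <- function(v) array(v, dim = dm)
  structure(list(t10 = shape(t10), s0 = shape(s0), quality = shape(quality),
                 flag = shape(bad), tr = stack$tr),
            class = "relaxation_maps")
}

#' Convert a dynamic signal series to contrast concentration
#'
#' Estimates the per-voxel equilibrium signal from the pre-contrast baseline
#' frames and the spoiled gradient-echo equation, inverts the signal model for
#' `T1(t)`, and applies the fast-exchange relaxivity relation
#' `C(t) = (1 / T1(t) - 1 / T10) / r1`. Baseline frames therefore map to
#' concentration ~0 by construction. Signals at or above the SPGR ceiling
#' (non-physical `T1`) are clamped and flagged.
#'
#' @param dyn A [conc_image()]-like 4D signal series (signal units).
#' @param relax A [fit_t10_vfa()] result (or list with a `t10` array).
#' @param acq An [acquisition_params()].
#' @param n_baseline Number of pre-contrast frames averaged for the baseline
#'   (>= 1).
#' @return A [conc_image()] of concentration (mM), with a logical
#'   `clamped` attribute marking flagged voxels/frames.
#' @export
signal_to_concentration <- function(dyn, relax, acq, n_baseline = 6L) {
  dat <- as_image_data(dyn)
  d <- dim(dat)
  stopifnot(n_baseline >= 1, n_baseline <= d[4])
  t10 <- relax$t10
  stopifnot(identical(dim(t10), d[1:3]))
  a <- acq$flip_angle * pi / 180
  E10 <- exp(-acq$tr / t10)
  f10 <- (1 - E10) * sin(a) / (1 - cos(a) * E10)
  sbase <- apply(array(dat[, , , seq_len(n_baseline), drop = FALSE],
                       dim = c(d[1:3], n_baseline)), 1:3, mean)
  s0 <- sbase / f10
  eps <- 1e-12
  sp <- dat / (rep(s0, d[4]) * sin(a))             # normalized signal
  ceiling_hit <- sp >= 1 / cos(a) - eps | sp <= 0
  sp_cl <- pmin(pmax(sp, eps), 1 / cos(a) - 1e-9)
  E1 <- (1 - sp_cl) / (1 - cos(a) * sp_cl)
  E1 <- pmin(pmax(E1, 1e-12), 1 - 1e-12)
  t1t <- -acq$tr / log(E1)
  conc <- (1 / t1t - rep(1 / t10, d[4])) / acq$r1
  fi <- if (inherits(dyn, "conc_image")) dyn$frame_interval else acq$frame_interval
  spc <- if (inherits(dyn, "conc_image")) dyn$spacing else c(1, 1, 1)
  out <- conc_image(conc, spacing = spc, frame_interval = fi)
  attr(out, "clamped") <- ceiling_hit
  out
}

#' Bolus-arrival-time estimation by bilinear regression
#'
#' Restricts the curve to the segment up to its maximum and, for every
#' candidate breakpoint, fits a continuous two-segment linear model (second
#' segment anchored to the first segment's value at the breakpoint) by least
#' squares. The breakpoint minimising the summed squared error is returned;
#' ties break to the earliest candidate.
#'
#' @param values Concentration time course.
#' @param times Sample times in seconds (default: 0, 1, 2, ...).
#' @return A list with `bat` (seconds), `index` (breakpoint sample), `sse`,
#'   `coef` (intercept, pre-slope, post-minus-pre slope change) and `flag`
#'   (`"ok"`, `"monotone_decreasing"` or `"degenerate"`).
#' @export
estimate_bat <- function(values, times = seq_along(values) - 1) {
  stopifnot(length(values) == length(times))
  imax <- which.max(values)
  if (imax == 1L) {
    flag <- if (all(diff(values) <= 0)) "monotone_decreasing" else "degenerate"
    warning("curve peaks at the first sample; returning BAT = 0")
    return(list(bat = times[1], index = 1L, sse = NA_real_,
                coef = c(NA_real_, NA_real_, NA_real_), flag = flag))
  }
  tt <- times[1:imax]; yy <- values[1:imax]
  if (imax < 4L) stop("need at least 4 samples before the curve maximum")
  if (stats::sd(yy) == 0) {
    warning("constant curve; bolus-arrival time undefined")
    return(list(bat = times[1], index = 1L, sse = 0,
                coef = c(yy[1], 0, 0), flag = "degenerate"))
  }
  cand <- 2:(imax - 1L)
  best <- NULL
  for (k in cand) {
    hinge <- pmax(tt - tt[k], 0)
    X <- cbind(1, tt, hinge)
    fit <- stats::lm.fit(X, yy)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12 * max(best$sse, 1)) {
      best <- list(bat = tt[k], index = k, sse = sse,
                   coef = unname(fit$coefficients), flag = "ok")
    }
  }
  best
}

#' Map bolus-arrival times over a volume
#'
#' @param conc A [conc_image()].
#' @param mask Optional 3D logical array of voxels to process.
#' @return A 3D array of BAT in seconds (`NA` outside the mask or where the
#'   curve is degenerate).
#' @export
estimate_bat_map <- function(conc, mask = NULL) {
  dat <- as_image_data(conc)
  d <- dim(dat)
  times <- frame_times(conc)
  out <- array(NA_real_, d[1:3])
  idx <- if (is.null(mask)) seq_len(prod(d[1:3])) else which(mask)
  m <- matrix(dat, nrow = prod(d[1:3]))
  for (v in idx) {
    b <- tryCatch(suppressWarnings(estimate_bat(m[v, ], times)),
                  error = function(e) NULL)
    if (!is.null(b) && b$flag == "ok") out[v] <- b$bat
  }
  out
}

#' Automatic vascular-input-function extraction
#'
#' Selects rapidly enhancing voxels (bolus-arrival time below
#' `bat_threshold` seconds) whose peak enhancement lies in the upper
#' `enhance_quantile` of all voxels, averages their curves, and scales the
#' result by `1 / (1 - hematocrit)` to account for the plasma/whole-blood
#' difference and partial-volume dilution.
#'
#' @param conc A [conc_image()].
#' @param bat_map 3D array from [estimate_bat_map()].
#' @param acq An [acquisition_params()] (supplies the hematocrit).
#' @param bat_threshold Arrival-time cut in seconds (default 10).
#' @param enhance_quantile Peak-enhancement percentile cut (default 0.90).
#' @return A [vif_series()]; its `bat` is re-estimated from the mean curve and
#'   `n_voxels` records how many voxels were averaged.
#' @export
extract_vif <- function(conc, bat_map, acq = acquisition_params(),
                        bat_threshold = 10, enhance_quantile = 0.90) {
  dat <- as_image_data(conc)
  d <- dim(dat)
  stopifnot(identical(dim(bat_map), d[1:3]))
  m <- matrix(dat, nrow = prod(d[1:3]))
  peak <- apply(m, 1, max)
  cut <- stats::quantile(peak, enhance_quantile, names = FALSE)
  cand <- !is.na(bat_map) & as.vector(bat_map) < bat_threshold & peak >= cut
  if (!any(cand))
    stop("no vascular candidate voxels found; relax bat_threshold or enhance_quantile")
  curve <- colMeans(m[cand, , drop = FALSE]) / (1 - acq$hematocrit)
  times <- frame_times(conc)
  bat <- tryCatch(suppressWarnings(estimate_bat(curve, times)$bat),
                  error = function(e) NA_real_)
  vif_series(times, curve, bat = bat, n_voxels = sum(cand))
}

#' Align a vascular input function to a voxel's bolus-arrival time
#'
#' Time-shifts the curve by `voxel_bat - vif$bat` with linear interpolation,
#' padding the left edge with the pre-bolus baseline value and extending the
#' right edge with the final value; the output length is unchanged and its
#' recorded BAT becomes `voxel_bat`.
#'
#' @param vif A [vif_series()] with a known `bat`.
#' @param voxel_bat Target bolus-arrival time in seconds, inside the scan
#'   window.
#' @return A shifted [vif_series()].
#' @export
shift_vif <- function(vif, voxel_bat) {
  if (is.na(vif$bat)) stop("the VIF has no estimated bolus-arrival time")
  stopifnot(voxel_bat >= min(vif$times), voxel_bat <= max(vif$times))
  delta <- voxel_bat - vif$bat
  if (delta == 0) return(vif)
  baseline <- vif$values[1]
  shifted <- stats::approx(vif$times, vif$values, xout = vif$times - delta,
                           rule = 2)$y
  shifted[vif$times - delta < vif$times[1]] <- baseline
  vif_series(vif$times, shifted, bat = voxel_bat, n_voxels = vif$n_voxels)
}
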