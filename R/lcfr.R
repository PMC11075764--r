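#' @title Feature library for localized convolutional function regression
#' @description
#' Assembles the weak-form feature library: the transport model
#' `dc/dt = div(D grad c) - div(u c) + Ktrans VIF - Kep c + vp dVIF/dt`,
#' projected onto a compact test function, becomes a linear model
#' `c~t = Theta Xi` with columns
#' `Theta = [c~xx, c~yy, c~zz, c~x, c~y, c~z, c~, VIF~, VIF~t]`.
#' All spatial/temporal derivatives land on the analytic kernel, never on the
#' noisy data.
#'
#' @param conc A [conc_image()].
#' @param vif A [vif_series()] sampled at the frame times (broadcast over
#'   space), a 4D array of per-voxel (e.g. bolus-arrival-aligned) input
#'   functions, or `NULL` for source-free scenarios.
#' @param tf A [build_test_function()]; its spacings must match `conc`.
#' @param terms Library columns to build. Defaults to the six transport
#'   columns `c("cxx","cyy","czz","cx","cy","cz")` when `vif` is `NULL`, and
#'   to the full nine columns otherwise.
#' @param method Convolution path passed to [convolve_weak()].
#' @return An object of class `library_stack`: named list of convolved feature
#'   fields, the convolved temporal-derivative target, margins and metadata.
#' @export
assemble_library <- function(conc, vif = NULL, tf, terms = NULL,
                             method = "separable") {
  dat <- as_image_data(conc)
  d <- dim(dat)
  sp <- if (inherits(conc, "conc_image")) c(conc$spacing, conc$frame_interval)
        else tf$spacings
  if (max(abs(sp - tf$spacings)) > 1e-9)
    stop("test function was built for different voxel spacings / frame interval")
  term_map <- list(cxx = "xx", cyy = "yy", czz = "zz",
                   cx = "x", cy = "y", cz = "z", c0 = "none",
                   vif0 = "none", vift = "t")
  if (is.null(terms))
    terms <- if (is.null(vif)) c("cxx", "cyy", "czz", "cx", "cy", "cz")
             else names(term_map)
  terms <- match.arg(terms, names(term_map), several.ok = TRUE)
  vdat <- NULL
  if (any(c("vif0", "vift") %in% terms)) {
    if (is.null(vif)) stop("VIF columns requested but no VIF supplied")
    if (inherits(vif, "vif_series")) {
      if (length(vif$values) != d[4])
        stop("VIF length does not match the number of frames")
      vdat <- array(rep(vif$values, each = prod(d[1:3])), dim = d)
    } else {
      vdat <- as_image_data(vif)
      if (!identical(dim(vdat), d)) stop("per-voxel VIF array shape mismatch")
    }
  }
  cols <- lapply(terms, function(tm) {
    src <- if (tm %in% c("vif0", "vift")) vdat else dat
    convolve_weak(src, tf, term_map[[tm]], method = method)$values
  })
  names(cols) <- terms
  target <- convolve_weak(dat, tf, "t", method = method)$values
  structure(list(columns = cols, target = target, terms = terms,
                 dims = d, margins = tf$support, tf = tf,
                 frame_interval = sp[4], spacing = sp[1:3]),
            class = "library_stack")
}

#' @export
print.library_stack <- function(x, ...) {
  cat(sprintf("<library_stack> %s columns [%s] on a %s field\n",
              length(x$columns), paste(x$terms, collapse = ", "),
              paste(x$dims, collapse = " x ")))
  invisible(x)
}

term_units <- c(cxx = "mm^2/s", cyy = "mm^2/s", czz = "mm^2/s",
                cx = "mm/s", cy = "mm/s", cz = "mm/s",
                c0 = "1/s", vif0 = "1/s", vift = "")

# valid frame indices (outside the temporal convolution border)
stack_frames <- function(stack) {
  (stack$margins[4] + 1L):(stack$dims[4] - stack$margins[4])
}

# spatial index ranges of voxels whose 3x3x3 window lies in the
# convolution-valid region, after the Gibbs edge trim
fit_ranges <- function(stack, trim = NULL) {
  d <- stack$dims[1:3]
  if (is.null(trim)) trim <- stack$margins[1:3] + 1L
  trim <- pmax(as.integer(trim), stack$margins[1:3] + 1L)
  lo <- trim + 1L
  hi <- d - trim
  if (any(hi < lo)) stop("no voxels remain after edge trimming")
  list(lo = lo, hi = hi, trim = trim)
}

# truncated-eigendecomposition OLS on equilibrated normal equations
solve_window <- function(XtX, Xty, yty, rcond_tol = 1e-10, ridge = 0) {
  k <- length(Xty)
  dsc <- sqrt(diag(XtX))
  keep <- dsc > max(dsc) * 1e-13
  out <- list(coef = rep(0, k), residual = NA_real_, cond = NA_real_,
              flag = FALSE)
  if (!any(keep) || max(dsc) == 0) {
    out$coef <- rep(NA_real_, k); out$flag <- TRUE
    return(out)
  }
  dk <- dsc[keep]
  A <- XtX[keep, keep, drop = FALSE] / tcrossprod(dk)
  if (ridge > 0) A <- A + diag(ridge, nrow(A))
  b <- Xty[keep] / dk
  eg <- eigen(A, symmetric = TRUE)
  lam <- eg$values
  pos <- lam > rcond_tol * lam[1]
  if (!any(pos)) {
    out$coef <- rep(NA_real_, k); out$flag <- TRUE
    return(out)
  }
  V <- eg$vectors[, pos, drop = FALSE]
  beta_s <- V %*% (crossprod(V, b) / lam[pos])
  beta <- numeric(k)
  beta[keep] <- beta_s / dk
  r2 <- yty - 2 * sum(beta * Xty) + drop(crossprod(beta, XtX %*% beta))
  out$coef <- beta
  out$residual <- sqrt(max(r2, 0))
  out$cond <- sqrt(lam[1] / min(lam[pos]))
  out
}

#' Per-voxel windowed least-squares fit
#'
#' Builds the explicit design matrix by sampling every library column at the
#' 27 positions of the 3x3x3 window centred on `index`, at all
#' convolution-valid frames, and solves the ordinary least-squares problem for
#' the local coefficient vector by rank-revealing QR. Columns that are
#' identically zero within the window (e.g. z-derivatives of z-replicated
#' data) are dropped and reported as zero coefficients; a design that is
#' rank-deficient beyond that is flagged rather than raised as an error.
#'
#' @param stack A [assemble_library()] result.
#' @param index Integer length-3 voxel index (x, y, z).
#' @return A list with `coef` (named coefficient vector), `residual`
#'   (residual norm), `cond` (design condition number) and `flag`
#'   (rank-deficiency indicator).
#' @export
fit_voxel <- function(stack, index) {
  d <- stack$dims
  m <- stack$margins
  index <- as.integer(index)
  if (any(index - 1L < m[1:3] + 1L) || any(index + 1L > d[1:3] - m[1:3]))
    stop("the 3x3x3 window around this voxel leaves the convolution-valid region")
  tidx <- stack_frames(stack)
  ix <- (index[1] - 1L):(index[1] + 1L)
  iy <- (index[2] - 1L):(index[2] + 1L)
  iz <- (index[3] - 1L):(index[3] + 1L)
  X <- vapply(stack$columns,
              function(a) as.vector(a[ix, iy, iz, tidx, drop = FALSE]),
              numeric(27L * length(tidx)))
  y <- as.vector(stack$target[ix, iy, iz, tidx, drop = FALSE])
  k <- ncol(X)
  nrms <- sqrt(colSums(X^2))
  keep <- nrms > max(nrms) * 1e-13
  coef <- rep(0, k); names(coef) <- stack$terms
  if (!any(keep) || max(nrms) == 0)
    return(list(coef = coef + NA_real_, residual = NA_real_,
                cond = NA_real_, flag = TRUE))
  Xk <- X[, keep, drop = FALSE]
  qrx <- qr(Xk)
  if (qrx$rank < ncol(Xk))
    return(list(coef = coef + NA_real_, residual = NA_real_,
                cond = NA_real_, flag = TRUE))
  coef[keep] <- qr.coef(qrx, y)
  sv <- svd(Xk, nu = 0, nv = 0)$d
  list(coef = coef,
       residual = sqrt(sum(qr.resid(qrx, y)^2)),
       cond = sv[1] / sv[length(sv)],
       flag = FALSE)
}

boxsum3 <- function(a3) {
  k <- c(1, 1, 1)
  out <- conv_axis(a3, k, 1L)
  out <- conv_axis(out, k, 2L)
  conv_axis(out, k, 3L)
}

#' Fit the local transport model over a whole volume
#'
#' Applies the 3x3x3-window ordinary least-squares fit at every voxel whose
#' window lies inside the convolution-valid region, after trimming a
#' Gibbs-contaminated edge margin (default: convolution half-support plus one
#' voxel per axis). The windowed Gram matrices are precomputed with box sums,
#' so the per-voxel solve reduces to a k x k symmetric system; the result is
#' identical to calling [fit_voxel()] at every voxel, up to floating-point
#' rounding.
#'
#' @param stack A [assemble_library()] result.
#' @param mask Optional 3D logical array restricting the fitted voxels.
#' @param trim Edge margin (voxels) per spatial axis; scalar or length 3.
#' @param rcond_tol Relative eigenvalue cutoff below which directions of the
#'   (equilibrated) normal matrix are truncated.
#' @param ridge Optional ridge penalty on the equilibrated normal matrix
#'   (default 0: plain ordinary least squares).
#' @return An object of class `coef_maps`: one 3D map per library column, a
#'   residual-norm map, a condition-number map and a validity mask. Invalid
#'   voxels carry `NA`.
#' @export
fit_volume <- function(stack, mask = NULL, trim = NULL, rcond_tol = 1e-10,
                       ridge = 0) {
  d <- stack$dims
  k <- length(stack$columns)
  rng <- fit_ranges(stack, trim)
  tidx <- stack_frames(stack)
  nvox <- prod(d[1:3])
  M <- lapply(stack$columns, function(a) matrix(a, nrow = nvox)[, tidx, drop = FALSE])
  Y <- matrix(stack$target, nrow = nvox)[, tidx, drop = FALSE]
  to3 <- function(v) array(v, dim = d[1:3])
  # box-summed cross products: entry (v) holds sum over the 3x3x3 window and
  # all valid frames of col_i * col_j at v
  G <- vector("list", k * k)
  for (i in seq_len(k)) for (j in i:k) {
    g <- boxsum3(to3(rowSums(M[[i]] * M[[j]])))
    G[[(i - 1) * k + j]] <- g
    G[[(j - 1) * k + i]] <- g
  }
  Gy <- lapply(seq_len(k), function(i) boxsum3(to3(rowSums(M[[i]] * Y))))
  Gyy <- boxsum3(to3(rowSums(Y * Y)))

  sel <- array(FALSE, d[1:3])
  sel[rng$lo[1]:rng$hi[1], rng$lo[2]:rng$hi[2], rng$lo[3]:rng$hi[3]] <- TRUE
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == d[1:3]))
    sel <- sel & mask
  }
  if (!any(sel)) stop("no voxels to fit: mask is empty after edge trimming")
  idx <- which(sel)

  coef <- matrix(NA_real_, nvox, k)
  residual <- cond <- rep(NA_real_, nvox)
  ok <- rep(FALSE, nvox)
  XtX <- matrix(0, k, k)
  for (v in idx) {
    for (i in seq_len(k)) for (j in i:k)
      XtX[i, j] <- XtX[j, i] <- G[[(i - 1) * k + j]][v]
    Xty <- vapply(Gy, function(g) g[v], numeric(1))
    sol <- solve_window(XtX, Xty, Gyy[v], rcond_tol = rcond_tol, ridge = ridge)
    coef[v, ] <- sol$coef
    residual[v] <- sol$residual
    cond[v] <- sol$cond
    ok[v] <- !sol$flag
  }
  maps <- lapply(seq_len(k), function(i) to3(coef[, i]))
  names(maps) <- stack$terms
  structure(list(maps = maps, residual = to3(residual), cond = to3(cond),
                 valid = to3(ok & sel), terms = stack$terms,
                 units = term_units[stack$terms], trim = rng$trim,
                 spacing = stack$spacing),
            class = "coef_maps")
}

#' @export
print.coef_maps <- function(x, ...) {
  cat(sprintf("<coef_maps> %d coefficient maps [%s], %d valid voxels\n",
              length(x$maps), paste(x$terms, collapse = ", "), sum(x$valid)))
  invisible(x)
}

#' Map regression coefficients to physical transport parameters
#'
#' The library is written for the expanded transport PDE, so the fitted
#' coefficients translate directly: axis diffusivities `D_q = xi_D,q`; the
#' velocity is reported as magnitude `|xi_u|` with direction `-xi_u` (the
#' advective term enters as `-u . grad c`; a spatial diffusion gradient is
#' structurally indistinguishable from advection, so `|xi_u| = |grad D - u|`
#' is interpreted as speed); `Ktrans = xi_trans`; plasma fraction
#' `vp = xi_VIF`; and the efflux map `-xi_ep` absorbs `Kep` plus the velocity
#' divergence.
#'
#' @param cm A [fit_volume()] result.
#' @return An object of class `physical_maps` with per-channel 3D maps
#'   (`D_x`, `D_y`, `D_z`, `u_x`, `u_y`, `u_z`, `speed`, `ktrans`, `vp`,
#'   `efflux`, as available), the validity mask and units.
#' @export
coefficients_to_physical <- function(cm) {
  maps <- list()
  units <- character()
  grab <- function(nm) if (nm %in% cm$terms) cm$maps[[nm]] else NULL
  for (ax in c("x", "y", "z")) {
    dmap <- grab(paste0("c", ax, ax))
    if (!is.null(dmap)) { maps[[paste0("D_", ax)]] <- dmap
                          units[paste0("D_", ax)] <- "mm^2/s" }
    umap <- grab(paste0("c", ax))
    if (!is.null(umap)) { maps[[paste0("u_", ax)]] <- -umap
                          units[paste0("u_", ax)] <- "mm/s" }
  }
  ucomp <- maps[intersect(c("u_x", "u_y", "u_z"), names(maps))]
  if (length(ucomp)) {
    maps$speed <- sqrt(Reduce(`+`, lapply(ucomp, function(m) m^2)))
    units["speed"] <- "mm/s"
  }
  if (!is.null(grab("vif0"))) { maps$ktrans <- grab("vif0"); units["ktrans"] <- "1/s" }
  if (!is.null(grab("vift"))) { maps$vp <- grab("vift"); units["vp"] <- "" }
  if (!is.null(grab("c0")))   { maps$efflux <- -grab("c0"); units["efflux"] <- "1/s" }
  structure(list(maps = maps, valid = cm$valid, units = units,
                 residual = cm$residual, cond = cm$cond, trim = cm$trim,
                 spacing = cm$spacing),
            class = "physical_maps")
}

#' @export
print.physical_maps <- function(x, ...) {
  cat(sprintf("<physical_maps> channels [%s], %d valid voxels\n",
              paste(names(x$maps), collapse = ", "), sum(x$valid)))
  invisible(x)
}

broadcast_truth <- function(tr, dm) {
  if (length(tr) == 1L) return(array(tr, dm))
  if (is.matrix(tr)) return(array(tr, dm))       # replicate across z
  stopifnot(identical(dim(tr), dm))
  tr
}

#' Recovery metrics against ground truth
#'
#' Computes, per physical channel with supplied truth, the root-mean-squared
#' error, the median and interquartile range of the relative error (over
#' voxels with nonzero truth), and mean +/- SD of the estimate, over valid
#' (optionally masked) voxels.
#'
#' @param pm A [coefficients_to_physical()] result.
#' @param truth Named list of ground-truth values: scalars, `nx x ny`
#'   matrices (replicated across z) or full 3D arrays, keyed by channel name
#'   (`speed`, `ktrans`, `vp`, ...).
#' @param mask Optional 3D logical array (e.g. an enhancing-tissue mask).
#' @return A tibble with one row per channel.
#' @export
summarize_recovery <- function(pm, truth = NULL, mask = NULL) {
  sel <- pm$valid
  if (!is.null(mask)) sel <- sel & mask
  dm <- dim(pm$valid)
  rows <- lapply(names(pm$maps), function(nm) {
    est <- pm$maps[[nm]][sel]
    out <- tibble::tibble(parameter = nm, units = unname(pm$units[nm]),
                          n = length(est),
                          mean = mean(est), sd = stats::sd(est),
                          rmse = NA_real_, median_rel_err = NA_real_,
                          rel_err_q25 = NA_real_, rel_err_q75 = NA_real_)
    if (!is.null(truth) && nm %in% names(truth)) {
      tr <- broadcast_truth(truth[[nm]], dm)[sel]
      out$rmse <- sqrt(mean((est - tr)^2))
      nz <- tr != 0
      if (any(nz)) {
        rel <- abs(est[nz] - tr[nz]) / abs(tr[nz])
        q <- stats::quantile(rel, c(0.25, 0.5, 0.75), names = FALSE)
        out$median_rel_err <- 100 * q[2]
        out$rel_err_q25 <- 100 * q[1]
        out$rel_err_q75 <- 100 * q[3]
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Enhancing-voxel analysis mask
#'
#' Voxels whose peak concentration over time reaches at least `frac` of the
#' global spatiotemporal maximum: the phantom analogue of the enhancing-lesion
#' region of interest used on clinical data. Relative errors are only
#' meaningful where contrast actually passed.
#'
#' @param conc A [conc_image()].
#' @param frac Fraction of the global maximum (default 0.05).
#' @return A 3D logical array.
#' @export
mask_enhancing <- function(conc, frac = 0.05) {
  dat <- as_image_data(conc)
  d <- dim(dat)
  peak <- array(apply(matrix(dat, nrow = prod(d[1:3])), 1, max), dim = d[1:3])
  peak >= frac * max(dat)
}

default_support <- function(dm, spatial = 5L, temporal = 5L) {
  sz <- function(n) max(1L, min(spatial, (n - 3L) %/% 2L))
  st <- max(1L, min(temporal, (dm[4] - 1L) %/% 2L))
  c(sz(dm[1]), sz(dm[2]), sz(dm[3]), st)
}

#' End-to-end local transport-coefficient recovery
#'
#' Convenience wrapper: builds a test function matched to the image spacing,
#' assembles the weak-form library, fits the local model at every interior
#' voxel, and maps coefficients to physical parameters.
#'
#' @param conc A [conc_image()].
#' @param vif Optional [vif_series()] or per-voxel 4D array (enables the
#'   perfusion columns).
#' @param terms Library columns (see [assemble_library()]).
#' @param support,degrees Test-function half-widths and degrees; by default
#'   the spatial half-width is 5 voxels (shrunk to fit thin axes, e.g. 1 for a
#'   5-slice volume) and the temporal half-width 5 frames, with degrees
#'   (4, 4, 3, 3).
#' @param mask,trim,rcond_tol,ridge Passed to [fit_volume()].
#' @return An object of class `lcfr_fit` with elements `coef`
#'   ([fit_volume()] output), `physical` ([coefficients_to_physical()]),
#'   `tf` and `terms`.
#' @export
recover_transport <- function(conc, vif = NULL, terms = NULL, support = NULL,
                              degrees = c(4L, 4L, 3L, 3L), mask = NULL,
                              trim = NULL, rcond_tol = 1e-10, ridge = 0) {
  dat <- as_image_data(conc)
  if (is.null(support)) support <- default_support(dim(dat))
  tf <- build_test_function(support, degrees,
                            c(conc$spacing, conc$frame_interval))
  stack <- assemble_library(conc, vif = vif, tf = tf, terms = terms)
  cm <- fit_volume(stack, mask = mask, trim = trim, rcond_tol = rcond_tol,
                   ridge = ridge)
  structure(list(coef = cm, physical = coefficients_to_physical(cm),
                 tf = tf, terms = stack$terms),
            class = "lcfr_fit")
}

#' @export
print.lcfr_fit <- function(x, ...) {
  cat("<lcfr_fit>\n")
  print(x$coef)
  print(x$physical)
  invisible(x)
}
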