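#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient maps into a long tibble
#'
#' One row per valid voxel and coefficient, with voxel indices, the physical
#' units of the coefficient, and per-voxel diagnostics.
#'
#' @param x A [fit_volume()] result.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `z`, `term`, `estimate`, `units`,
#'   `residual`, `cond`.
#' @export
tidy.coef_maps <- function(x, ...) {
  idx <- which(x$valid, arr.ind = TRUE)
  resid <- x$residual[x$valid]
  cond <- x$cond[x$valid]
  rows <- lapply(x$terms, function(tm) {
    est <- x$maps[[tm]][x$valid]
    un <- unname(x$units[tm])
    tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3], term = tm,
                   estimate = est, units = un, residual = resid, cond = cond)
  })
  dplyr::bind_rows(rows)
}

#' @export
tidy.lcfr_fit <- function(x, ...) tidy(x$coef, ...)

#' Tidy physical parameter maps into a long tibble
#' @param x A [coefficients_to_physical()] result.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `z`, `parameter`, `estimate`,
#'   `units`.
#' @export
tidy.physical_maps <- function(x, ...) {
  idx <- which(x$valid, arr.ind = TRUE)
  rows <- lapply(names(x$maps), function(nm) {
    est <- x$maps[[nm]][x$valid]
    un <- unname(x$units[nm])
    tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3], parameter = nm,
                   estimate = est, units = un)
  })
  dplyr::bind_rows(rows)
}

#' One-row fit summary
#'
#' @param x An `lcfr_fit` or [fit_volume()] result.
#' @param ... Unused.
#' @return A tibble with the number of fitted voxels, median residual norm,
#'   and median design condition number.
#' @export
glance.coef_maps <- function(x, ...) {
  tibble::tibble(n_valid = sum(x$valid),
                 n_terms = length(x$terms),
                 median_residual = stats::median(x$residual[x$valid]),
                 median_cond = stats::median(x$cond[x$valid]))
}

#' @export
glance.lcfr_fit <- function(x, ...) glance(x$coef, ...)
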