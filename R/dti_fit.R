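#' Fit the diffusion tensor over a whole volume
#'
#' Per-voxel weighted-least-squares estimation with optional
#' iterative-reweighting outlier rejection (see [fit_tensor_robust()] for
#' the single-voxel algorithm; the field fit runs the same scheme in
#' compiled code). Voxels whose robust fit would retain fewer than seven
#' measurements fall back to the plain WLS estimate and are flagged.
#'
#' @param dwi a 4D [as_volume()] `volume4d` of diffusion-weighted signals.
#' @param scheme the matching [gradient_scheme()].
#' @param mask optional logical 3D array: voxels to fit (default: all).
#' @param method `"robust"` (default) or `"wls"`.
#' @param kappa outlier threshold in robust-scale units.
#' @param gm_tuning Geman-McClure tuning constant (see
#'   [fit_tensor_robust()]).
#' @param tol,max_iter convergence controls per voxel.
#' @return Object of class `dti_fit`: tensor elements (`tensors`, 4D with
#'   sixth-dimension order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, units 1e-3 mm^2/s),
#'   `s0`, per-voxel `fallback`/`n_outliers`/`clamped` flags, `grid`.
#' @export
fit_dti <- function(dwi, scheme, mask = NULL, method = c("robust", "wls"),
                    kappa = 6, tol = 1e-6, max_iter = 20L, gm_tuning = 3) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "volume4d"), inherits(scheme, "gradient_scheme"))
  dm <- dim(dwi$data)
  if (length(dm) != 4L) stop("'dwi' must be 4D")
  if (dm[4] != length(scheme$bvals))
    stop("fourth dimension does not match gradient scheme length")
  shp <- dm[1:3]
  nvox <- prod(shp)
  if (is.null(mask)) mask <- array(TRUE, shp)
  if (!all(dim(mask) == shp)) stop("mask shape mismatch")
  X <- tensor_design(scheme)
  check_design(X)
  idx <- which(mask)
  sig <- matrix(dwi$data, nrow = nvox, ncol = dm[4])[idx, , drop = FALSE]
  res <- fit_tensors_batch(t(sig), X, scheme$bvals, method == "robust",
                           kappa, tol, max_iter, gm_tuning)
  tens <- array(NA_real_, c(shp, 6L))
  tmat <- matrix(NA_real_, nvox, 6L)
  tmat[idx, ] <- t(res$beta[2:7, , drop = FALSE])
  tens[] <- tmat
  s0 <- array(NA_real_, shp)
  s0[idx] <- exp(res$beta[1, ])
  fb <- array(0L, shp); fb[idx] <- res$fallback
  no <- array(0L, shp); no[idx] <- res$n_outliers
  cl <- array(0L, shp); cl[idx] <- res$clamped
  structure(list(tensors = tens, s0 = s0, fallback = fb, n_outliers = no,
                 clamped = cl, mask = mask, grid = dwi$grid,
                 method = method, kappa = kappa),
            class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  n <- sum(x$mask)
  cat("<dti_fit> ", n, " voxel(s) fitted (", x$method, ")",
      if (x$method == "robust")
        sprintf(", %d fallback, %d measurement outliers total",
                sum(x$fallback), sum(x$n_outliers)), "\n", sep = "")
  print(x$grid)
  invisible(x)
}

#' @export
summary.dti_fit <- function(object, ...) {
  maps <- eigen_maps(object)
  ok <- !maps$flag & object$mask
  out <- list(n_fitted = sum(object$mask), n_flagged = sum(maps$flag[object$mask]),
              fa = stats::median(maps$fa[ok]), md = stats::median(maps$md[ok]),
              method = object$method)
  class(out) <- "summary.dti_fit"
  out
}

#' @export
print.summary.dti_fit <- function(x, ...) {
  cat(sprintf("dti_fit (%s): %d voxels, %d flagged; median FA %.3f, median MD %.3f (1e-3 mm2/s)\n",
              x$method, x$n_fitted, x$n_flagged, x$fa, x$md))
  invisible(x)
}

#' Scalar maps from a fitted tensor field
#'
#' Per voxel: eigen-decomposition with eigenvalues sorted descending;
#' MD = mean eigenvalue, RD = mean of the two smaller eigenvalues,
#' FA = sqrt(3/2) * sqrt(sum((lambda_i - MD)^2) / sum(lambda_i^2)) (0 when
#' all eigenvalues are 0). Voxels with negative eigenvalues (physically
#' invalid diffusion) or a fit fallback are kept in the maps but flagged;
#' downstream muscle means exclude them.
#'
#' @param fit a [fit_dti()] result.
#' @return Object of class `scalar_maps`: 3D arrays `fa`, `md`, `lambda1`,
#'   `lambda2`, `lambda3`, `rd`, principal direction `v1` (4D), logical
#'   `flag`, and the `grid`.
#' @export
eigen_maps <- function(fit) {
  stopifnot(inherits(fit, "dti_fit"))
  shp <- fit$grid$shape
  nvox <- prod(shp)
  tmat <- matrix(fit$tensors, nrow = nvox, ncol = 6L)
  idx <- which(fit$mask)
  ef <- eigen_field(tmat[idx, , drop = FALSE])
  mk <- function(v) { a <- array(NA_real_, shp); a[idx] <- v; a }
  l1 <- mk(ef$values[, 1]); l2 <- mk(ef$values[, 2]); l3 <- mk(ef$values[, 3])
  maps <- list(fa = mk(ef$fa),
               md = (l1 + l2 + l3) / 3,
               lambda1 = l1, lambda2 = l2, lambda3 = l3,
               rd = (l2 + l3) / 2,
               v1 = {
                 a <- array(NA_real_, c(shp, 3L))
                 m <- matrix(NA_real_, nvox, 3L)
                 m[idx, ] <- ef$v1
                 a[] <- m
                 a
               },
               flag = {
                 f <- array(FALSE, shp)
                 neg <- ef$values[, 3] < 0 | !is.finite(ef$values[, 3])
                 f[idx] <- neg | fit$fallback[idx] > 0L | fit$clamped[idx] > 0L
                 f
               },
               grid = fit$grid)
  class(maps) <- "scalar_maps"
  maps
}

#' @export
print.scalar_maps <- function(x, ...) {
  ok <- !is.na(x$fa) & !x$flag
  cat("<scalar_maps> ", sum(!is.na(x$fa)), " voxel(s), ",
      sum(x$flag & !is.na(x$fa)), " flagged\n", sep = "")
  invisible(x)
}

#' Signal-to-noise ratio map
#'
#' Per voxel: mean non-diffusion-weighted signal divided by the local noise
#' sigma. Voxels with sigma <= 0 are undefined and returned as NA (masked
#' out), never infinite.
#'
#' @param dwi 4D `volume4d` of signals.
#' @param scheme matching [gradient_scheme()]; identifies the b = 0 frames.
#' @param sigma a 3D `volume4d` of local Gaussian noise sigma on the same
#'   grid.
#' @return 3D numeric array of SNR values with attribute `grid`.
#' @export
snr_map <- function(dwi, scheme, sigma) {
  stopifnot(inherits(dwi, "volume4d"), inherits(sigma, "volume4d"))
  stop_if_grid_mismatch(dwi$grid, sigma$grid, "dwi and sigma map")
  b0 <- which(scheme$bvals == 0)
  if (!length(b0)) stop("gradient scheme has no b = 0 measurement")
  shp <- dim(dwi$data)[1:3]
  mean_b0 <- array(rowMeans(matrix(dwi$data[, , , b0, drop = FALSE],
                                   ncol = length(b0))), shp)
  sg <- array(sigma$data, shp)
  snr <- ifelse(sg > 0, mean_b0 / sg, NA_real_)
  snr <- array(snr, shp)
  attr(snr, "grid") <- dwi$grid
  snr
}

# write a scalar map (NA -> 0) as NIfTI; used by the pipeline writers
write_map <- function(map, grid, path) {
  map[!is.finite(map)] <- 0
  write_nifti(as_volume(array(map, grid$shape), grid), path)
}
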