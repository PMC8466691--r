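# Volume-based tractography (VBT): deterministic streamline tracking
# constrained to each muscle volume, visitation-weighted sampling and
# tract properties.

#' Fiber-tracking stop parameters
#'
#' Defaults follow the standard muscle protocol: maximum turning angle 15
#' degrees per step, step size 1.5 mm, FA range 0.1-0.6; streamlines
#' shorter than `min_length` (10 mm) are discarded and integration stops
#' after `max_steps` Euler steps per direction.
#'
#' @param max_angle maximum turning angle between consecutive steps
#'   (degrees, 0 < max_angle < 90).
#' @param step_size Euler step length in mm (> 0).
#' @param fa_min,fa_max FA tracking range, 0 <= fa_min < fa_max <= 1.
#' @param min_length minimum retained streamline arc length (mm).
#' @param max_steps maximum steps per direction.
#' @param seeds_per_voxel seeds per in-mask voxel (1 = voxel centres;
#'   more adds deterministic low-discrepancy offsets within the voxel).
#' @return Object of class `tracking_params`.
#' @export
tracking_params <- function(max_angle = 15, step_size = 1.5, fa_min = 0.1,
                            fa_max = 0.6, min_length = 10, max_steps = 2000L,
                            seeds_per_voxel = 1L) {
  if (!(max_angle > 0 && max_angle < 90)) stop("max_angle must be in (0, 90)")
  if (step_size <= 0) stop("step_size must be positive")
  if (!(fa_min >= 0 && fa_min < fa_max && fa_max <= 1))
    stop("need 0 <= fa_min < fa_max <= 1")
  if (min_length < 0) stop("min_length must be >= 0")
  if (seeds_per_voxel < 1L) stop("seeds_per_voxel must be >= 1")
  structure(list(max_angle = max_angle, step_size = step_size,
                 fa_min = fa_min, fa_max = fa_max, min_length = min_length,
                 max_steps = as.integer(max_steps),
                 seeds_per_voxel = as.integer(seeds_per_voxel)),
            class = "tracking_params")
}

#' @export
print.tracking_params <- function(x, ...) {
  cat(sprintf(paste0("<tracking_params> angle <= %g deg, step %g mm, ",
                     "FA [%g, %g], min length %g mm\n"),
              x$max_angle, x$step_size, x$fa_min, x$fa_max, x$min_length))
  invisible(x)
}

as_mask <- function(mask, label = NULL) {
  if (inherits(mask, "label_map")) {
    if (is.null(label)) mask$labels > 0L else mask$labels == label
  } else if (is.array(mask)) {
    mask > 0
  } else stop("mask must be a label_map or 3D array")
}

# deterministic within-voxel seed offsets (radical-inverse sequence)
seed_offsets <- function(n) {
  if (n == 1L) return(matrix(0, 1L, 3L))
  halton <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
    r
  }
  cbind(vapply(seq_len(n) - 1L, halton, 0, base = 2),
        vapply(seq_len(n) - 1L, halton, 0, base = 3),
        vapply(seq_len(n) - 1L, halton, 0, base = 5)) - 0.5
}

#' Deterministic streamline tractography within a muscle mask
#'
#' Seeds at every in-mask voxel centre whose FA lies in the tracking
#' range; bidirectional Euler integration along the principal eigenvector
#' with per-step sign alignment to the incoming direction. The direction
#' field is obtained by trilinear interpolation of the six tensor
#' components over in-mask voxels (out-of-mask and non-finite neighbours
#' carry no weight), then eigen-decomposition at the interpolated point.
#' A step terminates when the next point would leave the mask, local FA
#' exits the range, the turning angle exceeds `max_angle`, or `max_steps`
#' is reached. Streamlines shorter than `min_length` are discarded.
#'
#' @param fit a [fit_dti()] result.
#' @param mask a [label_map()] (optionally with `label`) or logical 3D
#'   array selecting the muscle volume on the same grid.
#' @param params a [tracking_params()].
#' @param label muscle label when `mask` is a label map.
#' @return Object of class `tract_set`: `streamlines` (list of n x 3
#'   world-mm matrices), per-streamline termination reasons at both ends
#'   (`mask-exit`, `fa-bound`, `angle`, `max-steps`), the `params`, `grid`
#'   and seed bookkeeping.
#' @export
track_muscle <- function(fit, mask, params = tracking_params(), label = NULL) {
  stopifnot(inherits(fit, "dti_fit"), inherits(params, "tracking_params"))
  if (inherits(mask, "label_map"))
    stop_if_grid_mismatch(fit$grid, mask$grid, "tensor field and mask")
  m <- as_mask(mask, label)
  if (!all(dim(m) == fit$grid$shape)) stop("mask shape mismatch")
  shp <- fit$grid$shape
  nvox <- prod(shp)
  tmat <- matrix(fit$tensors, nrow = nvox, ncol = 6L)
  finite <- rowSums(!is.finite(tmat)) == 0L
  mvec <- as.integer(as.vector(m) & finite)
  empty <- structure(list(streamlines = list(),
                          term_start = character(), term_end = character(),
                          seed_voxels = integer(), params = params,
                          grid = fit$grid, n_seed_voxels = sum(mvec)),
                     class = "tract_set")
  if (!any(mvec == 1L)) return(empty)
  idx <- which(mvec == 1L) - 1L
  k <- idx %/% (shp[1] * shp[2])
  j <- (idx %/% shp[1]) %% shp[2]
  i <- idx %% shp[1]
  seeds <- cbind(i, j, k)
  off <- seed_offsets(params$seeds_per_voxel)
  if (nrow(off) > 1L) {
    seeds <- seeds[rep(seq_len(nrow(seeds)), each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = length(idx)), , drop = FALSE]
  }
  res <- track_field(tmat, mvec, as.integer(shp), fit$grid$voxel_size,
                     round(seeds), params$step_size, params$max_angle,
                     params$fa_min, params$fa_max, params$min_length,
                     params$max_steps)
  reasons <- c("mask-exit", "fa-bound", "angle", "max-steps")
  sl <- lapply(res$streamlines, function(p) voxel_to_world(fit$grid, p))
  structure(list(streamlines = sl,
                 term_start = reasons[res$term_start + 1L],
                 term_end = reasons[res$term_end + 1L],
                 seed_voxels = res$seed, params = params, grid = fit$grid,
                 n_seed_voxels = sum(mvec)),
            class = "tract_set")
}

#' @export
print.tract_set <- function(x, ...) {
  n <- length(x$streamlines)
  cat("<tract_set> ", n, " streamline(s) from ", x$n_seed_voxels,
      " seed voxel(s)", sep = "")
  if (n > 0) {
    len <- streamline_lengths(x)
    cat(sprintf("; length %.1f-%.1f mm (mean %.1f)", min(len), max(len),
                mean(len)))
  }
  cat("\n")
  invisible(x)
}

#' Arc lengths of the streamlines in a tract set (mm)
#' @param tracts a `tract_set`.
#' @export
streamline_lengths <- function(tracts) {
  vapply(tracts$streamlines,
         function(p) (nrow(p) - 1L) * tracts$params$step_size, 0)
}

#' Visitation-weighted diffusion metrics along tracts
#'
#' For every streamline point the underlying map value is sampled at the
#' nearest voxel and the muscle metric is the mean over all points of all
#' streamlines. A voxel visited by many tract points therefore contributes
#' with its visitation count — the spatial weighting that distinguishes
#' tract-based from voxel-averaged (MSB) extraction. Non-finite samples
#' are dropped.
#'
#' @param tracts a [track_muscle()] `tract_set`.
#' @param maps a [eigen_maps()] `scalar_maps` object on the same grid.
#' @return One-row data frame with `fa`, `md`, `lambda1`, `rd`,
#'   `n_points`, `n_tracts`; `NULL` (with a warning) for an empty tract
#'   set, mirroring a muscle that cannot be tracked.
#' @export
tract_sample <- function(tracts, maps) {
  stopifnot(inherits(tracts, "tract_set"), inherits(maps, "scalar_maps"))
  stop_if_grid_mismatch(tracts$grid, maps$grid, "tracts and scalar maps")
  if (length(tracts$streamlines) == 0L) {
    warning("empty tract set: no metrics to sample")
    return(NULL)
  }
  pts <- do.call(rbind, tracts$streamlines)
  vox <- round(world_to_voxel(maps$grid, pts))
  shp <- maps$grid$shape
  vox[, 1] <- pmin(pmax(vox[, 1], 0), shp[1] - 1)
  vox[, 2] <- pmin(pmax(vox[, 2], 0), shp[2] - 1)
  vox[, 3] <- pmin(pmax(vox[, 3], 0), shp[3] - 1)
  lin <- 1L + vox[, 1] + shp[1] * (vox[, 2] + shp[2] * vox[, 3])
  smpl <- function(map) {
    v <- map[lin]
    mean(v[is.finite(v)])
  }
  data.frame(fa = smpl(maps$fa), md = smpl(maps$md),
             lambda1 = smpl(maps$lambda1), rd = smpl(maps$rd),
             n_points = nrow(pts), n_tracts = length(tracts$streamlines))
}

#' Tract properties: density, length, volume, pennation angle
#'
#' `vol` is the volume of the (un-eroded) muscle mask in cm^3; `td` the
#' number of retained streamlines per cm^3 of that volume; `mtl` the mean
#' streamline arc length in mm; `mean_angle` the mean over all streamline
#' segments of the angle between the segment and the craniocaudal image
#' axis (+z of the slice stack), in degrees within [0, 90] — the
#' tract-level pennation estimate.
#'
#' @param tracts a [track_muscle()] `tract_set`.
#' @param mask the un-eroded muscle mask: a [label_map()] (with `label`)
#'   or logical array on the tracking grid.
#' @param label muscle label when `mask` is a label map.
#' @return One-row data frame with `td`, `mtl`, `vol`, `mean_angle`,
#'   `n_tracts`.
#' @export
tract_properties <- function(tracts, mask, label = NULL) {
  stopifnot(inherits(tracts, "tract_set"))
  m <- as_mask(mask, label)
  n_mask <- sum(m)
  if (n_mask == 0L) stop("zero-volume muscle mask")
  vol_cm3 <- n_mask * voxel_volume_mm3(tracts$grid) / 1000
  n <- length(tracts$streamlines)
  if (n == 0L)
    return(data.frame(td = 0, mtl = NA_real_, vol = vol_cm3,
                      mean_angle = NA_real_, n_tracts = 0L))
  mtl <- mean(streamline_lengths(tracts))
  zax <- tracts$grid$affine[1:3, 3]
  zax <- zax / sqrt(sum(zax^2))
  seg_angles <- unlist(lapply(tracts$streamlines, function(p) {
    if (nrow(p) < 2L) return(numeric())
    seg <- diff(p)
    cosang <- abs(seg %*% zax) / sqrt(rowSums(seg^2))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }))
  data.frame(td = n / vol_cm3, mtl = mtl, vol = vol_cm3,
             mean_angle = mean(seg_angles), n_tracts = n)
}

#' Full VBT report over all muscles of a label map
#'
#' Runs [track_muscle()], [tract_sample()] and [tract_properties()] per
#' muscle and assembles one table. Muscles with no retained streamline
#' report tract properties only (metrics NA) with a warning.
#'
#' @param fit a [fit_dti()] result.
#' @param labels diffusion-space [label_map()] (un-eroded masks).
#' @param params a [tracking_params()].
#' @param maps optional precomputed [eigen_maps()] of `fit`.
#' @return Data frame of class `tract_report`: one row per muscle with the
#'   weighted metrics and tract properties.
#' @export
vbt_report <- function(fit, labels, params = tracking_params(), maps = NULL) {
  stopifnot(inherits(labels, "label_map"))
  stop_if_grid_mismatch(fit$grid, labels$grid, "tensor field and labels")
  if (is.null(maps)) maps <- eigen_maps(fit)
  rows <- list()
  for (l in labels_present(labels)) {
    tr <- track_muscle(fit, labels, params, label = l)
    props <- tract_properties(tr, labels, label = l)
    metr <- if (length(tr$streamlines) > 0L) tract_sample(tr, maps) else {
      warning(sprintf("muscle '%s' (label %d): no streamlines retained",
                      labels$names[as.character(l)], l))
      data.frame(fa = NA_real_, md = NA_real_, lambda1 = NA_real_,
                 rd = NA_real_, n_points = 0L, n_tracts = 0L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = l, muscle = unname(labels$names[as.character(l)]),
      fa = metr$fa, md = metr$md, lambda1 = metr$lambda1, rd = metr$rd,
      td = props$td, mtl = props$mtl, vol = props$vol,
      mean_angle = props$mean_angle, n_tracts = props$n_tracts)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tract_report", "data.frame")
  out
}
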