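# Manual-segmentation-based (MSB) analysis: mask post-processing, label
# resampling to diffusion space, and voxel-averaged per-muscle metrics.

shift3 <- function(a, d) {
  # shift logical 3D array by integer offset d, padding with FALSE
  out <- array(FALSE, dim(a))
  dm <- dim(a)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq(1 - d[ax], dm[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

neighbour_offsets <- function(connectivity = 6L) {
  if (connectivity == 6L) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else if (connectivity == 26L) {
    g <- expand.grid(-1:1, -1:1, -1:1)
    g <- g[rowSums(abs(g)) > 0, ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  } else stop("connectivity must be 6 or 26")
}

erode_bin <- function(a, connectivity = 6L) {
  out <- a
  for (d in neighbour_offsets(connectivity)) out <- out & shift3(a, d)
  out
}

dilate_bin <- function(a, connectivity = 6L) {
  out <- a
  for (d in neighbour_offsets(connectivity)) out <- out | shift3(a, d)
  out
}

#' Smooth and erode a muscle label map
#'
#' Per label: binary closing (dilation then erosion) with a 3D structuring
#' element as smoothing, followed by erosion by `erosion_voxels` with the
#' same element — the standard guard against partial-volume contamination
#' at muscle boundaries. The closing step never expands a label into a
#' voxel already owned by another label, so disjoint labels stay disjoint.
#' Muscles eroded to zero voxels are dropped with a warning.
#'
#' @param lmap a [label_map()].
#' @param erosion_voxels number of erosion passes after smoothing.
#' @param smooth apply the closing step (default TRUE).
#' @param connectivity 6 (face-connected, default) or 26.
#' @return A [label_map()] on the same grid.
#' @export
smooth_and_erode <- function(lmap, erosion_voxels = 1L, smooth = TRUE,
                             connectivity = 6L) {
  stopifnot(inherits(lmap, "label_map"))
  out <- array(0L, dim(lmap$labels))
  for (l in labels_present(lmap)) {
    bin <- lmap$labels == l
    if (smooth) {
      closed <- dilate_bin(bin, connectivity)
      closed <- closed & (lmap$labels == l | lmap$labels == 0L)
      bin <- erode_bin(closed, connectivity)
    }
    if (erosion_voxels > 0L)
      for (i in seq_len(erosion_voxels)) bin <- erode_bin(bin, connectivity)
    if (!any(bin)) {
      warning(sprintf("muscle '%s' (label %d) eroded to zero voxels; dropped",
                      lmap$names[as.character(l)], l))
      next
    }
    claim <- bin & out == 0L
    out[claim] <- l
  }
  label_map(out, lmap$grid, lmap$names)
}

#' Resample a label map onto another grid
#'
#' Nearest-neighbour assignment: each target voxel centre is mapped through
#' both affines into the source lattice and takes the label of the source
#' voxel whose centre is nearest (labels are categorical; no interpolation).
#' Typical use: anatomical-resolution masks onto the coarser diffusion grid.
#'
#' @param lmap a [label_map()].
#' @param target_grid an [image_grid()] overlapping the source in world
#'   space.
#' @return A [label_map()] on `target_grid`.
#' @export
resample_labels <- function(lmap, target_grid) {
  stopifnot(inherits(lmap, "label_map"))
  if (same_grid(lmap$grid, target_grid)) return(lmap)
  shp <- target_grid$shape
  vox_t <- as.matrix(expand.grid(i = 0:(shp[1] - 1), j = 0:(shp[2] - 1),
                                 k = 0:(shp[3] - 1)))
  world <- voxel_to_world(target_grid, vox_t)
  vox_s <- round(world_to_voxel(lmap$grid, world))
  sshp <- lmap$grid$shape
  inside <- vox_s[, 1] >= 0 & vox_s[, 1] < sshp[1] &
            vox_s[, 2] >= 0 & vox_s[, 2] < sshp[2] &
            vox_s[, 3] >= 0 & vox_s[, 3] < sshp[3]
  if (!any(inside))
    stop("disjoint fields of view: no target voxel centre falls inside the source grid")
  lab <- integer(nrow(vox_t))
  lin <- 1L + vox_s[inside, 1] + sshp[1] * (vox_s[inside, 2] +
                                            sshp[2] * vox_s[inside, 3])
  lab[inside] <- lmap$labels[lin]
  label_map(array(lab, shp), target_grid, lmap$names)
}

#' Voxel-averaged per-muscle diffusion metrics (MSB)
#'
#' Unweighted arithmetic mean of FA, MD, lambda1 and RD over the in-mask
#' voxels of each muscle — each voxel contributes exactly once, in contrast
#' to the visitation weighting of [tract_sample()]. Voxels flagged by the
#' tensor stage (fit fallback, clamped signals, negative eigenvalues) are
#' excluded and counted.
#'
#' @param maps a [eigen_maps()] `scalar_maps` object.
#' @param labels a [label_map()] on the same grid (normally the output of
#'   [smooth_and_erode()] resampled to diffusion space).
#' @return A data frame of class `muscle_metrics`: one row per muscle with
#'   `label`, `muscle`, `fa`, `md`, `lambda1`, `rd`, `n_voxels`,
#'   `n_flagged`.
#' @export
extract_msb <- function(maps, labels) {
  stopifnot(inherits(maps, "scalar_maps"), inherits(labels, "label_map"))
  stop_if_grid_mismatch(maps$grid, labels$grid, "scalar maps and labels")
  rows <- list()
  for (l in labels_present(labels)) {
    in_mask <- labels$labels == l & !is.na(maps$fa)
    ok <- in_mask & !maps$flag
    n_flag <- sum(in_mask) - sum(ok)
    if (!any(ok)) {
      warning(sprintf("muscle '%s' (label %d): no valid voxels; omitted",
                      labels$names[as.character(l)], l))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = l, muscle = unname(labels$names[as.character(l)]),
      fa = mean(maps$fa[ok]), md = mean(maps$md[ok]),
      lambda1 = mean(maps$lambda1[ok]), rd = mean(maps$rd[ok]),
      n_voxels = sum(ok), n_flagged = n_flag)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(), muscle = character(), fa = numeric(),
                      md = numeric(), lambda1 = numeric(), rd = numeric(),
                      n_voxels = integer(), n_flagged = integer())
  class(out) <- c("muscle_metrics", "data.frame")
  out
}

#' Per-muscle and whole-calf fat fraction
#'
#' Per-muscle mean fat fraction on the un-eroded masks; the whole-calf
#' value is the unweighted mean of the per-muscle means (muscles count
#' equally regardless of size), not a voxel-pooled mean.
#'
#' @param ff a 3D `volume4d` (or array) of fat fractions in `[0, 1]`.
#' @param labels a [label_map()] on the same grid (un-eroded masks).
#' @return List with `per_muscle` (data frame `label`, `muscle`, `ff`,
#'   `n_voxels`) and `whole_calf` (scalar).
#' @export
fat_fraction_summary <- function(ff, labels) {
  stopifnot(inherits(labels, "label_map"))
  if (inherits(ff, "volume4d")) {
    stop_if_grid_mismatch(ff$grid, labels$grid, "fat-fraction map and labels")
    ff <- ff$data
  }
  if (!all(dim(ff) == labels$grid$shape)) stop("fat-fraction map shape mismatch")
  if (any(ff < 0 | ff > 1, na.rm = TRUE))
    stop("fat fraction outside [0, 1]")
  rows <- lapply(labels_present(labels), function(l) {
    m <- labels$labels == l
    data.frame(label = l, muscle = unname(labels$names[as.character(l)]),
               ff = mean(ff[m], na.rm = TRUE), n_voxels = sum(m))
  })
  per <- do.call(rbind, rows)
  list(per_muscle = per, whole_calf = mean(per$ff))
}
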