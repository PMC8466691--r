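# Synthetic lower-leg phantom: seven pennate muscle compartments around a
# central bone void, ground-truth tensor field, Rician-noise DWI at a
# configurable SNR, fat-infiltration mixing, and simulated two-rater
# segmentations. Every output carries its ground truth so downstream
# modules always have an oracle.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic calf phantom
#'
#' Defines the acquisition grid, the acquisition scheme, per-muscle fiber
#' architecture and diffusivities, the target b0 SNR, fat fractions and
#' the rater-jitter magnitude. Per-muscle eigenvalues are drawn once (at
#' spec construction, under `seed`) from Gaussians centred on the cohort
#' means so that muscles differ the way a real cohort's do; fat fractions
#' follow the cohort preset (`healthy`: ~0.03-0.05; `nmd`: uniform
#' 0.03-0.78).
#'
#' @param seed RNG seed; fixes every random element of the phantom.
#' @param cohort `"healthy"` or `"nmd"` preset.
#' @param grid_shape,voxel_size acquisition grid (diffusion resolution).
#' @param snr target b0 signal-to-noise ratio inside muscle.
#' @param s0 non-diffusion-weighted muscle signal (arbitrary units).
#' @param lambda1_mean,rd_mean cohort-mean axial and radial diffusivity
#'   (1e-3 mm^2/s); defaults are the healthy-calf group values, `nmd`
#'   switches to the disease-group ones. Per-muscle values are drawn by
#'   sampling mean diffusivity and FA around the centre these imply (MD
#'   and FA are the quantities whose cohort spread group tables report;
#'   sampling the two eigenvalues independently would inflate the FA
#'   spread far beyond observed cohorts) and converting back to an
#'   axially symmetric (lambda1, RD) pair.
#' @param md_sd,fa_sd cohort standard deviations of mean diffusivity
#'   (1e-3 mm^2/s) and FA used for those draws.
#' @param pennation per-muscle pennation angles in degrees (length 7).
#' @param bipennate logical length 7: fiber tilt flips sign across the
#'   muscle's axial mid-plane.
#' @param fat_diffusivity isotropic diffusivity of the fat compartment
#'   (1e-3 mm^2/s).
#' @param rim_voxels thickness (voxels) of a degraded boundary rim inside
#'   each muscle, emulating partial-volume contamination with fascia and
#'   subcutaneous tissue: rim voxels keep the muscle's axial diffusivity
#'   but their radial diffusivity is raised until FA drops to `rim_fa`.
#'   0 (default) disables the rim.
#' @param rim_fa FA of the rim voxels (below the usual tracking range, so
#'   streamlines avoid the rim while voxel averaging does not).
#' @param rater_jitter boundary perturbation magnitude for
#'   [simulate_raters()] (voxels).
#' @param scheme acquisition [gradient_scheme()]; default 17 directions at
#'   b = 400 s/mm^2 plus three b = 0.
#' @return Object of class `phantom_spec` with a `muscles` table holding
#'   the drawn ground-truth parameters.
#' @export
phantom_spec <- function(seed = 1L, cohort = c("healthy", "nmd"),
                         grid_shape = c(64L, 64L, 40L),
                         voxel_size = c(3, 3, 6), snr = 59, s0 = 1000,
                         lambda1_mean = NULL, rd_mean = NULL,
                         md_sd = NULL, fa_sd = NULL,
                         pennation = c(10, 12, 17, 12, 20, 8, 14),
                         bipennate = c(FALSE, FALSE, FALSE, FALSE,
                                       TRUE, TRUE, FALSE),
                         fat_diffusivity = 0.2, rim_voxels = 0L,
                         rim_fa = 0.07, rater_jitter = 1,
                         scheme = default_scheme()) {
  cohort <- match.arg(cohort)
  defs <- if (cohort == "healthy")
    c(l1 = 1.97, rd = 1.39, mdsd = 0.10, fasd = 0.03)
  else
    c(l1 = 1.92, rd = 1.35, mdsd = 0.18, fasd = 0.04)
  if (is.null(lambda1_mean)) lambda1_mean <- defs[["l1"]]
  if (is.null(rd_mean)) rd_mean <- defs[["rd"]]
  if (is.null(md_sd)) md_sd <- defs[["mdsd"]]
  if (is.null(fa_sd)) fa_sd <- defs[["fasd"]]
  if (snr <= 0) stop("snr must be positive")
  nm <- calf_muscle_names()
  # cohort centre in (MD, FA) implied by the mean eigenvalues
  md_mean <- (lambda1_mean + 2 * rd_mean) / 3
  delta0 <- lambda1_mean - rd_mean
  fa_mean <- delta0 / sqrt(3 * md_mean^2 + 2 * delta0^2 / 3)
  muscles <- with_seed(seed, {
    md <- stats::rnorm(7, md_mean, md_sd)
    fa <- pmin(pmax(stats::rnorm(7, fa_mean, fa_sd), 0.05), 0.6)
    # axially symmetric tensor with that MD and FA:
    # lambda1 - RD = FA * MD * sqrt(3 / (1 - 2 FA^2 / 3))
    delta <- fa * md * sqrt(3 / (1 - 2 * fa^2 / 3))
    l1 <- md + 2 * delta / 3
    rd <- md - delta / 3
    ff <- if (cohort == "healthy") stats::runif(7, 0.03, 0.05)
          else stats::runif(7, 0.03, 0.78)
    data.frame(label = 1:7, muscle = unname(nm), lambda1 = l1, rd = rd,
               pennation = pennation, bipennate = bipennate, ff = ff)
  })
  structure(list(seed = as.integer(seed), cohort = cohort,
                 grid = image_grid(grid_shape, voxel_size), snr = snr,
                 s0 = s0, fat_diffusivity = fat_diffusivity,
                 rim_voxels = as.integer(rim_voxels), rim_fa = rim_fa,
                 rater_jitter = rater_jitter, scheme = scheme,
                 muscles = muscles),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s cohort, seed %d, SNR %g\n", x$cohort,
              x$seed, x$snr))
  print(x$grid)
  print(x$muscles[, c("muscle", "lambda1", "rd", "pennation", "ff")],
        digits = 3)
  invisible(x)
}

#' Build the phantom geometry: label map and fiber direction field
#'
#' Seven prismatic angular-sector compartments arranged in an annulus
#' around a central "bone" void, separated by one-voxel fascia gaps and
#' running along the slice axis with an axial margin. Each voxel of a
#' muscle carries a unit fiber direction tilted from the craniocaudal +z
#' axis by the muscle's pennation angle (tilt direction fixed per muscle
#' at its sector azimuth); bipennate muscles flip the tilt sign across the
#' axial mid-plane, emulating a central aponeurosis.
#'
#' @param spec a [phantom_spec()].
#' @return List with `labels` (a [label_map()]) and `fibers` (4D array,
#'   last dimension the xyz direction components; NA outside muscle).
#' @export
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$grid$shape
  vs <- spec$grid$voxel_size
  cx <- (shp[1] - 1) / 2 * vs[1]
  cy <- (shp[2] - 1) / 2 * vs[2]
  x <- (0:(shp[1] - 1)) * vs[1] - cx
  y <- (0:(shp[2] - 1)) * vs[2] - cy
  xm <- matrix(x, shp[1], shp[2])
  ym <- matrix(y, shp[1], shp[2], byrow = TRUE)
  r <- sqrt(xm^2 + ym^2)
  theta <- atan2(ym, xm) %% (2 * pi)
  extent <- min(cx, cy)
  r_in <- 0.22 * extent            # bone void radius
  r_out <- 0.92 * extent
  gap_rad <- 2 * vs[1] / ((r_in + r_out) / 2)  # ~1 voxel fascia gap
  # unequal angular widths: calf muscles differ substantially in volume
  # (soleus and the gastrocnemii dominate), and downstream between-muscle
  # variance should reflect that
  wts <- c(1.2, 1.7, 2.3, 1.4, 3.4, 1.6, 1.3)
  widths <- 2 * pi * wts / sum(wts)
  th_lo <- cumsum(c(0, widths[-7]))
  slab <- array(0L, c(shp[1], shp[2]))
  for (l in 1:7) {
    dth <- (theta - th_lo[l]) %% (2 * pi)
    sel <- r >= r_in & r <= r_out & dth >= gap_rad / 2 &
      dth <= widths[l] - gap_rad / 2
    slab[sel] <- l
  }
  z_margin <- max(1L, round(0.05 * shp[3]))
  labels <- array(0L, shp)
  for (k in (z_margin + 1):(shp[3] - z_margin)) labels[, , k] <- slab
  lmap <- label_map(labels, spec$grid)
  for (l in 1:7)
    if (sum(labels == l) < 8L)
      stop("phantom compartment degenerate; enlarge the grid")
  fibers <- array(NA_real_, c(shp, 3L))
  zc <- (shp[3] - 1) / 2
  kz <- array(rep(0:(shp[3] - 1), each = shp[1] * shp[2]), shp)
  for (l in 1:7) {
    mrow <- spec$muscles[l, ]
    a <- mrow$pennation * pi / 180
    phi <- th_lo[l] + widths[l] / 2        # tilt azimuth: sector middle
    u <- c(cos(phi), sin(phi), 0)
    sel <- labels == l
    sgn <- if (mrow$bipennate) ifelse(kz[sel] <= zc, 1, -1) else 1
    fibers[, , , 1][sel] <- sgn * sin(a) * u[1]
    fibers[, , , 2][sel] <- sgn * sin(a) * u[2]
    fibers[, , , 3][sel] <- cos(a)
  }
  list(labels = lmap, fibers = fibers)
}

# radial diffusivity giving target FA at fixed axial diffusivity
# (axially symmetric tensor); used for the degraded boundary rim
rim_rd <- function(lambda1, fa_target) {
  fa_of <- function(rd) {
    d <- lambda1 - rd
    md <- (lambda1 + 2 * rd) / 3
    d / sqrt(3 * md^2 + 2 * d^2 / 3)
  }
  stats::uniroot(function(rd) fa_of(rd) - fa_target,
                 c(lambda1 * 0.01, lambda1 * 0.999))$root
}

# axially symmetric tensor elements from fiber direction + eigenvalues
fiber_tensor_elems <- function(f, lambda1, rd) {
  # D = rd*I + (lambda1-rd) f f'
  d <- lambda1 - rd
  cbind(rd + d * f[, 1]^2, rd + d * f[, 2]^2, rd + d * f[, 3]^2,
        d * f[, 1] * f[, 2], d * f[, 1] * f[, 3], d * f[, 2] * f[, 3])
}

#' Simulate the phantom's diffusion-weighted acquisition
#'
#' Per muscle voxel the ground-truth signal is a two-compartment mix:
#' `S_i = s0 * ((1 - FF) * exp(-b_i g_i' D g_i) + FF * exp(-b_i D_fat))`
#' with the muscle tensor `D` built from the voxel's fiber direction and
#' the muscle's eigenvalues, and isotropic fat diffusivity `D_fat`.
#' Rician noise is applied as two independent Gaussian channels with
#' `sigma = s0 / snr`; the sigma map records the true Gaussian sigma.
#' Background voxels contain pure noise.
#'
#' Because voxels with FF > 0 are deliberately non-mono-exponential, the
#' `truth$muscles` table reports both the pure-muscle eigenvalue metrics
#' and the *effective* single-tensor metrics (`md_eff`, `fa_eff`, ...)
#' obtained by fitting the noise-free mixed signal — the correct reference
#' for parameter-recovery checks.
#'
#' @param spec a [phantom_spec()].
#' @param geometry optional precomputed [make_geometry()] result.
#' @param noise apply Rician noise (default TRUE; FALSE gives the
#'   noise-free limit).
#' @return List: `dwi` (4D `volume4d`), `scheme`, `sigma` and `ff` (3D
#'   `volume4d`), `labels` (truth [label_map()]), and `truth` (fibers,
#'   per-voxel tensor elements, per-muscle parameter table).
#' @export
simulate_dwi <- function(spec, geometry = NULL, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(geometry)) geometry <- make_geometry(spec)
  labels <- geometry$labels$labels
  shp <- spec$grid$shape
  nvox <- prod(shp)
  nmeas <- length(spec$scheme$bvals)
  fib <- matrix(geometry$fibers, nrow = nvox, ncol = 3L)
  sig <- matrix(0, nvox, nmeas)
  ffv <- numeric(nvox)
  tens_true <- matrix(NA_real_, nvox, 6L)
  b <- spec$scheme$bvals
  g <- spec$scheme$bvecs
  fat_atten <- exp(-b * spec$fat_diffusivity * 1e-3)
  truth_rows <- list()
  rim <- array(FALSE, shp)
  if (spec$rim_voxels > 0L) {
    for (l in 1:7) {
      bin <- labels == l
      core <- bin
      for (i in seq_len(spec$rim_voxels)) core <- erode_bin(core)
      rim <- rim | (bin & !core)
    }
  }
  for (l in 1:7) {
    mrow <- spec$muscles[l, ]
    sel <- which(labels == l)
    f <- fib[sel, , drop = FALSE]
    te <- fiber_tensor_elems(f, mrow$lambda1, mrow$rd)
    if (spec$rim_voxels > 0L) {
      in_rim <- rim[sel]
      if (any(in_rim)) {
        rd_rim <- rim_rd(mrow$lambda1, spec$rim_fa)
        te[in_rim, ] <- fiber_tensor_elems(f[in_rim, , drop = FALSE],
                                           mrow$lambda1, rd_rim)
      }
    }
    tens_true[sel, ] <- te
    ffv[sel] <- mrow$ff
    # g' D g for all directions: quadratic form from the 6 elements
    gq <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
    quad <- te %*% t(gq)                       # voxels x measurements
    atten <- exp(sweep(quad * 1e-3, 2, b, `*`) * -1)
    mix <- (1 - mrow$ff) * atten +
      mrow$ff * matrix(fat_atten, nrow(atten), nmeas, byrow = TRUE)
    sig[sel, ] <- spec$s0 * mix
    # effective single-tensor metrics of the noise-free mixed signal,
    # evaluated for every distinct fiber direction the muscle contains
    # (the mixture's fitted tensor is not exactly rotation invariant under
    # a finite direction scheme; bipennate halves differ slightly) and
    # averaged with the voxel counts
    fdir <- unique(round(f, 12))
    wts <- sapply(seq_len(nrow(fdir)), function(i)
      sum(abs(f[, 1] - fdir[i, 1]) < 1e-9 & abs(f[, 2] - fdir[i, 2]) < 1e-9 &
          abs(f[, 3] - fdir[i, 3]) < 1e-9))
    effs <- lapply(seq_len(nrow(fdir)), function(i) {
      te0 <- fiber_tensor_elems(fdir[i, , drop = FALSE], mrow$lambda1,
                                mrow$rd)
      a0 <- exp(-b * as.vector(te0 %*% t(gq)) * 1e-3)
      s_mix <- spec$s0 * ((1 - mrow$ff) * a0 + mrow$ff * fat_atten)
      tensor_eigen(fit_tensor_wls(s_mix, spec$scheme, tol = 1e-13,
                                  max_iter = 200L))
    })
    wmean <- function(get) sum(wts * vapply(effs, get, 0)) / sum(wts)
    truth_rows[[l]] <- data.frame(
      label = l, muscle = mrow$muscle, lambda1 = mrow$lambda1, rd = mrow$rd,
      md = (mrow$lambda1 + 2 * mrow$rd) / 3,
      fa = tensor_eigen(fiber_tensor_elems(fdir[1, , drop = FALSE],
                                           mrow$lambda1, mrow$rd)[1, ])$fa,
      pennation = mrow$pennation, ff = mrow$ff,
      md_eff = wmean(function(e) e$md),
      fa_eff = wmean(function(e) e$fa),
      lambda1_eff = wmean(function(e) e$values[1]),
      rd_eff = wmean(function(e) e$rd))
  }
  sigma <- spec$s0 / spec$snr
  if (noise) {
    sig <- with_seed(spec$seed + 1L, {
      n1 <- matrix(stats::rnorm(nvox * nmeas, 0, sigma), nvox, nmeas)
      n2 <- matrix(stats::rnorm(nvox * nmeas, 0, sigma), nvox, nmeas)
      sqrt((sig + n1)^2 + n2^2)
    })
  }
  list(dwi = as_volume(array(sig, c(shp, nmeas)), spec$grid),
       scheme = spec$scheme,
       sigma = as_volume(array(sigma, shp), spec$grid),
       ff = as_volume(array(ffv, shp), spec$grid),
       labels = geometry$labels,
       truth = list(fibers = geometry$fibers,
                    tensors = array(tens_true, c(shp, 6L)),
                    muscles = do.call(rbind, truth_rows),
                    rim = rim, sigma = sigma))
}

#' Simulate two independent rater segmentations
#'
#' Each rater receives a copy of the truth label map with independent
#' random boundary perturbation: every interior boundary voxel of a
#' muscle (in-label, face-adjacent to non-label) is dropped with
#' probability `p`, and every exterior boundary voxel (background,
#' face-adjacent to the label) is added with probability `p`, where
#' `p = min(0.9, 0.15 * jitter)` — calibrated so that one voxel of jitter
#' behaves like a one-voxel boundary uncertainty (per-muscle Dice between
#' raters stays above ~0.85). Additions are restricted to background,
#' so muscles never bleed into each other, and are face-adjacent to the
#' label, so no new connected components appear.
#'
#' @param labels truth [label_map()].
#' @param jitter boundary perturbation magnitude (voxels; 0 = identical
#'   raters).
#' @param seed RNG seed.
#' @return List of two [label_map()] objects (`rater1`, `rater2`).
#' @export
simulate_raters <- function(labels, jitter = 1, seed = 1L) {
  stopifnot(inherits(labels, "label_map"))
  if (jitter < 0) stop("jitter must be >= 0")
  if (jitter == 0) return(list(rater1 = labels, rater2 = labels))
  p <- min(0.9, 0.15 * jitter)
  perturb <- function() {
    out <- labels$labels
    for (l in labels_present(labels)) {
      bin <- labels$labels == l
      interior_b <- bin & !erode_bin(bin)
      exterior_b <- dilate_bin(bin) & !bin & labels$labels == 0L
      drop_idx <- which(interior_b)
      drop_idx <- drop_idx[stats::runif(length(drop_idx)) < p]
      add_idx <- which(exterior_b)
      add_idx <- add_idx[stats::runif(length(add_idx)) < p]
      out[drop_idx] <- 0L
      out[add_idx] <- l
      if (!any(out == l))
        stop(sprintf("jitter %g removed muscle label %d entirely", jitter, l))
    }
    label_map(out, labels$grid, labels$names)
  }
  with_seed(seed, list(rater1 = perturb(), rater2 = perturb()))
}

#' Dice overlap between two label maps, per label
#'
#' @param a,b [label_map()] objects on the same grid.
#' @return Named numeric vector of Dice coefficients.
#' @export
dice_labels <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "label maps")
  ls <- union(labels_present(a), labels_present(b))
  out <- vapply(ls, function(l) {
    ma <- a$labels == l
    mb <- b$labels == l
    2 * sum(ma & mb) / (sum(ma) + sum(mb))
  }, 0)
  names(out) <- a$names[as.character(ls)]
  out
}

#' Write a complete phantom subject to disk
#'
#' Produces the on-disk layout of one acquired subject: `dwi.nii.gz`,
#' `bvals`/`bvecs`, `sigma.nii.gz`, `ff.nii.gz`, rater label maps, and a
#' `truth/` directory with the ground-truth labels and per-muscle
#' parameter table.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the simulation list from [simulate_dwi()] augmented
#'   with the rater maps.
#' @export
write_phantom_subject <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  sim <- simulate_dwi(spec)
  raters <- simulate_raters(sim$labels, spec$rater_jitter, spec$seed + 2L)
  write_nifti(sim$dwi, file.path(dir, "dwi.nii.gz"))
  write_gradients(sim$scheme, file.path(dir, "bvals"), file.path(dir, "bvecs"))
  write_nifti(sim$sigma, file.path(dir, "sigma.nii.gz"))
  write_nifti(sim$ff, file.path(dir, "ff.nii.gz"))
  write_nifti(raters$rater1, file.path(dir, "labels_rater1.nii.gz"))
  write_nifti(raters$rater2, file.path(dir, "labels_rater2.nii.gz"))
  write_nifti(sim$labels, file.path(dir, "truth", "labels.nii.gz"))
  utils::write.csv(sim$truth$muscles,
                   file.path(dir, "truth", "muscles.csv"), row.names = FALSE)
  sim$raters <- raters
  invisible(sim)
}
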