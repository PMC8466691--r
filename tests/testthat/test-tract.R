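# Volume-based tractography: streamline geometry against analytic
# constructions, visitation-weighted sampling, tract properties.

test_that("a uniform +z field tracks straight through the whole mask", {
  fit <- uniform_fit(c(10, 10, 20), c(3, 3, 1.5), dir = c(0, 0, 1), fa = 0.3)
  mask <- array(TRUE, c(10, 10, 20))
  tr <- track_muscle(fit, mask, tracking_params())
  expect_gt(length(tr$streamlines), 0)
  expect_true(all(tr$term_start == "mask-exit"))
  expect_true(all(tr$term_end == "mask-exit"))
  len <- streamline_lengths(tr)
  z_extent <- 20 * 1.5
  expect_true(all(abs(len - median(len)) <= 1.5 + 1e-9))
  expect_gt(min(len), z_extent - 2 * 1.5 - 1e-9)
  expect_lt(max(len), z_extent + 1e-9)
  # straight: x and y coordinates constant along each line
  for (p in tr$streamlines[1:5]) {
    expect_lt(max(abs(p[, 1] - p[1, 1])), 1e-9)
    expect_lt(max(abs(p[, 2] - p[1, 2])), 1e-9)
  }
})

test_that("fields below the FA floor yield no streamlines", {
  fit <- uniform_fit(c(8, 8, 12), c(3, 3, 3), fa = 0.05)
  tr <- track_muscle(fit, array(TRUE, c(8, 8, 12)), tracking_params())
  expect_length(tr$streamlines, 0L)
})

test_that("curvature beyond the angle criterion terminates streamlines", {
  # circular-arc field in the xz plane: turning per 1.5 mm step is
  # step / radius; radius chosen for 20 degrees per step (> 15 limit)
  radius <- 1.5 / (20 * pi / 180)
  shape <- c(30, 4, 30); vs <- c(1, 1, 1)
  grid <- image_grid(shape, vs)
  rd <- axial_rd_for_fa(2, 0.3)
  d <- 2 - rd
  tens <- array(NA_real_, c(shape, 6L))
  cx <- 15; cz <- 15
  for (i in 0:(shape[1] - 1)) for (k in 0:(shape[3] - 1)) {
    t_dir <- c(-(k - cz), 0, i - cx)
    n <- sqrt(sum(t_dir^2))
    t_dir <- if (n < 1e-9) c(0, 0, 1) else t_dir / n
    el <- c(rd + d * t_dir[1]^2, rd, rd + d * t_dir[3]^2,
            0, d * t_dir[1] * t_dir[3], 0)
    for (j in 0:(shape[2] - 1)) tens[i + 1, j + 1, k + 1, ] <- el
  }
  fit <- make_fit(tens, grid)
  # mask: annulus around the arc radius so seeds sit on curved field lines
  mask <- array(FALSE, shape)
  for (i in 0:(shape[1] - 1)) for (k in 0:(shape[3] - 1)) {
    r <- sqrt((i - cx)^2 + (k - cz)^2)
    if (abs(r - radius) < 2.5) mask[i + 1, , k + 1] <- TRUE
  }
  tr <- track_muscle(fit, mask, tracking_params(min_length = 0))
  expect_gt(length(tr$streamlines), 0)
  expect_true(any(c(tr$term_start, tr$term_end) == "angle"))
})

test_that("retained streamlines respect step size and the angle bound", {
  ph <- small_phantom()
  tr <- track_muscle(ph$fit, ph$sim$labels, label = 2L)
  cos_max <- cos(tr$params$max_angle * pi / 180)
  mask <- ph$sim$labels$labels == 2L
  shp <- ph$fit$grid$shape
  for (p in tr$streamlines[seq_len(min(50, length(tr$streamlines)))]) {
    seg <- diff(p)
    sl <- sqrt(rowSums(seg^2))
    expect_lt(max(abs(sl - tr$params$step_size)), 1e-6)
    if (nrow(seg) > 1) {
      cosang <- rowSums(seg[-nrow(seg), , drop = FALSE] *
                        seg[-1, , drop = FALSE]) /
        (sl[-length(sl)] * sl[-1])
      expect_gte(min(cosang), cos_max - 1e-9)
    }
    # every point lies inside the muscle mask (nearest voxel)
    v <- round(world_to_voxel(ph$fit$grid, p)) + 1
    expect_true(all(mask[cbind(v[, 1], v[, 2], v[, 3])]))
  }
})

test_that("tracking is deterministic", {
  ph <- small_phantom()
  a <- track_muscle(ph$fit, ph$sim$labels, label = 3L)
  b <- track_muscle(ph$fit, ph$sim$labels, label = 3L)
  expect_identical(a$streamlines, b$streamlines)
  expect_identical(a$term_end, b$term_end)
})

test_that("MTL converges to the mask extent as the step shrinks", {
  shape <- c(6, 6, 20)
  fit <- uniform_fit(shape, c(3, 3, 3), dir = c(0, 0, 1), fa = 0.25)
  mask <- array(TRUE, shape)
  extent <- 20 * 3
  mtl <- sapply(c(3, 1.5, 0.75), function(st) {
    tr <- track_muscle(fit, mask, tracking_params(step_size = st))
    mean(streamline_lengths(tr))
  })
  err <- abs(mtl - extent)
  expect_true(all(diff(err) <= 1e-9))     # error shrinks with the step
  expect_lt(err[3], 2 * 0.75 + 1e-9)
})

test_that("visitation weighting reproduces hand-counted means", {
  grid <- image_grid(c(4, 4, 4))
  fa <- array(0, c(4, 4, 4))
  fa[1, 1, 1] <- 0.1      # visited once
  fa[2, 1, 1] <- 0.3      # visited three times
  maps <- make_maps(grid, fa = fa)
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  tr <- make_tracts(list(pts), grid, step_size = 1)
  res <- tract_sample(tr, maps)
  expect_equal(res$fa, 0.25)              # visitation-weighted
  # the voxel-averaged value over the same two voxels is 0.2
  lab <- array(0L, c(4, 4, 4)); lab[1:2, 1, 1] <- 1L
  msb <- extract_msb(maps, label_map(lab, grid, names = c(`1` = "m")))
  expect_equal(msb$fa, 0.2)
})

test_that("a constant map samples to its value regardless of geometry", {
  grid <- image_grid(c(5, 5, 5))
  maps <- make_maps(grid, fa = array(0.22, c(5, 5, 5)))
  set.seed(30)
  lines <- lapply(1:7, function(i)
    cbind(runif(5, 0, 4), runif(5, 0, 4), runif(5, 0, 4)))
  res <- tract_sample(make_tracts(lines, grid, 1), maps)
  expect_equal(res$fa, 0.22)
  # empty tract set: warning, no metrics
  expect_warning(res0 <- tract_sample(make_tracts(list(), grid, 1), maps),
                 "empty")
  expect_null(res0)
})

test_that("tract sampling equals MSB when each voxel is visited exactly once", {
  grid <- image_grid(c(4, 3, 5))
  set.seed(31)
  fa <- array(runif(60), c(4, 3, 5))
  maps <- make_maps(grid, fa = fa)
  # one straight z line through every (i, j) column: every voxel once
  lines <- list()
  for (i in 0:3) for (j in 0:2)
    lines[[length(lines) + 1L]] <- cbind(i, j, 0:4)
  res <- tract_sample(make_tracts(lines, grid, 1), maps)
  lab <- label_map(array(1L, c(4, 3, 5)), grid, names = c(`1` = "m"))
  msb <- extract_msb(maps, lab)
  expect_equal(res$fa, msb$fa, tolerance = 1e-12)
})

test_that("tract properties match constructed geometry", {
  grid <- image_grid(c(20, 20, 10))          # 1 mm voxels
  mask <- array(TRUE, c(20, 20, 10))         # 4000 mm^3 = 4 cm^3
  lines <- lapply(1:100, function(i) cbind(i %% 10, i %/% 10,
                                           seq(0, 60, by = 1.5)))
  tr <- make_tracts(lines, grid, step_size = 1.5)
  props <- tract_properties(tr, mask)
  expect_equal(props$vol, 4)
  expect_equal(props$td, 25)
  expect_equal(props$mtl, 60)
  expect_equal(props$mean_angle, 0, tolerance = 1e-9)
  # uniform 30-degree inclination to +z
  dirv <- c(sin(pi / 6), 0, cos(pi / 6))
  lines30 <- lapply(1:10, function(i)
    t(sapply(0:20, function(s) c(0, i, 0) + s * 1.5 * dirv)))
  props30 <- tract_properties(make_tracts(lines30, grid, 1.5), mask)
  expect_equal(props30$mean_angle, 30, tolerance = 1e-9)
  expect_error(tract_properties(tr, array(FALSE, c(20, 20, 10))),
               "zero-volume")
})

test_that("phantom pennation angles are recovered from tract geometry", {
  ph <- small_phantom()
  rep <- vbt_report(ph$fit, ph$sim$labels)
  expect_identical(rep$label, 1:7)
  expect_true(all(rep$n_tracts > 100))
  expect_lt(max(abs(rep$mean_angle - ph$spec$muscles$pennation)), 2)
  # visitation-weighted MD also recovers the generator truth
  expect_lt(max(abs(rep$md / ph$sim$truth$muscles$md_eff - 1)), 0.02)
})

test_that("tracking in a noise-free phantom recovers pennation within 1 degree", {
  spec <- phantom_spec(seed = 21, grid_shape = c(40L, 40L, 24L))
  sim <- simulate_dwi(spec, noise = FALSE)
  fit <- fit_dti(sim$dwi, sim$scheme, mask = sim$labels$labels > 0L,
                 method = "wls")
  rep <- vbt_report(fit, sim$labels)
  expect_lt(max(abs(rep$mean_angle - spec$muscles$pennation)), 1)
})
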