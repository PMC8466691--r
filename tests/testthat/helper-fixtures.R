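# Shared fixtures, built once per test run. The phantom simulations are
# the expensive pieces; they are cached in a session environment so every
# test file can reuse them.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env, inherits = FALSE))
    assign(name, force(expr), envir = fixture_env)
  get(name, envir = fixture_env)
}

# a moderately sized phantom subject, fitted, with scalar maps
small_phantom <- function() cached("small_phantom", {
  spec <- phantom_spec(seed = 11, grid_shape = c(40L, 40L, 24L))
  sim <- simulate_dwi(spec)
  fit <- fit_dti(sim$dwi, sim$scheme, mask = sim$labels$labels > 0L)
  list(spec = spec, sim = sim, fit = fit, maps = eigen_maps(fit))
})

# radial diffusivity giving a target FA at fixed axial diffusivity
# (axially symmetric tensor) -- used to construct fields with known FA
axial_rd_for_fa <- function(lambda1, fa_target) {
  fa_of <- function(rd) {
    d <- lambda1 - rd
    md <- (lambda1 + 2 * rd) / 3
    d / sqrt(3 * md^2 + 2 * d^2 / 3)
  }
  stats::uniroot(function(rd) fa_of(rd) - fa_target,
                 c(lambda1 * 0.001, lambda1 * 0.999), tol = 1e-12)$root
}

# assemble a dti_fit object from a given per-voxel tensor-element array
make_fit <- function(tensors, grid) {
  shp <- grid$shape
  mask <- array(rowSums(!is.na(matrix(tensors, prod(shp)))) == 6L, shp)
  structure(list(tensors = tensors, s0 = array(1, shp),
                 fallback = array(0L, shp), n_outliers = array(0L, shp),
                 clamped = array(0L, shp), mask = mask, grid = grid,
                 method = "wls", kappa = 6),
            class = "dti_fit")
}

# uniform axially symmetric tensor field along `dir` with given FA
uniform_fit <- function(shape, voxel_size, dir = c(0, 0, 1), lambda1 = 2,
                        fa = 0.3) {
  dir <- dir / sqrt(sum(dir^2))
  rd <- axial_rd_for_fa(lambda1, fa)
  d <- lambda1 - rd
  el <- c(rd + d * dir[1]^2, rd + d * dir[2]^2, rd + d * dir[3]^2,
          d * dir[1] * dir[2], d * dir[1] * dir[3], d * dir[2] * dir[3])
  grid <- image_grid(shape, voxel_size)
  tens <- array(rep(el, each = prod(shape)), c(shape, 6L))
  make_fit(tens, grid)
}

# minimal scalar_maps object from plain arrays (no flagged voxels)
make_maps <- function(grid, fa, md = fa, lambda1 = fa, rd = fa) {
  structure(list(fa = fa, md = md, lambda1 = lambda1,
                 lambda2 = rd, lambda3 = rd, rd = rd,
                 v1 = array(NA_real_, c(grid$shape, 3L)),
                 flag = array(FALSE, grid$shape), grid = grid),
            class = "scalar_maps")
}

# hand-built tract_set: list of world-mm point matrices
make_tracts <- function(streamlines, grid, step_size) {
  structure(list(streamlines = streamlines,
                 term_start = rep("mask-exit", length(streamlines)),
                 term_end = rep("mask-exit", length(streamlines)),
                 seed_voxels = seq_along(streamlines),
                 params = tracking_params(step_size = step_size),
                 grid = grid, n_seed_voxels = length(streamlines)),
            class = "tract_set")
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3L, 3L)
}
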