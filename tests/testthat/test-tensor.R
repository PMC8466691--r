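# Tensor model: forward signal prediction, WLS and robust fits, eigen
# decomposition and SNR. The forward model is the oracle throughout: a
# fit is correct iff it inverts predict_signal.

test_that("forward model evaluates the mono-exponential tensor signal", {
  sch <- default_scheme()
  iso <- dti_tensor(1.58 * diag(3), s0 = 1000)
  s <- predict_signal(iso, sch)
  expect_equal(s[sch$bvals == 0], rep(1000, 3))                # b = 0: s0
  expect_equal(s[sch$bvals == 400], rep(1000 * exp(-0.632), 17),
               tolerance = 1e-12)
  # attenuation is monotone in the quadratic form g' D g
  tt <- dti_tensor(c(2, 1, 1, 0, 0, 0), s0 = 500)
  along <- predict_signal(tt, gradient_scheme(c(0, rep(400, 7)),
    rbind(0, diag(3)[c(1, 1, 2, 3, 1, 2, 3), ])))
  expect_true(along[2] < along[4])     # g along lambda1 attenuates more
})

test_that("WLS fit inverts the forward model on noise-free signals", {
  set.seed(42)
  sch <- default_scheme()
  R <- random_rotation()
  D <- R %*% diag(c(2.0, 1.5, 1.0)) %*% t(R)
  truth <- dti_tensor(D, s0 = 1200)
  fit <- fit_tensor_wls(predict_signal(truth, sch), sch)
  expect_lt(max(abs(fit$D - truth$D)), 1e-9)
  expect_lt(abs(fit$s0 - 1200), 1e-6)
})

test_that("fit(predict(T)) = T over many random tensors", {
  set.seed(7)
  sch <- default_scheme()
  X <- muscledti:::tensor_design(sch)
  worst <- 0
  for (i in 1:1000) {
    R <- random_rotation()
    D <- R %*% diag(sort(runif(3, 0.3, 2.5), decreasing = TRUE)) %*% t(R)
    truth <- dti_tensor(D, s0 = runif(1, 100, 2000))
    fit <- fit_tensor_wls(predict_signal(truth, sch), sch)
    worst <- max(worst, max(abs(fit$D - truth$D)))
  }
  expect_lt(worst, 1e-9)
})

test_that("constant diffusion-weighted signals give an isotropic tensor", {
  sch <- default_scheme()
  s <- ifelse(sch$bvals == 0, 1000, 600)
  fit <- fit_tensor_wls(s, sch)
  expect_lt(tensor_eigen(fit)$fa, 1e-10)
})

test_that("WLS is unbiased for MD at the protocol SNR", {
  set.seed(99)
  sch <- default_scheme()
  truth <- dti_tensor(c(1.97, 1.39, 1.39, 0, 0, 0), s0 = 1000)
  clean <- predict_signal(truth, sch)
  sigma <- 1000 / 59
  mds <- replicate(500, {
    s <- sqrt((clean + rnorm(20, 0, sigma))^2 + rnorm(20, 0, sigma)^2)
    tensor_eigen(fit_tensor_wls(s, sch))$md
  })
  expect_lt(abs(mean(mds) / ((1.97 + 2 * 1.39) / 3) - 1), 0.02)
})

test_that("robust fit flags an injected outlier and recovers the tensor", {
  set.seed(5)
  sch <- default_scheme()
  R <- random_rotation()
  truth <- dti_tensor(R %*% diag(c(2.1, 1.4, 1.2)) %*% t(R), s0 = 900)
  s <- predict_signal(truth, sch)
  s[9] <- s[9] * 3
  fit <- fit_tensor_robust(s, sch)
  expect_identical(which(attr(fit, "outliers")), 9L)
  expect_false(attr(fit, "fallback"))
  expect_lt(max(abs(fit$D - truth$D)), 1e-6)
})

test_that("robust fit equals plain WLS when there is nothing to reject", {
  set.seed(6)
  sch <- default_scheme()
  truth <- dti_tensor(c(1.9, 1.5, 1.3, 0.1, -0.05, 0.02), s0 = 700)
  s <- predict_signal(truth, sch)
  rob <- fit_tensor_robust(s, sch)
  wls <- fit_tensor_wls(s, sch)
  expect_identical(sum(attr(rob, "outliers")), 0L)
  expect_lt(max(abs(rob$D - wls$D)), 1e-9)
})

test_that("robust fit is never worse than WLS with up to two outliers", {
  set.seed(8)
  sch <- default_scheme()
  for (i in 1:25) {
    R <- random_rotation()
    truth <- dti_tensor(R %*% diag(sort(runif(3, 0.8, 2.3),
                                        decreasing = TRUE)) %*% t(R),
                        s0 = 1000)
    s <- predict_signal(truth, sch)
    n_out <- sample(0:2, 1)
    idx <- sample(20, n_out)
    s[idx] <- s[idx] * runif(n_out, 1.5, 4)
    rob <- suppressWarnings(fit_tensor_robust(s, sch))
    wls <- suppressWarnings(fit_tensor_wls(s, sch))
    expect_lte(max(abs(rob$D - truth$D)), max(abs(wls$D - truth$D)) + 1e-12)
  }
})

test_that("corruption that starves the refit triggers the fallback path", {
  truth <- dti_tensor(c(1.9, 1.4, 1.4, 0, 0, 0), s0 = 1000)
  # mutually inconsistent gross corruption of every b = 0 measurement:
  # all three get flagged, leaving no baseline for the refit
  sch <- default_scheme()
  s <- predict_signal(truth, sch)
  s[sch$bvals == 0] <- s[sch$bvals == 0] * c(8, 0.05, 12)
  fit <- suppressWarnings(fit_tensor_robust(s, sch))
  expect_true(all(attr(fit, "outliers")[sch$bvals == 0]))
  expect_true(attr(fit, "fallback"))
})

test_that("non-positive signals are clamped with a warning", {
  sch <- default_scheme()
  s <- predict_signal(dti_tensor(1.5 * diag(3), s0 = 100), sch)
  s[3] <- 0
  expect_warning(fit_tensor_wls(s, sch), "clamped")
})

test_that("degenerate gradient schemes are rejected by condition number", {
  # seven DW measurements all along one axis cannot determine the tensor
  bv <- rbind(c(0, 0, 0), matrix(rep(c(1, 0, 0), 9), ncol = 3, byrow = TRUE))
  sch <- gradient_scheme(c(0, rep(400, 9)), bv)
  expect_error(fit_tensor_wls(rep(100, 10), sch), "condition number")
})

test_that("eigen metrics honour their defining identities", {
  # healthy-calf group eigenvalues: MD is their mean
  ax <- tensor_eigen(c(1.97, 1.39, 1.39, 0, 0, 0))
  expect_equal(ax$md, (1.97 + 2 * 1.39) / 3, tolerance = 1e-12)
  expect_equal(round(ax$md, 2), 1.58)
  expect_equal(ax$rd, 1.39, tolerance = 1e-12)
  # isotropic: FA 0, MD = RD = lambda1
  iso <- tensor_eigen(c(1.3, 1.3, 1.3, 0, 0, 0))
  expect_equal(iso$fa, 0)
  expect_equal(iso$md, 1.3)
  expect_equal(iso$rd, 1.3)
  expect_equal(iso$values[1], 1.3)
  # stick limit: FA 1
  expect_equal(tensor_eigen(c(1, 0, 0, 0, 0, 0))$fa, 1, tolerance = 1e-12)
})

test_that("FA is rotation invariant", {
  set.seed(12)
  base <- diag(c(2.2, 1.1, 0.9))
  fa0 <- tensor_eigen(dti_tensor(base))$fa
  for (i in 1:50) {
    R <- random_rotation()
    fa <- tensor_eigen(dti_tensor(R %*% base %*% t(R)))$fa
    expect_lt(abs(fa - fa0), 1e-10)
  }
})

test_that("single-voxel R fits and the compiled batch fit agree", {
  set.seed(13)
  sch <- default_scheme()
  X <- muscledti:::tensor_design(sch)
  sig <- sapply(1:20, function(i) {
    R <- random_rotation()
    truth <- dti_tensor(R %*% diag(runif(3, 0.5, 2.4)) %*% t(R), s0 = 1000)
    s <- predict_signal(truth, sch)
    sqrt((s + rnorm(20, 0, 17))^2 + rnorm(20, 0, 17)^2)
  })
  for (robust in c(FALSE, TRUE)) {
    batch <- muscledti:::fit_tensors_batch(sig, X, sch$bvals, robust,
                                           6, 1e-6, 20L, 3)
    for (v in 1:20) {
      single <- if (robust) fit_tensor_robust(sig[, v], sch)
                else fit_tensor_wls(sig[, v], sch)
      expect_lt(max(abs(batch$beta[2:7, v] - single$D)), 1e-10)
    }
  }
})

test_that("scalar-map identities hold map-wide on a fitted field", {
  ph <- small_phantom()
  m <- ph$maps
  ok <- !is.na(m$md)
  expect_equal(m$md[ok], ((m$lambda1 + m$lambda2 + m$lambda3) / 3)[ok],
               tolerance = 1e-12)
  expect_equal(m$rd[ok], ((m$lambda2 + m$lambda3) / 2)[ok],
               tolerance = 1e-12)
  neg <- ok & m$lambda3 >= 0
  expect_true(all(m$fa[neg] >= 0 & m$fa[neg] <= 1))
  expect_true(all(m$lambda1[ok] >= m$lambda2[ok] &
                  m$lambda2[ok] >= m$lambda3[ok]))
})

test_that("SNR map is signal over sigma, with sigma 0 masked out", {
  grid <- image_grid(c(2, 2, 2))
  sig <- array(100, c(2, 2, 2, 8))
  sch <- gradient_scheme(c(0, rep(400, 7)),
                         rbind(0, muscledti:::default_scheme(7)$bvecs[4:10, ]))
  sg <- array(2, c(2, 2, 2)); sg[1, 1, 1] <- 0
  snr <- snr_map(as_volume(sig, grid), sch, as_volume(sg, grid))
  expect_equal(snr[2, 2, 2], 50)
  expect_true(is.na(snr[1, 1, 1]))
  g2 <- image_grid(c(2, 2, 2), c(2, 2, 2))
  expect_error(snr_map(as_volume(sig, grid), sch, as_volume(sg, g2)),
               "grid mismatch")
})

test_that("phantom SNR is recovered from the noisy data", {
  ph <- small_phantom()
  snr <- snr_map(ph$sim$dwi, ph$sim$scheme, ph$sim$sigma)
  in_mask <- ph$sim$labels$labels > 0L
  expect_lt(abs(mean(snr[in_mask]) / ph$spec$snr - 1), 0.05)
})
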