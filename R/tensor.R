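#' Diffusion tensor for a single voxel
#'
#' Six unique elements of the symmetric 3x3 diffusion tensor, carried in
#' units of 1e-3 mm^2/s (the scale on which muscle diffusivities are
#' conventionally reported), plus the non-diffusion-weighted signal `s0`.
#'
#' @param D numeric length 6, elements `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` in
#'   1e-3 mm^2/s; or a symmetric 3x3 matrix.
#' @param s0 non-diffusion-weighted signal (arbitrary units, > 0).
#' @return Object of class `dti_tensor`.
#' @export
dti_tensor <- function(D, s0 = 1) {
  if (is.matrix(D)) {
    if (!all(dim(D) == c(3L, 3L)) || max(abs(D - t(D))) > 1e-10)
      stop("'D' matrix must be symmetric 3x3")
    D <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }
  if (length(D) != 6L || any(!is.finite(D)))
    stop("'D' must be six finite tensor elements")
  if (!is.finite(s0) || s0 <= 0) stop("'s0' must be positive")
  names(D) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  structure(list(D = D, s0 = s0), class = "dti_tensor")
}

#' @export
print.dti_tensor <- function(x, ...) {
  ev <- tensor_eigen(x$D)
  cat("<dti_tensor> eigenvalues", paste(format(ev$values, digits = 4),
                                        collapse = ", "),
      "(1e-3 mm2/s), s0 =", format(x$s0, digits = 5), "\n")
  invisible(x)
}

tensor_matrix <- function(D) {
  matrix(c(D[1], D[4], D[5],
           D[4], D[2], D[6],
           D[5], D[6], D[3]), 3L, 3L)
}

#' Forward model: predicted diffusion-weighted signal
#'
#' Mono-exponential tensor model `S_i = s0 * exp(-b_i * g_i' D g_i)` with
#' `b` in s/mm^2 and `D` converted internally from 1e-3 mm^2/s to mm^2/s.
#'
#' @param tensor a [dti_tensor()].
#' @param scheme a [gradient_scheme()].
#' @return Numeric vector of predicted signals, one per measurement.
#' @export
predict_signal <- function(tensor, scheme) {
  Dm <- tensor_matrix(tensor$D) * 1e-3          # mm^2/s
  g <- scheme$bvecs
  quad <- rowSums((g %*% Dm) * g)               # g' D g
  tensor$s0 * exp(-scheme$bvals * quad)
}

# Design matrix of the log-linear tensor model: columns are
# (log s0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) with D in 1e-3 mm^2/s.
tensor_design <- function(scheme) {
  b <- scheme$bvals * 1e-3
  g <- scheme$bvecs
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

check_design <- function(X) {
  sv <- svd(X, nu = 0, nv = 0)$d
  cn <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(cn) || cn > 1e10)
    stop(sprintf("degenerate gradient scheme: design condition number %.3g", cn))
  invisible(cn)
}

clamp_signals <- function(signals) {
  bad <- signals <= 0
  if (any(bad)) {
    warning(sprintf("%d non-positive signal(s) clamped to machine epsilon",
                    sum(bad)))
    signals[bad] <- .Machine$double.eps
  }
  signals
}

beta_to_tensor <- function(beta) {
  dti_tensor(beta[2:7], s0 = exp(beta[1]))
}

wls_solve <- function(X, y, w) {
  # normalise and floor the weights: keeps the normal equations well
  # conditioned when a wildly inconsistent voxel drives some predicted
  # signals (hence weights) to numerical zero
  w <- w / max(w)
  w <- pmax(w, 1e-10)
  Xw <- X * w
  solve(crossprod(Xw, X), crossprod(Xw, y))
}

#' Weighted-least-squares tensor fit for one voxel
#'
#' Log-linear least squares initialisation followed by weighted
#' least-squares iterations with weights equal to the squared predicted
#' signals (the asymptotically correct weighting for log-transformed
#' Rician/Gaussian magnitude data), iterated to a relative parameter change
#' below `tol` or `max_iter` iterations.
#'
#' @param signals numeric vector of measured signals (one per scheme entry);
#'   non-positive values are clamped to machine epsilon with a warning.
#' @param scheme a [gradient_scheme()].
#' @param tol relative parameter-change convergence threshold.
#' @param max_iter maximum WLS iterations.
#' @return A [dti_tensor()] with attributes `iterations` and `converged`.
#' @export
fit_tensor_wls <- function(signals, scheme, tol = 1e-6, max_iter = 20L) {
  if (length(signals) != length(scheme$bvals))
    stop("signal vector length does not match gradient scheme")
  signals <- clamp_signals(as.numeric(signals))
  X <- tensor_design(scheme)
  check_design(X)
  y <- log(signals)
  beta <- solve(crossprod(X), crossprod(X, y))   # OLS init
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- exp(2 * as.vector(X %*% beta))          # squared predicted signals
    beta_new <- wls_solve(X, y, w)
    if (max(abs(beta_new - beta)) <= tol * max(max(abs(beta)), 1)) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  out <- beta_to_tensor(as.vector(beta))
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

# Robust residual scale: 1.4826 * median absolute deviation, floored at a
# level proportional to the data magnitude so that exact fits (all
# residuals ~ machine noise) do not flag everything.
robust_scale <- function(r, floor_ref) {
  max(1.4826 * stats::median(abs(r - stats::median(r))),
      1e3 * .Machine$double.eps * max(abs(floor_ref), 1))
}

# Signal-scaled ("standardized") residuals: log-domain residuals times the
# predicted signal approximate linear-domain residuals, which share one
# noise sigma across b-values — the scale on which outliers are judged.
std_residuals <- function(y, X, beta) {
  pred <- as.vector(X %*% beta)
  (y - pred) * exp(pred)
}

#' Robust tensor fit with outlier rejection for one voxel
#'
#' Iterative reweighting in the spirit of robust mDTI estimators:
#' (1) iteratively reweighted least squares with Geman-McClure weights on
#' the log-domain residuals, (2) residual-based outlier flagging at
#' `kappa` times the robust residual scale (1.4826 x MAD), (3) a final
#' plain WLS refit excluding the flagged measurements. If exclusion would
#' leave fewer than 7 measurements (or no b = 0), the non-robust fit is
#' returned and the voxel is flagged as a fallback.
#'
#' @inheritParams fit_tensor_wls
#' @param kappa outlier threshold in robust-scale units.
#' @param gm_tuning tuning constant of the Geman-McClure weight (in
#'   robust-scale units): larger values barely downweight inliers, which
#'   keeps the redescending fit efficient on designs with few residual
#'   degrees of freedom while still annihilating gross outliers.
#' @return A [dti_tensor()] with attributes `outliers` (logical per
#'   measurement), `fallback` (logical) and `iterations`.
#' @export
fit_tensor_robust <- function(signals, scheme, kappa = 6, tol = 1e-6,
                              max_iter = 20L, gm_tuning = 3) {
  if (length(signals) != length(scheme$bvals))
    stop("signal vector length does not match gradient scheme")
  signals <- clamp_signals(as.numeric(signals))
  X <- tensor_design(scheme)
  check_design(X)
  y <- log(signals)
  beta <- solve(crossprod(X), crossprod(X, y))
  # Robust scale estimated once, from the initial fit's signal-scaled
  # residuals, and held fixed through the IRLS: re-estimating it from the
  # Geman-McClure fit's own residuals collapses the scale when the design
  # has few residual degrees of freedom (the redescending fit absorbs the
  # majority of the points). The sqrt(m/(m-p)) factor corrects the MAD for
  # the variance absorbed by the p fitted parameters.
  m <- length(y); p <- ncol(X)
  smax <- max(signals)
  beta <- wls_solve(X, y, exp(2 * as.vector(X %*% beta)))
  s <- robust_scale(std_residuals(y, X, beta), smax) * sqrt(m / (m - p))
  # stage 1: Geman-McClure IRLS on signal-scaled residuals at fixed scale
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pred_w <- exp(2 * as.vector(X %*% beta))
    rs <- std_residuals(y, X, beta)
    gm <- 1 / (1 + (rs / (gm_tuning * s))^2)^2
    beta_new <- wls_solve(X, y, pred_w * gm)
    if (max(abs(beta_new - beta)) <= tol * max(max(abs(beta)), 1)) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  # stage 2: flag outliers. The scale is re-estimated once from the
  # converged robust fit's residuals (so that gross outliers, which
  # inflate the initial-fit scale, do not mask themselves) with the same
  # dof correction; signal-scaled residuals share one noise sigma across
  # b-values (log residuals do not).
  rs <- std_residuals(y, X, beta)
  s2 <- robust_scale(rs, smax) * sqrt(m / (m - p))
  out_mask <- abs(rs) > kappa * s2
  keep <- !out_mask
  fallback <- sum(keep) < 7L || !any(keep & scheme$bvals == 0)
  if (fallback) {
    fit <- suppressWarnings(fit_tensor_wls(signals, scheme, tol, max_iter))
    attr(fit, "outliers") <- out_mask
    attr(fit, "fallback") <- TRUE
    return(fit)
  }
  # stage 3: final WLS on retained measurements
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  sv <- svd(Xk, nu = 0, nv = 0)$d
  cn <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(cn) || cn > 1e10) {          # survivors degenerate: fall back
    fit <- suppressWarnings(fit_tensor_wls(signals, scheme, tol, max_iter))
    attr(fit, "outliers") <- out_mask
    attr(fit, "fallback") <- TRUE
    return(fit)
  }
  beta <- solve(crossprod(Xk), crossprod(Xk, yk))
  it2 <- 0L
  while (it2 < max_iter) {
    it2 <- it2 + 1L
    w <- exp(2 * as.vector(Xk %*% beta))
    beta_new <- wls_solve(Xk, yk, w)
    if (max(abs(beta_new - beta)) <= tol * max(max(abs(beta)), 1)) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  fit <- beta_to_tensor(as.vector(beta))
  attr(fit, "outliers") <- out_mask
  attr(fit, "fallback") <- FALSE
  attr(fit, "iterations") <- iter + it2
  fit
}

#' Eigenvalues and scalar invariants of one tensor
#'
#' @param D six tensor elements `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` or a
#'   [dti_tensor()].
#' @return List with `values` (descending eigenvalues), `vectors` (columns,
#'   matching order), `fa`, `md`, `rd`.
#' @export
tensor_eigen <- function(D) {
  if (inherits(D, "dti_tensor")) D <- D$D
  e <- eigen(tensor_matrix(D), symmetric = TRUE)   # descending by default
  ev <- e$values
  md <- mean(ev)
  ss <- sum(ev^2)
  fa <- if (ss == 0) 0 else sqrt(1.5 * sum((ev - md)^2) / ss)
  list(values = ev, vectors = e$vectors, fa = fa, md = md,
       rd = (ev[2] + ev[3]) / 2)
}
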