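#' Diffusion gradient scheme
#'
#' Pairs b-values (s/mm^2) with unit gradient directions. Directions with
#' b > 0 must have unit Euclidean norm; they are interpreted in the image
#' coordinate frame (inputs are assumed already registered, so no
#' scanner-frame rotation is applied). A tensor fit needs at least seven
#' diffusion-weighted measurements and one b = 0 measurement.
#'
#' @param bvals numeric vector of b-values in s/mm^2.
#' @param bvecs n x 3 numeric matrix of gradient directions (rows may be the
#'   zero vector where b = 0).
#' @return Object of class `gradient_scheme` with elements `bvals` (numeric)
#'   and `bvecs` (n x 3 matrix).
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("'bvecs' must have three columns (x, y, z)")
  if (length(bvals) != nrow(bvecs))
    stop(sprintf("length mismatch: %d b-values vs %d directions",
                 length(bvals), nrow(bvecs)))
  if (any(bvals < 0)) stop("negative b-value")
  dw <- bvals > 0
  if (sum(dw) < 7L)
    stop("insufficient diffusion weighting: need >= 7 measurements with b > 0")
  if (!any(!dw))
    stop("gradient scheme has no b = 0 measurement")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- dw & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    if (any(dw & abs(nrm - 1) > 1e-3) || any(dw & nrm == 0)) {
      if (any(dw & nrm == 0))
        stop("zero direction vector with b > 0")
      warning(sprintf("%d non-unit gradient direction(s) renormalized", sum(bad)))
    } else {
      warning(sprintf("%d gradient direction(s) off unit norm by > 1e-6; renormalized",
                      sum(bad)))
    }
    bvecs[bad, ] <- bvecs[bad, , drop = FALSE] / nrm[bad]
  }
  structure(list(bvals = bvals, bvecs = unname(bvecs)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("<gradient_scheme> ", length(x$bvals), " measurements: ",
      sum(x$bvals == 0), " b=0, ", sum(x$bvals > 0),
      " diffusion-weighted (b = ",
      paste(unique(x$bvals[x$bvals > 0]), collapse = ", "), " s/mm2)\n",
      sep = "")
  invisible(x)
}

#' @export
length.gradient_scheme <- function(x) length(x$bvals)

#' Read an FSL-style bval/bvec pair
#'
#' The FSL dialect stores b-values as one whitespace-separated row and
#' directions as three rows (x, y, z components). Directions with b > 0 are
#' validated to unit norm (renormalized with a warning when off by more than
#' 1e-6).
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @return A [gradient_scheme()].
#' @export
read_gradients <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("gradient file not found: ", p)
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) != 3L)
    stop("bvec file must contain exactly three rows (x, y, z); got ", nrow(bv))
  if (ncol(bv) != length(bvals))
    stop(sprintf("length mismatch: %d b-values but %d directions",
                 length(bvals), ncol(bv)))
  gradient_scheme(bvals, t(bv))
}

#' Write a gradient scheme as FSL bval/bvec files
#' @param scheme a [gradient_scheme()].
#' @param bval_path,bvec_path output paths.
#' @export
write_gradients <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' The default acquisition scheme emulated by the phantom
#'
#' Seventeen diffusion directions at b = 400 s/mm^2 plus three b = 0
#' measurements, mirroring a clinical muscle-DTI protocol. Directions are
#' generated by a deterministic electrostatic-repulsion-style spiral on the
#' hemisphere so the scheme is reproducible without a lookup table.
#'
#' @param n_dirs number of diffusion-weighted directions.
#' @param bvalue diffusion weighting in s/mm^2.
#' @param n_b0 number of non-diffusion-weighted measurements (prepended).
#' @return A [gradient_scheme()].
#' @export
default_scheme <- function(n_dirs = 17L, bvalue = 400, n_b0 = 3L) {
  # Fibonacci hemisphere: near-uniform angular coverage, deterministic
  i <- seq_len(n_dirs) - 0.5
  z <- i / n_dirs                     # (0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  gradient_scheme(c(rep(0, n_b0), rep(bvalue, n_dirs)),
                  rbind(matrix(0, n_b0, 3), dirs))
}
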