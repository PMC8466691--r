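#' Default muscle name table: the seven calf muscles
#'
#' Label coding used throughout: 0 = background, 1..7 = the seven calf
#' muscles routinely segmented in lower-leg muscle DTI.
#'
#' @return Named character vector mapping label (as name) to muscle.
#' @export
calf_muscle_names <- function() {
  c(`1` = "extensor_digitorum",
    `2` = "gastrocnemius_lateralis",
    `3` = "gastrocnemius_medialis",
    `4` = "peroneus",
    `5` = "soleus",
    `6` = "tibialis_anterior",
    `7` = "tibialis_posterior")
}

#' Construct an image volume (3D scalar or 4D multi-measurement)
#'
#' @param data numeric 3D or 4D array, all values finite.
#' @param grid the [image_grid()] the data live on (first three dims must
#'   match `grid$shape`).
#' @return Object of class `volume4d` (also for 3D data; the fourth
#'   dimension is then absent).
#' @export
as_volume <- function(data, grid) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L)
    stop("volume data must be 3D or 4D; got ", nd, " dimensions")
  if (!all(dim(data)[1:3] == grid$shape))
    stop("data dimensions do not match grid shape")
  n_nan <- sum(!is.finite(data))
  if (n_nan > 0L)
    stop(sprintf("volume contains %d non-finite voxel value(s)", n_nan))
  structure(list(data = data, grid = grid), class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  cat("<volume4d> ", paste(dim(x$data), collapse = " x "), " on ", sep = "")
  print(x$grid)
  invisible(x)
}

#' Construct an integer label map
#'
#' @param labels integer 3D array; 0 is background, positive codes index
#'   `names`.
#' @param grid the [image_grid()].
#' @param names named character vector mapping label to muscle name;
#'   defaults to [calf_muscle_names()].
#' @return Object of class `label_map`.
#' @export
label_map <- function(labels, grid, names = calf_muscle_names()) {
  labels <- unclass(labels)
  attributes(labels) <- list(dim = dim(labels))
  if (length(dim(labels)) != 3L) stop("label map must be a 3D array")
  if (!all(dim(labels) == grid$shape))
    stop("label dimensions do not match grid shape")
  if (any(!is.finite(labels)) || any(labels != round(labels)))
    stop("labels must be finite integers")
  storage.mode(labels) <- "integer"
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  unknown <- setdiff(as.character(present), base::names(names))
  if (length(unknown))
    stop("labels without a name-table entry: ", paste(unknown, collapse = ", "))
  structure(list(labels = labels, grid = grid, names = names),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  present <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat("<label_map> ", length(present), " label(s): ",
      paste(x$names[as.character(present)], collapse = ", "), "\n", sep = "")
  print(x$grid)
  invisible(x)
}

labels_present <- function(lmap) {
  setdiff(sort(unique(as.vector(lmap$labels))), 0L)
}

grid_from_nifti <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  image_grid(dim(img)[1:3], affine = structure(RNifti::xform(img),
                                               dimnames = NULL))
}

#' Read a NIfTI-1/2 volume
#'
#' Integer-typed files (NIfTI datatypes uint8/int16/int32/uint16/uint32)
#' are returned as a [label_map()]; floating-point files as a
#' [as_volume()] `volume4d`. Data and voxel-to-world affine are preserved
#' losslessly. Files containing NaN voxels are rejected with the offending
#' voxel count.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param names name table used when the file is integer-typed (see
#'   [label_map()]).
#' @return A `volume4d` or `label_map`.
#' @export
read_nifti <- function(path, names = calf_muscle_names()) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  nd <- length(dim(img))
  if (nd < 3L)
    stop("expected a 3D or 4D NIfTI volume; file is ", nd, "-dimensional")
  if (nd > 4L) stop("NIfTI volumes above 4D are not supported")
  grid <- grid_from_nifti(img)
  dt <- RNifti::niftiHeader(img)$datatype
  integer_codes <- c(2L, 4L, 8L, 256L, 512L, 768L)
  dat <- array(as.numeric(img), dim = dim(img))
  n_nan <- sum(!is.finite(dat))
  if (n_nan > 0L)
    stop(sprintf("NIfTI file contains %d non-finite voxel(s): %s", n_nan, path))
  if (dt %in% integer_codes) {
    if (nd != 3L) stop("integer-typed label file must be 3D")
    label_map(dat, grid, names = names)
  } else {
    as_volume(dat, grid)
  }
}

#' Write a volume or label map as NIfTI
#'
#' `volume4d` objects are written as float64 (lossless round trip for R
#' doubles); `label_map` objects as int32. The grid affine is stored in
#' the sform (code 2).
#'
#' @param x a `volume4d` or `label_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "label_map")) {
    dat <- x$labels
    datatype <- "int32"
    grid <- x$grid
  } else if (inherits(x, "volume4d")) {
    dat <- x$data
    datatype <- "double"
    grid <- x$grid
  } else stop("'x' must be a volume4d or label_map")
  img <- RNifti::asNifti(dat, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
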