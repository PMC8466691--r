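#' Write streamlines to a TCK (MRtrix track) file
#'
#' Points are stored as little-endian float32 world-mm triplets; streamlines
#' are separated by a NaN triplet and the stream is terminated by an Inf
#' triplet. An empty set produces a valid file with zero streamlines.
#'
#' @param tracts a `tract_set` (see [track_muscle()]) or a list of n x 3
#'   numeric matrices of world-mm points.
#' @param path output path (conventionally `.tck`).
#' @export
write_tck <- function(tracts, path) {
  sl <- if (inherits(tracts, "tract_set")) tracts$streamlines else tracts
  if (!is.list(sl)) stop("'tracts' must be a tract_set or list of matrices")
  hdr_fixed <- c("mrtrix tracks", "datatype: Float32LE",
                 sprintf("count: %d", length(sl)))
  # 'file: . N' must state the data offset, which depends on its own length;
  # pad the offset field to make the computation closed-form
  offset_line <- sprintf("file: . %6d", 0L)
  n_bytes <- sum(nchar(c(hdr_fixed, offset_line, "END"), type = "bytes")) +
    length(hdr_fixed) + 2L          # newlines
  offset_line <- sprintf("file: . %6d", n_bytes)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr_fixed, offset_line, "END"), con, sep = "\n")
  for (m in sl) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("streamline matrices must have 3 columns")
    writeBin(as.vector(t(m)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a TCK (MRtrix track) file
#'
#' @param path path to a `.tck` file written by [write_tck()] or MRtrix.
#' @return List of n x 3 matrices of world-mm points (possibly empty).
#' @export
read_tck <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # locate END of the text header
  txt_end <- NULL
  hdr_lines <- character()
  pos <- 1L
  while (pos <= length(raw)) {
    nl <- which(raw[pos:length(raw)] == as.raw(10L))[1]
    if (is.na(nl)) break
    line <- rawToChar(raw[pos:(pos + nl - 2L)])
    hdr_lines <- c(hdr_lines, line)
    pos <- pos + nl
    if (identical(line, "END")) { txt_end <- pos - 1L; break }
  }
  if (is.null(txt_end) || !identical(hdr_lines[1], "mrtrix tracks"))
    stop("not a TCK file: ", path)
  if (!any(grepl("^datatype:\\s*Float32LE\\s*$", hdr_lines)))
    stop("unsupported TCK datatype (only Float32LE)")
  file_line <- grep("^file: \\.", hdr_lines, value = TRUE)
  offset <- if (length(file_line)) as.integer(sub("^file: \\.\\s*", "", file_line[1]))
            else txt_end
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric", size = 4L,
                  n = (length(raw) - offset) %/% 4L, endian = "little")
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  is_inf <- is.infinite(pts[, 1])
  if (any(is_inf)) pts <- pts[seq_len(which(is_inf)[1] - 1L), , drop = FALSE]
  breaks <- which(is.nan(pts[, 1]))
  out <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start) out[[length(out) + 1L]] <- pts[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
  }
  if (start <= nrow(pts)) out[[length(out) + 1L]] <- pts[start:nrow(pts), , drop = FALSE]
  out
}
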