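# Scalar maps and on-disk formats: NIfTI volumes, MRtrix TCK tractograms,
# per-streamline SIFT2 weight text files.

#' Scalar map on a regular voxel grid
#'
#' A 3-D voxel grid of one diffusion-derived parameter, with a diagonal RAS
#' affine: world (mm) coordinates relate to 1-based voxel indices by
#' `world = origin + (index - 0.5) * voxel_mm`, i.e. the centre of voxel
#' (1,1,1) sits half a voxel from `origin`. Integer-valued grids double as
#' parcellation label volumes.
#'
#' @param data 3-D numeric array.
#' @param voxel_mm voxel edge lengths (mm), length 3 (or scalar).
#' @param origin world position (mm) of the grid corner, length 3.
#' @param param name of the mapped parameter (e.g. "FA", "MD", "labels").
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(data, voxel_mm = c(2.5, 2.5, 2.5), origin = c(0, 0, 0),
                       param = "value") {
  if (length(dim(data)) != 3) stopf("data must be a 3-D array")
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  stopifnot(length(voxel_mm) == 3, all(voxel_mm > 0), length(origin) == 3)
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm),
                 origin = as.numeric(origin), param = param),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("Scalar map '%s': %s voxels of %s mm, range [%g, %g]\n",
              x$param, paste(dim(x$data), collapse = " x "),
              paste(x$voxel_mm, collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

# Continuous (1-based, voxel-centre) indices of world-mm points (n x 3).
world_to_voxel <- function(map, xyz) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  sweep(sweep(xyz, 2, map$origin), 2, map$voxel_mm, "/") + 0.5
}

voxel_to_world <- function(map, ijk) {
  if (!is.matrix(ijk)) ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk - 0.5, 2, map$voxel_mm, "*"), 2, map$origin, "+")
}

map_affine <- function(map) {
  aff <- diag(c(map$voxel_mm, 1))
  aff[1:3, 4] <- map$origin + map$voxel_mm / 2  # world of voxel (1,1,1)
  aff
}

#' Read and write scalar maps as NIfTI
#'
#' Serializes a [scalar_map()] (or plain 3-D/4-D array) to a NIfTI-1 file
#' with its diagonal RAS affine, and reads one back.
#'
#' @param map a `scalar_map`, or an array for raw volumes (e.g. 4-D DWI).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param voxel_mm,origin,param grid geometry for arrays / on reading.
#' @return `read_nifti_map`: a `scalar_map` (3-D files) or plain array with
#'   geometry attributes (4-D files).
#' @export
write_nifti_map <- function(map, path, voxel_mm = c(2.5, 2.5, 2.5),
                            origin = c(0, 0, 0)) {
  if (inherits(map, "scalar_map")) {
    arr <- map$data; voxel_mm <- map$voxel_mm; origin <- map$origin
  } else arr <- map
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- origin + voxel_mm / 2
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_map
#' @export
read_nifti_map <- function(path, param = "value") {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  voxel_mm <- abs(diag(aff)[1:3])
  origin <- aff[1:3, 4] - voxel_mm / 2
  arr <- as.array(img)
  # singleton trailing dimensions can be dropped on disk; restore to 3-D
  if (length(dim(arr)) < 3) dim(arr) <- c(dim(arr), rep(1L, 3 - length(dim(arr))))
  if (length(dim(arr)) == 3)
    scalar_map(arr, voxel_mm, origin, param)
  else
    structure(arr, voxel_mm = voxel_mm, origin = origin)
}

#' Read and write MRtrix TCK tractograms
#'
#' Streamlines are stored in world mm coordinates as little-endian float32
#' triplets, separated by NaN triplets and terminated by an Inf triplet,
#' after a plain-text header -- the MRtrix "tracks" format.
#'
#' @param streamlines list of n x 3 vertex matrices (world mm).
#' @param path file path.
#' @return `read_tck`: a list of vertex matrices.
#' @export
write_tck <- function(streamlines, path) {
  stopifnot(is.list(streamlines))
  for (s in streamlines)
    if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 2)
      stopf("each streamline must be an n x 3 matrix with n >= 2")
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           sprintf("count: %d", length(streamlines)))
  # the 'file' line points at the byte offset where binary data starts
  offset_line <- function(off) sprintf("file: . %d", off)
  body_len <- function(off) {
    txt <- paste0(paste(c(hdr, offset_line(off), "END"), collapse = "\n"), "\n")
    nchar(txt, type = "bytes")
  }
  off <- body_len(1000)          # fixed-point: offset depends on its own width
  off <- body_len(off)
  txt <- paste0(paste(c(hdr, offset_line(off), "END"), collapse = "\n"), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL)
  pad <- off - nchar(txt, type = "bytes")
  if (pad > 0) writeBin(raw(pad), con)
  for (s in streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  hdr_end <- grepRaw("\nEND\n", raw_all)
  if (length(hdr_end) == 0) stopf("not a TCK file: missing END header line")
  hdr <- strsplit(rawToChar(raw_all[1:hdr_end]), "\n")[[1]]
  if (hdr[1] != "mrtrix tracks") stopf("not a TCK file: bad magic line")
  file_ln <- grep("^file:", hdr, value = TRUE)
  off <- as.integer(sub(".* ", "", file_ln[1]))
  dt <- sub("^datatype: *", "", grep("^datatype:", hdr, value = TRUE)[1])
  endian <- if (grepl("BE$", dt)) "big" else "little"
  vals <- readBin(raw_all[(off + 1):length(raw_all)], "numeric",
                  n = (length(raw_all) - off) / 4, size = 4, endian = endian)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  fin <- is.finite(m[, 1])
  ends <- which(!fin & !is.nan(m[, 1]))  # Inf terminator
  stop_at <- if (length(ends)) ends[1] - 1 else nrow(m)
  seps <- c(which(is.nan(m[seq_len(stop_at), 1])), stop_at + 1)
  out <- list()
  start <- 1
  for (sp in seps) {
    if (sp > start) out[[length(out) + 1]] <- m[start:(sp - 1), , drop = FALSE]
    start <- sp + 1
  }
  out
}

#' Read and write SIFT2 streamline weights
#'
#' Plain-text weights, one positive float per streamline, whitespace
#' separated (single row, as written by the SIFT2 tool).
#'
#' @param weights numeric vector of positive weights.
#' @param path file path.
#' @return `read_sift2_weights`: numeric vector.
#' @export
write_sift2_weights <- function(weights, path) {
  writeLines(paste(sprintf("%.10g", weights), collapse = " "), path)
  invisible(path)
}

#' @rdname write_sift2_weights
#' @export
read_sift2_weights <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (!length(v)) stopf("no weights in %s", path)
  v
}
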