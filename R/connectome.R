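# Tractometry-weighted connectome construction: sample a scalar map along
# each streamline, take the per-streamline median, assign streamlines to
# parcel pairs, and average medians per edge with SIFT2 weights.

#' Sample a scalar map along a streamline
#'
#' Returns one map value per streamline vertex. Vertices outside the map
#' volume are dropped with a warning; it is an error for all vertices to
#' fall outside. Trilinear interpolation (the default, as used by the usual
#' streamline sampler) interpolates between the 8 surrounding voxel
#' centres, clamping at the volume faces; nearest-neighbour sampling
#' returns the value of the containing voxel and is exact for
#' piecewise-constant maps.
#'
#' @param map a [scalar_map()].
#' @param streamline n x 3 matrix of world-mm vertices.
#' @param interp `"trilinear"` or `"nearest"`.
#' @return numeric vector, one value per retained vertex.
#' @export
sample_map_along_streamline <- function(map, streamline,
                                        interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(map, "scalar_map"))
  if (!is.matrix(streamline) || ncol(streamline) != 3)
    stopf("streamline must be an n x 3 matrix of world coordinates")
  d <- dim(map$data)
  cidx <- world_to_voxel(map, streamline)
  inb <- cidx[, 1] >= 0.5 & cidx[, 1] <= d[1] + 0.5 &
    cidx[, 2] >= 0.5 & cidx[, 2] <= d[2] + 0.5 &
    cidx[, 3] >= 0.5 & cidx[, 3] <= d[3] + 0.5
  if (!any(inb)) stopf("all %d vertices fall outside the map volume",
                       nrow(streamline))
  if (!all(inb))
    warnf("%d of %d vertices outside the map volume were dropped",
          sum(!inb), nrow(streamline))
  cidx <- cidx[inb, , drop = FALSE]
  if (interp == "nearest") {
    ijk <- pmin(pmax(round(cidx), 1), matrix(d, nrow(cidx), 3, byrow = TRUE))
    return(map$data[ijk])
  }
  lo <- pmin(pmax(floor(cidx), 1), matrix(d, nrow(cidx), 3, byrow = TRUE))
  hi <- pmin(lo + 1, matrix(d, nrow(cidx), 3, byrow = TRUE))
  fr <- pmin(pmax(cidx - floor(cidx), 0), 1)
  fr[floor(cidx) < 1] <- 0            # clamp below the first voxel centre
  fr[floor(cidx) >= matrix(d, nrow(cidx), 3, byrow = TRUE)] <- 0
  val <- numeric(nrow(cidx))
  for (v in seq_len(nrow(cidx))) {
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- (if (dx) fr[v, 1] else 1 - fr[v, 1]) *
        (if (dy) fr[v, 2] else 1 - fr[v, 2]) *
        (if (dz) fr[v, 3] else 1 - fr[v, 3])
      if (wgt > 0)
        acc <- acc + wgt * map$data[if (dx) hi[v, 1] else lo[v, 1],
                                    if (dy) hi[v, 2] else lo[v, 2],
                                    if (dz) hi[v, 3] else lo[v, 3]]
    }
    val[v] <- acc
  }
  val
}

#' Median of per-vertex values along a streamline
#'
#' The per-streamline summary used for tractometry edge weighting: the
#' median is robust to outlying vertex values (e.g. partial-volume voxels at
#' bundle ends) and assumes nothing about the value distribution along the
#' bundle. Even-length inputs average the middle pair.
#'
#' @param values numeric vector with at least one value.
#' @return the median value.
#' @export
streamline_median <- function(values) {
  if (!length(values)) stopf("cannot take the median of zero sampled values")
  stats::median(values)
}

#' Assign a streamline to a parcel pair
#'
#' Maps each streamline endpoint to the nearest nonzero parcellation label
#' within `search_radius_mm` (the assignment tool's conventional 2 mm
#' default); if both endpoints find a parcel the streamline is assigned to
#' the edge `(min, max)`, otherwise it is unassigned.
#'
#' @param streamline n x 3 matrix of world-mm vertices.
#' @param parcellation integer-label [scalar_map()] (0 = background).
#' @param search_radius_mm endpoint search radius (mm).
#' @return integer vector `c(node_a, node_b)` with `node_a <= node_b`, or
#'   `NULL` if unassigned.
#' @export
assign_streamline_to_edge <- function(streamline, parcellation,
                                      search_radius_mm = 2) {
  stopifnot(inherits(parcellation, "scalar_map"))
  lab_at <- function(p) {
    d <- dim(parcellation$data)
    ci <- world_to_voxel(parcellation, p)
    ijk <- round(ci)
    if (all(ijk >= 1 & ijk <= d)) {
      l <- parcellation$data[ijk[1], ijk[2], ijk[3]]
      if (l > 0) return(l)
    }
    # nearest nonzero voxel centre within the search radius
    rad <- ceiling(search_radius_mm / parcellation$voxel_mm)
    best <- 0; bestd <- Inf
    for (dx in -rad[1]:rad[1]) for (dy in -rad[2]:rad[2]) for (dz in -rad[3]:rad[3]) {
      q <- ijk + c(dx, dy, dz)
      if (any(q < 1) || any(q > d)) next
      l <- parcellation$data[q[1], q[2], q[3]]
      if (l == 0) next
      dist <- vnorm(voxel_to_world(parcellation, q) - p)
      if (dist <= search_radius_mm && dist < bestd) { best <- l; bestd <- dist }
    }
    best
  }
  a <- lab_at(streamline[1, ])
  b <- lab_at(streamline[nrow(streamline), ])
  if (a == 0 || b == 0) return(NULL)
  as.integer(c(min(a, b), max(a, b)))
}

new_connectome <- function(mat, weighting, transformed = FALSE,
                           node_labels = NULL) {
  n <- nrow(mat)
  if (is.null(node_labels)) node_labels <- sprintf("parcel_%03d", seq_len(n))
  dimnames(mat) <- list(node_labels, node_labels)
  structure(list(matrix = mat, weighting = weighting,
                 transformed = transformed, node_labels = node_labels),
            class = "weighted_connectome")
}

#' Build a microstructure-weighted connectome
#'
#' The tractometry weighting rule: each streamline contributes the median of
#' the scalar map sampled at its vertices; the weight of edge (a, b) is the
#' SIFT2-weighted mean of those medians over all streamlines assigned to
#' that parcel pair. Streamlines with both endpoints in the same parcel are
#' recorded as self-loops and then zeroed on the diagonal; pairs with no
#' assigned streamline get weight 0. The matrix is symmetric by construction
#' (undirected assignment) and no thresholding or pruning is applied.
#'
#' @param streamlines list of n x 3 world-mm vertex matrices (or a
#'   [generate_tractogram_fixture()] result, from which all other arguments
#'   default).
#' @param sift2_weights positive per-streamline weights, same length.
#' @param map [scalar_map()] supplying the edge-weighting parameter.
#' @param parcellation integer-label [scalar_map()].
#' @param weighting name tag for the weighting parameter (e.g. "FA").
#' @param interp vertex sampling: `"trilinear"` (default) or `"nearest"`.
#' @param search_radius_mm endpoint assignment radius (mm).
#' @param n_nodes number of nodes; defaults to the largest label.
#' @return object of class `weighted_connectome`: the symmetric, zero
#'   diagonal `matrix` plus `weighting`, `transformed` and `node_labels`.
#' @export
build_weighted_connectome <- function(streamlines, sift2_weights = NULL,
                                      map = NULL, parcellation = NULL,
                                      weighting = "value",
                                      interp = c("trilinear", "nearest"),
                                      search_radius_mm = 2, n_nodes = NULL) {
  interp <- match.arg(interp)
  if (is.list(streamlines) && !is.null(streamlines$streamlines)) {
    fx <- streamlines
    streamlines <- fx$streamlines
    if (is.null(sift2_weights)) sift2_weights <- fx$sift2_weights
    if (is.null(map)) map <- fx$map
    if (is.null(parcellation)) parcellation <- fx$parcellation
  }
  if (!length(streamlines)) stopf("empty tractogram")
  if (length(sift2_weights) != length(streamlines))
    stopf("mismatched lengths: %d streamlines but %d SIFT2 weights",
          length(streamlines), length(sift2_weights))
  if (any(sift2_weights < 0)) stopf("SIFT2 weights must be nonnegative")
  if (is.null(n_nodes)) n_nodes <- max(parcellation$data)
  num <- matrix(0, n_nodes, n_nodes)
  den <- matrix(0, n_nodes, n_nodes)
  for (s in seq_along(streamlines)) {
    e <- assign_streamline_to_edge(streamlines[[s]], parcellation,
                                   search_radius_mm)
    if (is.null(e)) next
    med <- streamline_median(
      sample_map_along_streamline(map, streamlines[[s]], interp))
    num[e[1], e[2]] <- num[e[1], e[2]] + sift2_weights[s] * med
    den[e[1], e[2]] <- den[e[1], e[2]] + sift2_weights[s]
  }
  W <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0)
  W <- W + t(W) - diag(diag(W))
  diag(W) <- 0
  new_connectome(W, weighting)
}

#' Build a streamline-count (NOS) connectome
#'
#' Reference weighting: the weight of edge (a, b) is the sum of the SIFT2
#' weights of its assigned streamlines (a fibre-density-consistent
#' streamline count). Same assignment and symmetry conventions as
#' [build_weighted_connectome()].
#'
#' @inheritParams build_weighted_connectome
#' @return a `weighted_connectome` with weighting "NOS".
#' @export
build_nos_connectome <- function(streamlines, sift2_weights = NULL,
                                 parcellation = NULL, search_radius_mm = 2,
                                 n_nodes = NULL) {
  if (is.list(streamlines) && !is.null(streamlines$streamlines)) {
    fx <- streamlines
    streamlines <- fx$streamlines
    if (is.null(sift2_weights)) sift2_weights <- fx$sift2_weights
    if (is.null(parcellation)) parcellation <- fx$parcellation
  }
  if (!length(streamlines)) {
    if (is.null(n_nodes)) n_nodes <- max(parcellation$data)
    return(new_connectome(matrix(0, n_nodes, n_nodes), "NOS"))
  }
  if (length(sift2_weights) != length(streamlines))
    stopf("mismatched lengths: %d streamlines but %d SIFT2 weights",
          length(streamlines), length(sift2_weights))
  if (is.null(n_nodes)) n_nodes <- max(parcellation$data)
  W <- matrix(0, n_nodes, n_nodes)
  for (s in seq_along(streamlines)) {
    e <- assign_streamline_to_edge(streamlines[[s]], parcellation,
                                   search_radius_mm)
    if (is.null(e)) next
    W[e[1], e[2]] <- W[e[1], e[2]] + sift2_weights[s]
  }
  W <- W + t(W) - diag(diag(W))
  diag(W) <- 0
  new_connectome(W, "NOS")
}

#' Negative-log transform of a connectome
#'
#' For weightings where larger values mean weaker coupling (mean diffusivity,
#' extra-cellular fraction), network analysis requires inverting the scale:
#' every nonzero entry w becomes -ln(w) and zero entries stay zero (absent
#' edges). All nonzero entries are expected in (0, 1) -- true for MD in
#' mm^2/s and for volume fractions -- otherwise the transform would produce
#' nonpositive weights: entries >= 1 are clamped out (set to 0) with a
#' warning reporting the count. Transforming a weighting other than MD/ECVF
#' is flagged with an advisory warning.
#'
#' @param conn a `weighted_connectome`.
#' @return the transformed `weighted_connectome` (`transformed = TRUE`).
#' @export
neg_log_transform <- function(conn) {
  stopifnot(inherits(conn, "weighted_connectome"))
  if (!conn$weighting %in% c("MD", "ECVF", "value"))
    warnf("-log transform is conventionally applied to MD/ECVF weightings, not %s",
          conn$weighting)
  W <- conn$matrix
  bad <- W >= 1
  if (any(bad)) {
    warnf("%d entr%s >= 1 clamped out (set to 0) by the -log transform",
          sum(bad), if (sum(bad) == 1) "y" else "ies")
    W[bad] <- 0
  }
  nz <- W > 0
  W[nz] <- -log(W[nz])
  out <- conn
  out$matrix <- W
  dimnames(out$matrix) <- dimnames(conn$matrix)
  out$transformed <- TRUE
  out
}

#' @export
print.weighted_connectome <- function(x, ...) {
  nz <- sum(x$matrix[upper.tri(x$matrix)] != 0)
  cat(sprintf("%s-weighted connectome%s: %d nodes, %d edges (density %.3f)\n",
              x$weighting, if (x$transformed) " (-log transformed)" else "",
              nrow(x$matrix), nz, connectome_density(x)))
  invisible(x)
}

#' @export
as.matrix.weighted_connectome <- function(x, ...) x$matrix

#' @export
plot.weighted_connectome <- function(x, ...) {
  n <- nrow(x$matrix)
  graphics::image(seq_len(n), seq_len(n), t(x$matrix[n:1, ]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "node", ylab = "node",
                  main = sprintf("%s-weighted connectome", x$weighting), ...)
  invisible(x)
}

#' Write and read a connectome as CSV with a JSON sidecar
#'
#' The CSV holds the full N x N matrix, comma separated, with one header row
#' of node labels; a sidecar JSON (same path with extension `.json`) carries
#' the weighting name and transform flag.
#'
#' @param conn a `weighted_connectome`.
#' @param path CSV file path.
#' @return `read_connectome_csv`: a `weighted_connectome`.
#' @export
write_connectome_csv <- function(conn, path) {
  stopifnot(inherits(conn, "weighted_connectome"))
  utils::write.table(conn$matrix, path, sep = ",", row.names = FALSE,
                     col.names = conn$node_labels, qmethod = "double")
  meta <- list(weighting = conn$weighting, transformed = conn$transformed,
               n_nodes = nrow(conn$matrix))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(path) {
  mat <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
  else list(weighting = "value", transformed = FALSE)
  new_connectome(unname(mat), meta$weighting, isTRUE(meta$transformed),
                 colnames(mat))
}
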