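#' Multi-shell diffusion acquisition scheme
#'
#' An acquisition scheme pairs one b-value (diffusion weighting, s/mm^2) with
#' one gradient direction per acquired volume. Volumes with a b-value at or
#' below `b0_threshold` are treated as unweighted (b = 0) images; their
#' direction is irrelevant and may be the zero vector. Directions of weighted
#' volumes are renormalized to unit length on construction.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs gradient directions: an n x 3 matrix (or a list of 3-vectors),
#'   one row per volume.
#' @param b0_threshold b-value (s/mm^2) at or below which a volume counts as
#'   b = 0. Default 50, the usual dMRI convention.
#' @return An object of class `acquisition_scheme`: a list with elements
#'   `bvals`, `bvecs` (n x 3 matrix) and `b0_threshold`.
#' @examples
#' sch <- make_scheme(c(0, 1000), rbind(c(0, 0, 0), c(2, 0, 0)))
#' sch$bvecs[2, ]  # renormalized to (1, 0, 0)
#' @export
make_scheme <- function(bvals, bvecs, b0_threshold = 50) {
  if (is.list(bvecs)) bvecs <- do.call(rbind, bvecs)
  if (is.null(dim(bvecs))) bvecs <- matrix(bvecs, ncol = 3)
  bvecs <- as.matrix(bvecs)
  bvals <- as.numeric(bvals)
  if (!is.numeric(b0_threshold) || length(b0_threshold) != 1 || b0_threshold < 0)
    stopf("b0_threshold must be a single nonnegative number")
  if (ncol(bvecs) != 3)
    stopf("bvecs must have 3 columns (x, y, z), got %d", ncol(bvecs))
  if (length(bvals) != nrow(bvecs))
    stopf("length mismatch: %d b-values but %d directions",
          length(bvals), nrow(bvecs))
  if (!all(is.finite(bvals)) || !all(is.finite(bvecs)))
    stopf("b-values and directions must be finite")
  if (any(bvals < 0)) stopf("negative b-value(s): %s",
                            paste(bvals[bvals < 0], collapse = ", "))
  nrm <- row_norms(bvecs)
  dwi <- bvals > b0_threshold
  if (any(dwi & nrm < 1e-12))
    stopf("zero-norm direction for weighted volume(s) %s",
          paste(which(dwi & nrm < 1e-12), collapse = ", "))
  bvecs[dwi, ] <- bvecs[dwi, , drop = FALSE] / nrm[dwi]
  structure(list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  tb <- shell_table(x)
  cat(sprintf("Multi-shell acquisition scheme: %d volumes\n", length(x$bvals)))
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  b = %6g s/mm^2 : %3d volume(s)\n", tb$bval[i], tb$n[i]))
  invisible(x)
}

#' Shell membership of an acquisition scheme
#'
#' Groups volumes into shells by exact b-value, with every volume at or below
#' the scheme's `b0_threshold` pooled into the b = 0 shell, so that each
#' volume belongs to exactly one shell.
#'
#' @param scheme an [make_scheme()] object.
#' @return data.frame with columns `bval` (nominal shell b-value; 0 for the
#'   unweighted shell) and `n` (volume count), ordered by b-value.
#' @export
shell_table <- function(scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  b <- scheme$bvals
  b[b <= scheme$b0_threshold] <- 0
  tb <- table(b)
  data.frame(bval = as.numeric(names(tb)), n = as.integer(tb))
}

#' Near-uniform unit directions by electrostatic repulsion
#'
#' Spreads `n` directions quasi-uniformly over the sphere by minimizing the
#' Coulomb energy of the antipodally symmetrized point set (each direction
#' interacts with every other direction and its antipode), the standard layout
#' for HARDI gradient tables. Deterministic for a fixed seed: points are
#' initialized from a seeded uniform draw and refined by a fixed number of
#' projected gradient steps.
#'
#' @param n number of directions.
#' @param seed integer seed for the initial configuration.
#' @param n_iter number of descent iterations.
#' @return n x 3 matrix of unit row vectors.
#' @export
sphere_directions <- function(n, seed = 0, n_iter = 300) {
  stopifnot(is_count(n), n >= 1)
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  p <- with_local_seed(seed, {
    m <- matrix(stats::rnorm(3 * n), n, 3)
    m / row_norms(m)
  })
  step <- 0.1
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(-p[-i, , drop = FALSE], 2, p[i, ], "+")   # p_i - p_j
      d2 <- sweep(p[-i, , drop = FALSE], 2, p[i, ], "+")    # p_i + p_j
      r1 <- pmax(row_norms(d1), 1e-9)
      r2 <- pmax(row_norms(d2), 1e-9)
      frc[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    p <- p + step * frc / max(row_norms(frc))
    p <- p / row_norms(p)
    step <- step * 0.985
  }
  # canonical hemisphere and stable ordering for reproducibility of output
  flip <- p[, 3] < 0 | (p[, 3] == 0 & p[, 2] < 0) |
    (p[, 3] == 0 & p[, 2] == 0 & p[, 1] < 0)
  p[flip, ] <- -p[flip, , drop = FALSE]
  p[order(p[, 3], p[, 2], p[, 1]), , drop = FALSE]
}

# Assemble a multi-shell scheme with n0 unweighted volumes dispersed evenly
# between the weighted ones; shells listed as c(bval = n_directions).
build_protocol <- function(n0, shells, seed) {
  bv <- numeric(0); dirs <- NULL
  for (i in seq_along(shells)) {
    b <- as.numeric(names(shells)[i])
    d <- sphere_directions(shells[[i]], seed = seed + i)
    bv <- c(bv, rep(b, shells[[i]]))
    dirs <- rbind(dirs, d)
  }
  n <- length(bv) + n0
  # evenly dispersed b0 positions (first volume is always b0)
  pos0 <- unique(round(seq(1, n, length.out = n0)))
  bvals <- numeric(n); bvecs <- matrix(0, n, 3)
  bvals[pos0] <- 0
  bvals[-pos0] <- bv
  bvecs[-pos0, ] <- dirs
  make_scheme(bvals, bvecs)
}

#' Built-in four-shell HARDI protocol
#'
#' The four-shell scheme: 150 volumes in total, with 13 unweighted (b = 0)
#' images and shells of 6 directions at b = 700, 20 at b = 1000, 45 at
#' b = 2000 and 66 at b = 3000 s/mm^2. The per-shell direction sets are
#' deterministic electrostatic-repulsion layouts (see [sphere_directions()]).
#'
#' @param seed integer seed controlling the direction layout.
#' @return an [make_scheme()] object with 150 volumes.
#' @export
four_shell_protocol <- function(seed = 0) {
  build_protocol(13, c("700" = 6, "1000" = 20, "2000" = 45, "3000" = 66), seed)
}

#' Built-in two-shell protocol
#'
#' The two-shell scheme conventionally used for NODDI fitting: 99 volumes,
#' with 9 unweighted images, 30 directions at b = 1000 and 60 directions at
#' b = 2600 s/mm^2.
#'
#' @inheritParams four_shell_protocol
#' @return an [make_scheme()] object with 99 volumes.
#' @export
two_shell_protocol <- function(seed = 0) {
  build_protocol(9, c("1000" = 30, "2600" = 60), seed)
}

#' Read and write FSL-style bval/bvec gradient files
#'
#' The FSL dialect stores b-values as a single whitespace-separated row and
#' directions as three rows (x, y and z components). `read_bval_bvec` parses
#' a pair of such files into an acquisition scheme; `write_bval_bvec` writes
#' a scheme back out. Values round-trip to at least 6 significant digits.
#'
#' @param bval_file,bvec_file paths to the gradient text files.
#' @param b0_threshold passed to [make_scheme()].
#' @return `read_bval_bvec`: an `acquisition_scheme`. `write_bval_bvec`:
#'   invisibly, the two file paths.
#' @export
read_bval_bvec <- function(bval_file, bvec_file, b0_threshold = 50) {
  parse_rows <- function(path) {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    lapply(ln, function(l) {
      tok <- strsplit(trimws(l), "[ \t]+")[[1]]
      v <- suppressWarnings(as.numeric(tok))
      if (anyNA(v)) stopf("non-numeric token in %s: '%s'",
                          path, tok[which(is.na(v))[1]])
      v
    })
  }
  bv <- parse_rows(bval_file)
  if (length(bv) != 1)
    stopf("bval file must contain one row, found %d", length(bv))
  vec <- parse_rows(bvec_file)
  if (length(vec) != 3)
    stopf("bvec file must contain three rows (x, y, z), found %d", length(vec))
  if (length(unique(lengths(vec))) != 1 || length(vec[[1]]) != length(bv[[1]]))
    stopf("row length mismatch between bval (%d) and bvec (%s)",
          length(bv[[1]]), paste(lengths(vec), collapse = "/"))
  make_scheme(bv[[1]], cbind(vec[[1]], vec[[2]], vec[[3]]), b0_threshold)
}

#' @param scheme an `acquisition_scheme` to serialize.
#' @rdname read_bval_bvec
#' @export
write_bval_bvec <- function(scheme, bval_file, bvec_file) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  fmt <- function(x) paste(sprintf("%.8g", x), collapse = " ")
  writeLines(fmt(scheme$bvals), bval_file)
  writeLines(c(fmt(scheme$bvecs[, 1]), fmt(scheme$bvecs[, 2]),
               fmt(scheme$bvecs[, 3])), bvec_file)
  invisible(c(bval_file, bvec_file))
}
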