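# Synthetic data generators: crossing-fibre phantom DWI, Rician noise,
# two-site replicate values, and tractogram/parcellation fixtures with
# analytically known connectome ground truth. All generators are pure
# functions of their spec and seed.

#' Add Rician noise to magnitude signals
#'
#' Magnitude-MRI noise model: `sqrt((S + e1)^2 + e2^2)` with `e1`, `e2`
#' i.i.d. zero-mean Gaussians of standard deviation `1/snr`, so `snr` is the
#' signal-to-noise ratio of a unit (b = 0) signal. `snr = Inf` returns the
#' input unchanged.
#'
#' @param signal numeric vector/array of nonnegative signal amplitudes.
#' @param snr positive signal-to-noise ratio.
#' @param seed integer seed.
#' @return noisy signal, same shape, always nonnegative.
#' @export
add_rician_noise <- function(signal, snr, seed = 0) {
  if (!is.numeric(snr) || length(snr) != 1 || is.na(snr) || snr <= 0)
    stopf("snr must be a positive number")
  if (is.infinite(snr)) return(signal)
  with_local_seed(seed, {
    s <- 1 / snr
    e1 <- stats::rnorm(length(signal), 0, s)
    e2 <- stats::rnorm(length(signal), 0, s)
    out <- sqrt((signal + e1)^2 + e2^2)
    attributes(out) <- attributes(signal)
    out
  })
}

#' Crossing-fibre phantom specification
#'
#' Describes a digital version of a two-strand diffusion phantom: two fibre
#' bands crossing at `crossing_angle` degrees in the xy-plane, surrounded by
#' free fluid. Voxels are labelled `fluid` (0), `strand1` (1), `strand2` (2)
#' or `crossing` (3); the labels partition the grid. Strand voxels carry a
#' single coherent fibre population; crossing voxels mix the two populations
#' 50/50; fluid voxels are pure free water.
#'
#' @param shape grid dimensions in voxels (length 3).
#' @param voxel_mm voxel size (mm).
#' @param crossing_angle angle between the strands, degrees.
#' @param strand_params [bnoddi_params()] of a strand population (the angles
#'   are overridden by each strand's axis); defaults to a fluid-free, highly
#'   coherent fibre compartment (ODI 0.05).
#' @param snr b0 signal-to-noise ratio of the generated data.
#' @param strand_halfwidth_mm half-width of each strand band (mm).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(15, 15, 5), voxel_mm = 2.5,
                         crossing_angle = 60,
                         strand_params = bnoddi_params(
                           f_csf = 0, nu = 0.7,
                           kappa1 = kappa_from_odi(0.05),
                           kappa2 = 0.2 * kappa_from_odi(0.05)),
                         snr = 30, strand_halfwidth_mm = 4) {
  stopifnot(length(shape) == 3, all(shape >= 3), crossing_angle > 0,
            crossing_angle < 90, inherits(strand_params, "bnoddi_params"))
  if (!(is.numeric(snr) && snr > 0)) stopf("snr must be positive")
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 crossing_angle = crossing_angle,
                 strand_params = strand_params, snr = snr,
                 strand_halfwidth_mm = strand_halfwidth_mm),
            class = "phantom_spec")
}

# Region label for world points: strands are bands about two centre lines
# through the volume midpoint, at +/- half the crossing angle from x.
phantom_labels <- function(spec) {
  half <- spec$crossing_angle * pi / 360  # half-angle in radians
  u1 <- c(cos(half), sin(half), 0)
  u2 <- c(cos(half), -sin(half), 0)
  n1 <- c(-u1[2], u1[1], 0)
  n2 <- c(-u2[2], u2[1], 0)
  dims <- spec$shape
  centre <- dims * spec$voxel_mm / 2
  lab <- array(0L, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    p <- (c(i, j, k) - 0.5) * spec$voxel_mm - centre
    in1 <- abs(sum(p * n1)) <= spec$strand_halfwidth_mm
    in2 <- abs(sum(p * n2)) <= spec$strand_halfwidth_mm
    lab[i, j, k] <- if (in1 && in2) 3L else if (in1) 1L else if (in2) 2L else 0L
  }
  list(labels = lab, axes = rbind(u1, u2))
}

#' Generate phantom DWI data
#'
#' Simulates a 4-D diffusion-weighted volume for a [phantom_spec()] under an
#' acquisition scheme: strand voxels get the single-population dispersed
#' compartment signal along their strand axis, crossing voxels an
#' equal-weight mixture of both populations, fluid voxels the free-water
#' ball; Rician noise is then added at the spec's SNR (seeded,
#' deterministic).
#'
#' @param spec a [phantom_spec()].
#' @param scheme an [make_scheme()] acquisition scheme.
#' @param seed integer seed for the noise.
#' @return list with `dwi` (4-D array, x,y,z,volume), `labels`
#'   (`scalar_map` of region labels: 0 fluid, 1/2 strands, 3 crossing),
#'   `axes` (2 x 3 strand direction matrix), `scheme`, and `spec`.
#' @export
generate_phantom <- function(spec, scheme, seed = 0) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(scheme, "acquisition_scheme"))
  ph <- phantom_labels(spec)
  axang <- function(u) c(acos(u[3]), atan2(u[2], u[1]))
  sig_for <- function(u) {
    aa <- axang(u)
    p <- spec$strand_params
    bingham_noddi_signal(scheme, bnoddi_params(
      f_csf = p$f_csf, nu = p$nu, theta = aa[1], phi = aa[2], psi = p$psi,
      kappa1 = p$kappa1, kappa2 = p$kappa2,
      lambda_csf = p$lambda_csf, lambda_par = p$lambda_par))
  }
  s1 <- sig_for(ph$axes[1, ])
  s2 <- sig_for(ph$axes[2, ])
  sfl <- ball_signal(scheme$bvals, spec$strand_params$lambda_csf)
  sfl[scheme$bvals <= scheme$b0_threshold] <- 1
  n_vol <- length(scheme$bvals)
  dwi <- array(0, c(spec$shape, n_vol))
  flat <- matrix(dwi, ncol = n_vol)
  lab <- as.vector(ph$labels)
  flat[lab == 0L, ] <- rep(sfl, each = sum(lab == 0L))
  flat[lab == 1L, ] <- rep(s1, each = sum(lab == 1L))
  flat[lab == 2L, ] <- rep(s2, each = sum(lab == 2L))
  flat[lab == 3L, ] <- rep((s1 + s2) / 2, each = sum(lab == 3L))
  dwi <- array(add_rician_noise(flat, spec$snr, seed), c(spec$shape, n_vol))
  list(dwi = dwi,
       labels = scalar_map(ph$labels, spec$voxel_mm, param = "labels"),
       axes = ph$axes, scheme = scheme, spec = spec)
}

#' Two-site replicate values with known variance components
#'
#' Draws an n-subjects x 2-sites matrix from the two-way random-effects
#' model underlying the absolute-agreement intraclass correlation:
#' `X_ij = base + subject_i + site_j + error_ij`, the three components
#' Gaussian with the given standard deviations. The population ICC(2,1) of
#' this process is `sigma_subject^2 / (sigma_subject^2 + sigma_site^2 +
#' sigma_error^2)`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param sigma_subject,sigma_site,sigma_error component standard deviations.
#' @param base_value grand mean.
#' @param seed integer seed.
#' @return n_subjects x 2 numeric matrix.
#' @export
generate_two_site_dataset <- function(n_subjects, sigma_subject, sigma_site,
                                      sigma_error, base_value = 0, seed = 0) {
  if (!is_count(n_subjects) || n_subjects < 2) stopf("need n_subjects >= 2")
  if (any(c(sigma_subject, sigma_site, sigma_error) < 0))
    stopf("standard deviations must be nonnegative")
  with_local_seed(seed, {
    subj <- stats::rnorm(n_subjects, 0, sigma_subject)
    site <- stats::rnorm(2, 0, sigma_site)
    err <- matrix(stats::rnorm(2 * n_subjects, 0, sigma_error), n_subjects, 2)
    out <- base_value + outer(subj, site, "+") + err
    colnames(out) <- c("site1", "site2")
    out
  })
}

#' Erode a binary mask with a 3 x 3 x 3 box kernel
#'
#' Morphological erosion: a voxel survives iff it and its full
#' 26-neighbourhood are inside the mask; voxels on the image border never
#' survive. Used to shrink ROI masks away from partial-volume boundaries
#' before extracting ROI statistics.
#'
#' @param mask 3-D array of 0/1 (or logical).
#' @return eroded mask, same type/shape (integer 0/1).
#' @export
erode_mask <- function(mask) {
  if (length(dim(mask)) != 3) stopf("mask must be a 3-D array")
  v <- as.vector(mask)
  if (!all(v %in% c(0, 1))) stopf("mask must be binary (0/1 or logical)")
  m <- array(as.integer(mask), dim(mask))
  d <- dim(m)
  # zero-pad by one voxel so border voxels see an outside zero
  pad <- array(0L, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  out <- array(1L, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    out <- out & pad[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3])]
  }
  array(as.integer(out), d)
}

#' Mean and standard deviation of a map within labelled ROIs
#'
#' Summarizes a scalar map within each labelled region, optionally eroding
#' each region first (3 x 3 x 3 box, [erode_mask()]) to reduce
#' partial-volume contamination, mirroring common ROI practice.
#'
#' @param map a [scalar_map()] (or 3-D array).
#' @param labels integer label volume (`scalar_map` or array), 0 background.
#' @param erode logical; erode each region mask before summarizing.
#' @return data.frame with columns label, n_voxels, mean, sd.
#' @export
roi_stats <- function(map, labels, erode = TRUE) {
  md <- if (inherits(map, "scalar_map")) map$data else map
  lb <- if (inherits(labels, "scalar_map")) labels$data else labels
  stopifnot(all(dim(md) == dim(lb)))
  labs <- sort(setdiff(unique(as.vector(lb)), 0))
  rows <- lapply(labs, function(l) {
    msk <- array(as.integer(lb == l), dim(lb))
    if (erode) msk <- erode_mask(msk)
    vals <- md[msk == 1L]
    data.frame(label = l, n_voxels = length(vals),
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Tractogram/parcellation fixture with analytic connectome ground truth
#'
#' Builds a small synthetic bundle of streamlines over a block parcellation,
#' with per-streamline SIFT2 weights and a piecewise-constant scalar map, and
#' computes the exact edge weights the tractometry connectome must produce
#' (per-streamline medians of the map sampled at the vertices, averaged per
#' edge with SIFT2 weights). Parcels are disjoint axis-aligned blocks laid
#' out on a grid; streamlines connect random parcel pairs through the
#' background with mild sinusoidal curvature, vertices kept off voxel
#' boundaries so that nearest-neighbour sampling is unambiguous.
#'
#' @param n_parcels number of parcels (>= 2).
#' @param n_streamlines number of streamlines.
#' @param map_rule function(label integer vector) -> map value per voxel;
#'   the default assigns background 0.2 and parcel r the value
#'   0.2 + 0.1 * r, giving a piecewise-constant map.
#' @param seed integer seed.
#' @return list (the fixture): `streamlines` (list of n x 3 world-mm vertex
#'   matrices), `sift2_weights`, `parcellation` (`scalar_map` of labels),
#'   `map` (`scalar_map`), `true_edge_weights` (n_parcels x n_parcels
#'   symmetric matrix), `true_nos` (SIFT2-weighted streamline counts),
#'   `edges` (per-streamline parcel pairs).
#' @export
generate_tractogram_fixture <- function(n_parcels = 6, n_streamlines = 40,
                                        map_rule = NULL, seed = 0) {
  if (!is_count(n_parcels) || n_parcels < 2) stopf("need n_parcels >= 2")
  if (is.null(map_rule)) map_rule <- function(lab) 0.2 + 0.1 * lab
  voxel_mm <- 2
  block <- 3L                     # parcel blocks of 3x3x3 voxels
  gap <- 2L
  ncol_grid <- ceiling(sqrt(n_parcels))
  nrow_grid <- ceiling(n_parcels / ncol_grid)
  dims <- c(ncol_grid * block + (ncol_grid + 1) * gap,
            nrow_grid * block + (nrow_grid + 1) * gap,
            block + 2L * gap)
  lab <- array(0L, dims)
  centres <- matrix(0, n_parcels, 3)
  for (r in seq_len(n_parcels)) {
    gx <- (r - 1) %% ncol_grid
    gy <- (r - 1) %/% ncol_grid
    x0 <- gap + gx * (block + gap)
    y0 <- gap + gy * (block + gap)
    lab[x0 + seq_len(block), y0 + seq_len(block), gap + seq_len(block)] <- r
    centres[r, ] <- (c(x0, y0, gap) + block / 2) * voxel_mm
  }
  parc <- scalar_map(lab, voxel_mm, param = "labels")
  mp <- scalar_map(array(map_rule(as.vector(lab)), dims), voxel_mm,
                   param = "synthetic")
  label_of_point <- function(p) {
    ijk <- floor(p / voxel_mm) + 1
    if (any(ijk < 1) || any(ijk > dims)) 0L else lab[ijk[1], ijk[2], ijk[3]]
  }
  with_local_seed(seed, {
    streamlines <- vector("list", n_streamlines)
    edges <- matrix(0L, n_streamlines, 2)
    for (s in seq_len(n_streamlines)) {
      ab <- sort(sample.int(n_parcels, 2))
      edges[s, ] <- ab
      jitter <- function(r) centres[r, ] +
        stats::runif(3, -0.3, 0.3) * block * voxel_mm / 2
      p0 <- jitter(ab[1]); p1 <- jitter(ab[2])
      tseq <- seq(0, 1, length.out = 12)
      pts <- outer(1 - tseq, p0) + outer(tseq, p1)
      # mild curvature in z, amplitude under half a voxel
      pts[, 3] <- pts[, 3] + 0.4 * voxel_mm * sin(pi * tseq) *
        stats::runif(1, -1, 1)
      # nudge vertices off voxel-boundary planes
      onb <- abs(pts / voxel_mm - round(pts / voxel_mm)) < 1e-9
      pts[onb] <- pts[onb] + 1e-6
      streamlines[[s]] <- pts
    }
    w <- exp(stats::rnorm(n_streamlines, 0, 0.5))
    # analytic ground truth from the block geometry
    tw <- matrix(0, n_parcels, n_parcels)
    sw <- matrix(0, n_parcels, n_parcels)
    nos <- matrix(0, n_parcels, n_parcels)
    for (s in seq_len(n_streamlines)) {
      vals <- map_rule(vapply(seq_len(nrow(streamlines[[s]])), function(i)
        label_of_point(streamlines[[s]][i, ]), integer(1)))
      a <- edges[s, 1]; b <- edges[s, 2]
      med <- stats::median(vals)
      tw[a, b] <- tw[a, b] + w[s] * med
      sw[a, b] <- sw[a, b] + w[s]
      nos[a, b] <- nos[a, b] + w[s]
    }
    tw <- ifelse(sw > 0, tw / pmax(sw, .Machine$double.eps), 0)
    tw <- tw + t(tw) - diag(diag(tw))
    nos <- nos + t(nos) - diag(diag(nos))
    diag(tw) <- 0
    diag(nos) <- 0
    list(streamlines = streamlines, sift2_weights = w, parcellation = parc,
         map = mp, true_edge_weights = tw, true_nos = nos, edges = edges)
  })
}
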