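test_that("streamline sampling interpolates and handles bounds", {
  cmap <- scalar_map(array(0.7, c(4, 4, 4)), 2)
  sl <- rbind(c(1, 1, 1), c(3, 3, 3), c(6, 6, 6))
  expect_equal(sample_map_along_streamline(cmap, sl, "trilinear"),
               rep(0.7, 3))
  expect_equal(sample_map_along_streamline(cmap, sl, "nearest"), rep(0.7, 3))

  # two adjacent voxels valued 0 and 1; vertex midway interpolates to 0.5
  grad <- scalar_map(array(0, c(2, 1, 1)), 2)
  grad$data[2, 1, 1] <- 1
  # voxel centres at x = 1 and x = 3; midpoint x = 2
  mid <- rbind(c(2, 1, 1), c(1, 1, 1), c(3, 1, 1))
  expect_equal(sample_map_along_streamline(grad, mid, "trilinear"),
               c(0.5, 0, 1))

  # nearest sampling is exact on piecewise-constant maps
  pc <- scalar_map(array(rep(c(2, 9), each = 4), c(2, 2, 2)), 2)
  v <- rbind(c(1.4, 1.1, 3.2), c(3.3, 2.9, 1.2))
  expect_equal(sample_map_along_streamline(pc, v, "nearest"),
               c(pc$data[1, 1, 2], pc$data[2, 2, 1]))

  expect_warning(
    out <- sample_map_along_streamline(cmap, rbind(c(1, 1, 1), c(99, 1, 1))),
    "dropped")
  expect_length(out, 1)
  expect_error(sample_map_along_streamline(cmap, rbind(c(99, 99, 99))),
               "outside")
})

test_that("streamline medians are the standard median", {
  expect_equal(streamline_median(c(1, 2, 3)), 2)
  expect_equal(streamline_median(c(1, 2, 3, 100)), 2.5)  # outlier-robust
  expect_equal(streamline_median(7.3), 7.3)
  expect_error(streamline_median(numeric(0)), "zero")
})

test_that("endpoint assignment finds the nearest parcel within the radius", {
  lab <- array(0L, c(10, 4, 4))
  lab[1:3, , ] <- 5L
  lab[8:10, , ] <- 12L
  parc <- scalar_map(lab, 2, param = "labels")
  sl <- rbind(c(3, 3, 3), c(10, 4, 4), c(17, 3, 3))
  expect_equal(assign_streamline_to_edge(sl, parc), c(5L, 12L))
  # endpoint in background but within 2 mm of a parcel-5 voxel centre
  sl2 <- rbind(c(6.8, 3, 3), c(17, 3, 3))
  expect_equal(assign_streamline_to_edge(sl2, parc), c(5L, 12L))
  # endpoint too deep in the background: unassigned
  sl3 <- rbind(c(10, 3, 3), c(17, 3, 3))
  expect_null(assign_streamline_to_edge(sl3, parc))
  # both endpoints in one parcel: the self-loop is zeroed on the diagonal
  sl4 <- rbind(c(2, 2, 2), c(4, 4, 4))
  expect_equal(assign_streamline_to_edge(sl4, parc), c(5L, 5L))
  conn <- build_nos_connectome(list(sl4), 1, parc, n_nodes = 12)
  expect_true(all(conn$matrix == 0))
})

test_that("the tractometry connectome matches the analytic fixture oracle", {
  fx <- generate_tractogram_fixture(6, 40, seed = 3)
  conn <- build_weighted_connectome(fx, interp = "nearest")
  expect_lt(max(abs(conn$matrix - fx$true_edge_weights)), 1e-10)
  expect_symmetric_zero_diag(conn$matrix)

  nos <- build_nos_connectome(fx)
  expect_lt(max(abs(nos$matrix - fx$true_nos)), 1e-10)

  # rescaling all SIFT2 weights leaves the weighted mean untouched
  c2 <- build_weighted_connectome(fx$streamlines, fx$sift2_weights * 7,
                                  fx$map, fx$parcellation, interp = "nearest")
  expect_equal(c2$matrix, conn$matrix)

  # a streamline with SIFT2 weight zero contributes nothing
  w0 <- fx$sift2_weights
  w0[5] <- 0
  c3 <- build_weighted_connectome(fx$streamlines, w0, fx$map,
                                  fx$parcellation, interp = "nearest")
  c4 <- build_weighted_connectome(fx$streamlines[-5], w0[-5], fx$map,
                                  fx$parcellation, interp = "nearest")
  expect_equal(c3$matrix, c4$matrix)

  # convexity: edge weights bounded by the sampled map range
  rng <- range(fx$map$data)
  nzw <- conn$matrix[conn$matrix != 0]
  expect_true(all(nzw >= rng[1] - 1e-12 & nzw <= rng[2] + 1e-12))

  expect_error(build_weighted_connectome(fx$streamlines, 1:3, fx$map,
                                         fx$parcellation),
               "mismatched")
  expect_error(build_weighted_connectome(list(), 1, fx$map, fx$parcellation),
               "empty")
})

test_that("NOS weights accumulate and ignore streamline order", {
  lab <- array(0L, c(8, 3, 3))
  lab[1:2, , ] <- 1L
  lab[7:8, , ] <- 2L
  parc <- scalar_map(lab, 2, param = "labels")
  sl <- rbind(c(2, 2, 2), c(14, 3, 3))
  conn <- build_nos_connectome(list(sl, sl, sl), rep(1, 3), parc)
  expect_equal(conn$matrix[1, 2], 3)
  perm <- build_nos_connectome(list(sl, sl, sl)[c(3, 1, 2)], rep(1, 3), parc)
  expect_equal(perm$matrix, conn$matrix)
  empty <- build_nos_connectome(list(), numeric(0), parc)
  expect_true(all(empty$matrix == 0))
})

test_that("the negative-log transform maps entries as specified", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- exp(-1)
  W[2, 3] <- W[3, 2] <- 7.0e-4           # a typical MD in mm^2/s
  conn <- new_connectome <- mwconn:::new_connectome(W, "MD")
  tr <- neg_log_transform(conn)
  expect_true(tr$transformed)
  expect_equal(tr$matrix[1, 2], 1)
  expect_equal(tr$matrix[2, 3], -log(7.0e-4))
  expect_equal(round(tr$matrix[2, 3], 3), 7.264)
  expect_equal(tr$matrix[1, 3], 0)        # absent edges stay absent

  Wbad <- W
  Wbad[1, 3] <- Wbad[3, 1] <- 1.5
  expect_warning(trb <- neg_log_transform(mwconn:::new_connectome(Wbad, "MD")),
                 "clamped")
  expect_equal(trb$matrix[1, 3], 0)
  expect_warning(neg_log_transform(mwconn:::new_connectome(W, "FA")),
                 "conventionally")
})

test_that("connectome CSV + sidecar round-trips with metadata", {
  fx <- generate_tractogram_fixture(5, 20, seed = 4)
  conn <- build_weighted_connectome(fx, weighting = "FA")
  path <- file.path(tempfile(fileext = ".csv"))
  write_connectome_csv(conn, path)
  expect_true(file.exists(sub("\\.csv$", ".json", path)))
  rt <- read_connectome_csv(path)
  expect_equal(rt$matrix, conn$matrix, tolerance = 1e-12)
  expect_equal(rt$weighting, "FA")
  expect_false(rt$transformed)
  expect_equal(rt$node_labels, conn$node_labels)
})
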