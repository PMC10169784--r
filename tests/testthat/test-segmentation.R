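test_that("crop_roi keeps all foreground, round-trips coordinates, and
           errors on empty hearts", {
  ph <- fixture_phantom("normal")
  b <- oracle_backend(ph$truth)
  roi <- crop_roi(ph$image, b)
  d <- dim(roi$roi$data)
  # every foreground truth voxel lies inside the RoI box
  fg <- which(ph$truth$data > 0, arr.ind = TRUE)
  expect_true(all(sweep(fg, 2, roi$offset) >= 1))
  expect_true(all(sweep(fg, 2, roi$offset) <= matrix(d, nrow(fg), 3,
                                                     byrow = TRUE)))
  # RoI voxel + offset indexes the identical intensity in the original
  set.seed(2)
  for (i in 1:20) {
    v <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    w <- v + roi$offset
    expect_identical(roi$roi$data[v[1], v[2], v[3]],
                     ph$image$data[w[1], w[2], w[3]])
  }
  empty <- label_volume(array(0L, dim(ph$truth$data)), ph$truth$spacing)
  expect_error(crop_roi(ph$image, oracle_backend(empty)), "no heart found")
})

test_that("oracle chamber segmentation equals majority-downsampled truth and
           contains no vessel codes", {
  ph <- fixture_phantom("normal")
  b <- oracle_backend(ph$body_truth)
  roi <- crop_roi(ph$image, b)
  seg <- segment_chambers_3d(roi$roi, b)
  expect_equal(dim(seg$data), c(64L, 64L, 64L))
  expect_true(all(seg$data %in% c(0L, chamber_codes(), label_codes()[["Myo"]])))
  # recompute the downsampling rule independently
  truth_roi <- ph$body_truth$data[
    roi$offset[1] + seq_len(dim(roi$roi$data)[1]),
    roi$offset[2] + seq_len(dim(roi$roi$data)[2]),
    roi$offset[3] + seq_len(dim(roi$roi$data)[3])]
  truth_roi[truth_roi %in% c(6L, 7L)] <- 0L
  expected <- cpp_majority_downsample(array(truth_roi, dim(truth_roi)),
                                      dim(truth_roi), c(64L, 64L, 64L), 7L)
  expect_identical(seg$data, array(expected, c(64, 64, 64)))
})

test_that("majority downsampling lets background lose ties", {
  lab <- array(0L, c(4, 2, 2))
  lab[1:2, , ] <- 3L     # half background, half LA in each 2-cell: tie 8:8
  down <- cpp_majority_downsample(lab, dim(lab), c(1L, 1L, 1L), 7L)
  expect_identical(as.integer(down), 3L)
})

test_that("the blood-pool oracle partitions pool into interior and a closed
           boundary", {
  # single filled disk in one slice
  dims <- c(32, 32, 3)
  truth <- array(0L, dims)
  idx <- which(array(TRUE, dims[1:2]), arr.ind = TRUE)
  disk <- (idx[, 1] - 16)^2 + (idx[, 2] - 16)^2 <= 100
  sl <- array(0L, dims[1:2]); sl[idx[disk, ]] <- 1L
  truth[, , 2] <- sl
  tv <- label_volume(truth)
  img <- intensity_volume(array(0, dims))
  bp <- segment_bloodpool_2d(img, oracle_backend(tv))
  expect_true(all(bp$data[, , c(1, 3)] == 0L))
  pool <- bp$data[, , 2] > 0
  expect_identical(pool, sl == 1L)             # partition covers the pool
  boundary <- bp$data[, , 2] == 2L
  interior <- bp$data[, , 2] == 1L
  expect_false(any(boundary & interior))
  # the boundary ring is 8-connected and encloses the interior
  ring <- array(as.integer(boundary), c(dims[1:2], 1))
  expect_equal(max(cpp_label_components(ring, dim(ring), 26L)), 1L)
  # every interior voxel is strictly inside (no background 8-neighbour)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- which(interior, arr.ind = TRUE)
    nb <- cbind(sh[, 1] + dx, sh[, 2] + dy)
    expect_true(all(sl[nb] == 1L))
  }
})

test_that("backends validate their state", {
  expect_error(trained_backend(NULL, "3D"), "weights")
  ph <- fixture_phantom("normal")
  wrong <- structure(list(kind = "trained", model = list(),
                          dimensionality = "2D"),
                     class = c("trained_backend", "segmenter_backend"))
  roi <- crop_roi(ph$image, oracle_backend(ph$truth))
  expect_error(segment_chambers_3d(roi$roi, wrong), "trained for 2D")
  expect_error(segment_chambers_3d(ph$image, oracle_backend(ph$truth)),
               "crop_roi")
})
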