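test_that("smooth_mask keeps interior voxels and removes isolated ones", {
  dims <- c(15, 15, 15)
  cube <- array(FALSE, dims)
  cube[4:12, 4:12, 4:12] <- TRUE               # solid 9^3 cube
  for (k in c(1, 4, 7)) {
    sm <- smooth_mask(cube, k)
    expect_true(sm[8, 8, 8])                    # 27 in-mask neighbours >= 14
  }
  lone <- array(FALSE, dims); lone[8, 8, 8] <- TRUE
  expect_false(any(smooth_mask(lone, 1)))      # neighbourhood sum 1 < 14
  sm1 <- smooth_mask(cube, 1)
  expect_false(sm1[4, 4, 4])                    # cube corner: sum 8 < 14
})

test_that("smooth_mask validates k and is nested on solid boxes", {
  m <- array(TRUE, c(8, 8, 8))
  expect_error(smooth_mask(m, 0), "between 1 and 7")
  expect_error(smooth_mask(m, 8), "between 1 and 7")
  box <- array(FALSE, c(20, 16, 14)); box[3:18, 3:14, 3:12] <- TRUE
  prev <- smooth_mask(box, 1)
  for (k in 2:7) {
    cur <- smooth_mask(box, k)
    expect_true(all(!cur | prev))               # output(k) subset output(k-1)
    prev <- cur
  }
})

test_that("skeletonizing a thin line returns it unchanged", {
  m <- array(FALSE, c(20, 9, 9))
  m[3:17, 5, 5] <- TRUE
  expect_identical(skeletonize_mask(m), m)
})

test_that("a solid cylinder thins to a single centred path", {
  m <- cylinder_mask(dims = c(40, 24, 24), r = 4, len = 24)
  sk <- skeletonize_mask(m)
  expect_true(all(m[sk]))                       # subset of the mask
  g <- extract_graph(sk, radius_map(m), sample_spacing = 2)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(length(g$edges), 1L)
  # endpoints near the cylinder axis ends (centre row y = z = 12 at voxel
  # coords 11 in 0-based mm)
  ends <- as.matrix(g$nodes[c("x", "y", "z")])
  expect_true(all(abs(ends[, 2] - 11) <= 2) && all(abs(ends[, 3] - 11) <= 2))
  axis_lo <- min(which(apply(m, 1, any))) - 1
  axis_hi <- max(which(apply(m, 1, any))) - 1
  expect_lte(min(abs(ends[, 1] - axis_lo)), 4)
  expect_lte(min(abs(ends[, 1] - axis_hi)), 4)
})

test_that("skeletonization preserves connected components", {
  two <- cylinder_mask(c(40, 40, 20), r = 3, len = 22,
                       center = c(20, 10, 10)) |
    cylinder_mask(c(40, 40, 20), r = 3, len = 22, center = c(20, 30, 10))
  sk <- skeletonize_mask(two)
  comp_in <- max(cpp_label_components(array(as.integer(two), dim(two)),
                                      dim(two), 26L))
  comp_out <- max(cpp_label_components(array(as.integer(sk), dim(sk)),
                                       dim(sk), 26L))
  expect_equal(comp_in, 2L)
  expect_equal(comp_out, 2L)
  expect_true(all(!sk | two))
})

test_that("graph extraction: Y fixture gives 4 nodes / 3 edges, ring gives a
           self-loop, samples carry exact radii", {
  y <- y_skeleton()
  dmap <- array(2, dim(y))
  g <- extract_graph(y, dmap, sample_spacing = 2)
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(length(g$edges), 3L)
  degs <- table(c(vapply(g$edges, function(e) e$u, 1),
                  vapply(g$edges, function(e) e$v, 1)))
  expect_setequal(as.integer(degs), c(1L, 1L, 1L, 3L))

  # octagonal closed loop: every voxel has exactly two 26-neighbours
  ring <- array(FALSE, c(20, 20, 5))
  dirs <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
                c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  pos <- c(6, 10)
  for (d in seq_len(8)) for (i in 1:3) {
    ring[pos[1], pos[2], 3] <- TRUE
    pos <- pos + dirs[d, ]
  }
  gr <- extract_graph(ring, array(1.5, dim(ring)), sample_spacing = 2)
  expect_equal(nrow(gr$nodes), 1L)
  expect_equal(length(gr$edges), 1L)
  expect_equal(gr$edges[[1]]$u, gr$edges[[1]]$v)

  # every sample's r equals the distance-map value at its voxel
  m <- cylinder_mask()
  dmap <- radius_map(m)
  sk <- skeletonize_mask(m)
  g2 <- extract_graph(sk, dmap, sample_spacing = 2)
  s <- do.call(rbind, lapply(g2$edges, function(e) e$samples))
  vox <- round(s[, 1:3]) + 1
  expect_equal(s[, 4], dmap[vox], tolerance = 1e-12)
  # sample count >= 2 per edge
  expect_true(all(vapply(g2$edges, function(e) nrow(e$samples), 1L) >= 2L))
})

test_that("candidate_graphs spans scales, deduplicates, and reports
           vanished pools", {
  # thin tube: vanishes at larger k, so not all 7 scales survive
  thin <- cylinder_mask(c(40, 16, 16), r = 2, len = 26, center = c(20, 8, 8))
  gs <- candidate_graphs(thin)
  expect_lt(length(gs), 7L)
  expect_true(all(vapply(gs, function(g) g$provenance, 1L) <= 3L))

  # a clean thick tube gives one graph after dedup
  thick <- cylinder_mask(c(40, 26, 26), r = 6, len = 26, center = c(20, 13, 13))
  gt <- candidate_graphs(thick)
  expect_equal(length(gt), 1L)
  expect_equal(gt[[1]]$provenance, 1L)

  expect_error(candidate_graphs(array(FALSE, c(8, 8, 8))), "vessel pool")
  lone <- array(FALSE, c(10, 10, 10)); lone[5, 5, 5] <- TRUE
  expect_error(candidate_graphs(lone), "vessel pool vanished")
})

test_that("touching tubes disconnect at coarser smoothing scales", {
  # two tubes joined by a thin spurious rod (the "small anomalous
  # connection" scenario): connected at fine scales, separated at coarse
  dims <- c(40, 36, 20)
  a <- cylinder_mask(dims, r = 4, len = 26, center = c(20, 11, 10))
  b <- cylinder_mask(dims, r = 4, len = 26, center = c(20, 25, 10))
  m <- a | b
  m[19:21, 15:21, 9:11] <- TRUE
  expect_equal(max(cpp_label_components(array(as.integer(m), dims), dims, 26L)),
               1L)  # touching: one component
  gs <- candidate_graphs(m)
  ncomp <- vapply(gs, n_components_graph, 1L)
  ks <- vapply(gs, function(g) g$provenance, 1L)
  expect_gt(max(ncomp), ncomp[which.min(ks)])
})

test_that("vessel graphs round-trip through JSON", {
  m <- cylinder_mask()
  g <- extract_graph(skeletonize_mask(m), radius_map(m), sample_spacing = 2,
                     provenance = 3L)
  path <- tempfile(fileext = ".json")
  write_vessel_graph(g, path)
  g2 <- read_vessel_graph(path)
  expect_equal(g2$provenance, 3L)
  expect_equal(nrow(g2$nodes), nrow(g$nodes))
  expect_equal(g2$edges[[1]]$samples, g$edges[[1]]$samples,
               ignore_attr = TRUE)
})
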