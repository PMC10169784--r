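test_that("anatomy specs validate their structure", {
  spec <- canonical_anatomy("normal")
  expect_s3_class(spec, "anatomy_spec")
  expect_error(canonical_anatomy("situs_inversus"), "anomaly")
  bad <- spec
  expect_error(
    anatomy_spec(spec$chambers, list(list(
      name = "v", category = "Ao", points = rbind(c(0, 0, 0), c(1, 1, 1)),
      radius = c(2, 2), attach = "nowhere"))),
    "undeclared")
  expect_error(
    anatomy_spec(spec$chambers, list(list(
      name = "v", category = "Ao", points = rbind(c(0, 0, 0)),
      radius = 2, attach = "LV"))),
    "control points")
})

test_that("generate_phantom is deterministic given spec and seed", {
  a <- generate_phantom(canonical_anatomy("normal", seed = 3))
  b <- generate_phantom(canonical_anatomy("normal", seed = 3))
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$data, b$truth$data)
  c <- generate_phantom(canonical_anatomy("normal", seed = 4))
  expect_false(identical(a$image$data, c$image$data))
})

test_that("a straight tube voxelises to approximately pi r^2 L", {
  # vessel of radius 4 mm, length 20 mm on a 1 mm grid, far from chambers
  chambers <- canonical_anatomy("normal")$chambers
  spec <- anatomy_spec(chambers, list(list(
    name = "Ao", category = "Ao",
    points = rbind(c(36, 54, 40), c(36, 54, 44), c(36, 54, 74)),
    radius = c(4, 4, 4), attach = "LV")))
  ph <- generate_phantom(spec)
  # 20 slices of free-standing tube, above the LV (z in [52, 72))
  n <- sum(ph$truth$data[, , 53:72] == 6L)
  expect_lt(abs(n - pi * 16 * 20) / (pi * 16 * 20), 0.10)
})

test_that("vessels touch their attachment chamber", {
  ph <- fixture_phantom("normal")
  ao <- array(as.integer(ph$truth$data == 6L), dim(ph$truth$data))
  grown <- cpp_competitive_grow(ao, array(1L, dim(ao)), dim(ao), 1L, 26L)
  # after one dilation step the Ao component overlaps LV voxels
  expect_gt(sum(grown == 1L & ph$truth$data == 1L), 0)
})

test_that("truth uses taxonomy codes and anomalous vessels take their
           attachment's code", {
  ph <- fixture_phantom("anomalous_vein")
  expect_true(all(ph$truth$data %in% c(0L, label_codes())))
  vein <- vapply(ph$truth_graph, function(g) g$name == "vein", TRUE)
  expect_equal(ph$truth_graph[[which(vein)]]$code, label_codes()[["RA"]])
  expect_equal(ph$truth_graph[[which(vein)]]$category, "anomalous")
  # the body truth blanks the vein but keeps the chambers
  mid <- ph$truth_graph[[which(vein)]]$centerline
  mid <- round(mid[ceiling(nrow(mid) / 2), ]) + 1
  expect_equal(ph$truth$data[mid[1], mid[2], mid[3]], label_codes()[["RA"]])
  expect_equal(ph$body_truth$data[mid[1], mid[2], mid[3]], 0L)
})

test_that("phantom_suite cycles round-robin through the anomaly flags", {
  specs <- phantom_suite(20, seed = 2, specs_only = TRUE)
  flags <- vapply(specs, function(s) s$anomaly, "")
  expect_equal(unname(table(flags)[anomaly_flags()]), rep(4L, 5),
               ignore_attr = TRUE)
  specs5 <- phantom_suite(5, seed = 2, specs_only = TRUE)
  expect_setequal(vapply(specs5, function(s) s$anomaly, ""), anomaly_flags())
  again <- phantom_suite(5, seed = 2, specs_only = TRUE)
  expect_identical(specs5, again)
})

test_that("rasterization rejects sub-voxel radii and names the vessel", {
  spec <- canonical_anatomy("normal")
  spec$vessels[[2]]$radius <- rep(0.4, nrow(spec$vessels[[2]]$points))
  expect_error(generate_phantom(spec), "PA.*radius below one voxel")
})

test_that("phantom round-trips through NIfTI + JSON sidecar", {
  ph <- generate_phantom(canonical_anatomy("normal", seed = 3),
                         shape = c(48, 48, 48), spacing = c(2, 2, 2))
  prefix <- file.path(tempdir(), "case1")
  paths <- write_phantom(ph, prefix)
  expect_true(all(file.exists(paths)))
  img <- read_volume(paths[1], "intensity")
  tru <- read_volume(paths[2], "label")
  expect_equal(img$data, ph$image$data, tolerance = 1e-6)
  expect_identical(tru$data, ph$truth$data)
  expect_equal(tru$spacing, c(2, 2, 2))
  sidecar <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(sidecar$anomaly, "normal")
})
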