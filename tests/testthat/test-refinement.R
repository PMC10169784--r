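make_pool_chambers <- function() {
  # a blood pool of two blobs plus a tube; chambers cover the blobs eroded
  dims <- c(40, 24, 24)
  pool <- array(FALSE, dims)
  pool[4:14, 6:18, 6:18] <- TRUE                     # blob A
  pool[26:36, 6:18, 6:18] <- TRUE                    # blob B
  pool[15:25, 11:13, 11:13] <- TRUE                  # connecting tube
  ch <- array(0L, dims)
  ch[6:12, 8:16, 8:16] <- 1L                         # LV, eroded
  ch[28:34, 8:16, 8:16] <- 2L                        # RV, eroded
  list(pool = pool, chambers = label_volume(ch), dims = dims)
}

test_that("refinement conserves pool voxels and is identity when chambers
           cover the pool", {
  f <- make_pool_chambers()
  ref <- refine_chambers(f$pool, f$chambers, K = 5L)
  claimed <- ref$refined$data != 0L & f$pool
  expect_equal(sum(f$pool), sum(claimed) + sum(ref$vessel_pool))
  expect_false(any(ref$vessel_pool & ref$refined$data != 0L))

  # identity case: chambers already cover the entire pool
  full <- f$chambers
  full$data[f$pool] <- 1L
  ref2 <- refine_chambers(f$pool, full, K = 3L)
  expect_identical(ref2$refined$data, full$data)
  expect_false(any(ref2$vessel_pool))
})

test_that("growth is monotone in K and geometry mismatches error", {
  f <- make_pool_chambers()
  prev <- refine_chambers(f$pool, f$chambers, K = 0L)
  for (K in 1:6) {
    cur <- refine_chambers(f$pool, f$chambers, K = K)
    expect_true(all(prev$refined$data == 0L |
                      cur$refined$data == prev$refined$data))
    expect_lte(sum(cur$vessel_pool), sum(prev$vessel_pool))
    prev <- cur
  }
  small <- label_volume(array(0L, c(10, 10, 10)))
  expect_error(refine_chambers(f$pool, small), "shape")
  expect_error(refine_myocardium(f$pool, small), "shape")
})

test_that("a component reachable only from one chamber never takes another
           chamber's label", {
  dims <- c(40, 12, 12)
  pool <- array(FALSE, dims)
  pool[2:10, 5:8, 5:8] <- TRUE      # RA blob
  pool[11:16, 6:7, 6:7] <- TRUE     # appendage reachable from RA only
  pool[30:38, 5:8, 5:8] <- TRUE     # far LV blob
  ch <- array(0L, dims)
  ch[2:10, 5:8, 5:8] <- 4L
  ch[30:38, 5:8, 5:8] <- 1L
  ref <- refine_chambers(pool, label_volume(ch), K = 4L)
  app <- ref$refined$data[11:16, 6:7, 6:7]
  expect_true(all(app %in% c(0L, 4L)))
})

test_that("refinement improves chamber Dice on an eroded-chamber phantom", {
  ph <- fixture_phantom("normal", seed = 21)
  truth <- ph$truth
  pool <- array(truth$data %in% bloodpool_codes(), dim(truth$data))
  # erode the chamber truth by 2 voxels to emulate low-resolution loss
  eroded <- array(0L, dim(truth$data))
  for (code in chamber_codes()) {
    m <- array(as.numeric(truth$data == code), dim(truth$data))
    m <- cpp_boxblur3(m, dim(m)); m <- cpp_boxblur3(m, dim(m))
    eroded[m >= 27^2 - 1e-9] <- code   # voxels whose 5^3-ish support is full
  }
  ref <- refine_chambers(pool, label_volume(eroded), K = 5L)
  pred_before <- label_volume(eroded, truth$spacing)
  pred_after <- ref$refined
  for (ch in c("LV", "RV", "LA", "RA")) {
    code <- label_codes()[[ch]]
    expect_gt(dice_score(pred_after, truth, code),
              dice_score(pred_before, truth, code))
  }
})

test_that("refine_myocardium subtracts refined chambers", {
  f <- make_pool_chambers()
  ref <- refine_chambers(f$pool, f$chambers, K = 2L)
  myo <- array(FALSE, f$dims)
  myo[2:16, 2:5, 2:5] <- TRUE                  # disjoint from chambers
  expect_identical(refine_myocardium(myo, ref$refined), myo)
  inside <- array(FALSE, f$dims)
  inside[7:10, 9:12, 9:12] <- TRUE             # fully inside refined LV
  expect_false(any(refine_myocardium(inside, ref$refined)))
  mixed <- myo | inside
  out <- refine_myocardium(mixed, ref$refined)
  expect_false(any(out & ref$refined$data %in% chamber_codes()))
})
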