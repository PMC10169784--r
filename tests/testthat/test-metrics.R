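test_that("dice_score handles identity, disjoint and partial overlap", {
  mk <- function(v) label_volume(array(as.integer(v), c(length(v), 1, 1)))
  expect_equal(dice_score(mk(c(1, 1, 0)), mk(c(1, 1, 0)), 1L), 1.0)
  expect_equal(dice_score(mk(c(1, 0, 0)), mk(c(0, 1, 0)), 1L), 0.0)
  # pred {v1,v2}, truth {v2,v3}: one shared voxel of two each
  expect_equal(dice_score(mk(c(1, 1, 0, 0)), mk(c(0, 1, 1, 0)), 1L), 0.5)
  # both empty: structure correctly absent
  expect_equal(dice_score(mk(c(0, 0)), mk(c(0, 0)), 7L), 1.0)
})

test_that("dice_score is symmetric and errors on geometry mismatch", {
  set.seed(4)
  a <- label_volume(array(sample(0:2, 60, TRUE), c(5, 4, 3)))
  b <- label_volume(array(sample(0:2, 60, TRUE), c(5, 4, 3)))
  for (code in 0:2)
    expect_equal(dice_score(a, b, code), dice_score(b, a, code))
  c <- label_volume(array(0L, c(4, 5, 3)))
  expect_error(dice_score(a, c, 1L), "shape or spacing")
})

test_that("combined_loss matches hand-computed closed forms", {
  g <- matrix(c(1, 0), 1)
  # perfect prediction: both terms vanish
  expect_equal(combined_loss(g, g), 0, tolerance = 1e-6)
  # N=1, C=2, p=(.5,.5): dice term 2/3, CE term ln(2)/2
  # up to the 1e-6 smoothing constant on the absent class
  expect_equal(combined_loss(matrix(c(0.5, 0.5), 1), g),
               (1 - 0.5 * (2 * 0.5 / 1.5)) + 0.5 * log(2),
               tolerance = 1e-5)
  expect_equal(combined_loss(matrix(c(0.5, 0.5), 1), g), 1.01324,
               tolerance = 1e-5)
})

test_that("combined_loss equals the literal summation oracle", {
  set.seed(42)
  for (trial in 1:50) {
    N <- sample(2:40, 1); C <- sample(2:5, 1)
    p <- matrix(rexp(N * C), N)
    p <- p / rowSums(p)
    g <- one_hot(sample(0:(C - 1), N, TRUE), 0:(C - 1))
    expect_equal(combined_loss(p, g), literal_combined_loss(p, g),
                 tolerance = 1e-9)
  }
})

test_that("combined_loss is invariant to voxel permutation and duplication", {
  set.seed(7)
  N <- 20; C <- 3
  p <- matrix(rexp(N * C), N); p <- p / rowSums(p)
  g <- one_hot(sample(0:(C - 1), N, TRUE), 0:(C - 1))
  o <- sample(N)
  expect_equal(combined_loss(p[o, ], g[o, ]), combined_loss(p, g))
  # duplicating every voxel leaves the loss unchanged
  expect_equal(combined_loss(rbind(p, p), rbind(g, g)), combined_loss(p, g),
               tolerance = 1e-6)
})

test_that("combined_loss validates inputs", {
  g <- matrix(c(1, 0), 1)
  expect_error(combined_loss(matrix(numeric(0), 0, 2),
                             matrix(numeric(0), 0, 2)), "empty")
  expect_error(combined_loss(matrix(c(0.7, 0.7), 1), g), "sum to 1")
  expect_error(combined_loss(matrix(c(0.5, 0.5), 1), matrix(c(1, 1), 1)),
               "one-hot")
})
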