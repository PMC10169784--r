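# Shared fixtures, built once per test run.

# one canonical phantom per anomaly flag, generated lazily and cached
.fixture_env <- new.env(parent = emptyenv())

fixture_phantom <- function(flag = "normal", seed = 11L) {
  key <- paste0(flag, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantom(canonical_anatomy(flag, seed = seed))
  .fixture_env[[key]]
}

# solid axis-aligned cylinder along x: radius r voxels, length len voxels
cylinder_mask <- function(dims = c(40, 24, 24), r = 4, len = 20,
                          center = NULL, axis = 1) {
  if (is.null(center)) center <- dims / 2
  m <- array(FALSE, dims)
  idx <- which(!m, arr.ind = TRUE)
  ax <- idx[, axis]
  perp <- setdiff(1:3, axis)
  rad2 <- (idx[, perp[1]] - center[perp[1]])^2 +
    (idx[, perp[2]] - center[perp[2]])^2
  along <- ax >= center[axis] - len / 2 & ax < center[axis] + len / 2
  m[idx[along & rad2 <= r^2, , drop = FALSE]] <- TRUE
  m
}

# Y-shaped one-voxel-thick skeleton: three straight arms from a centre voxel
y_skeleton <- function(dims = c(31, 31, 15)) {
  m <- array(FALSE, dims)
  c0 <- c(16, 16, 8)
  for (i in 0:10) m[c0[1] - i, c0[2], c0[3]] <- TRUE              # arm 1 (-x)
  for (i in 1:10) m[c0[1] + i, c0[2] + i, c0[3]] <- TRUE          # arm 2 (diag)
  for (i in 1:10) m[c0[1] + i, c0[2] - i, c0[3]] <- TRUE          # arm 3 (diag)
  m
}

# random normalized point distribution with n bins
random_distribution <- function(n, scale = 10) {
  pos <- matrix(runif(3 * n, 0, scale), ncol = 3)
  w <- runif(n, 0.1, 1)
  point_distribution(pos, w)
}
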