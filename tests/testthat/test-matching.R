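test_that("graph_to_distribution cubes radii and normalizes mass and frame", {
  samples <- cbind(x = c(0, 2), y = c(0, 0), z = c(0, 0), r = c(1, 2))
  g <- structure(list(nodes = data.frame(id = 1:2),
                      edges = list(list(u = 1, v = 2, samples = samples)),
                      spacing = c(1, 1, 1), provenance = 1L),
                 class = "vessel_graph")
  raw <- graph_to_distribution(g, normalize = FALSE)
  expect_equal(raw$weights, c(1, 8))            # r^3
  d <- graph_to_distribution(g)
  expect_equal(d$weights, c(1 / 9, 8 / 9))
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  # rigid translation leaves the normalized distribution unchanged
  g2 <- g
  g2$edges[[1]]$samples[, 1:3] <- samples[, 1:3] + 50
  d2 <- graph_to_distribution(g2)
  expect_equal(d2$positions, d$positions, tolerance = 1e-12)
  expect_equal(d2$weights, d$weights)
  # all radii zero is degenerate
  g3 <- g
  g3$edges[[1]]$samples[, 4] <- 0
  expect_error(graph_to_distribution(g3), "degenerate")
})

test_that("emd analytic cases: identity and single-bin pairs", {
  a <- point_distribution(rbind(c(0, 0, 0), c(1, 2, 3)), c(0.3, 0.7))
  expect_equal(emd(a, a), 0, tolerance = 1e-12)
  p <- point_distribution(rbind(c(0, 0, 0)), 1)
  q <- point_distribution(rbind(c(3, 4, 0)), 1)
  expect_equal(emd(p, q), 5, tolerance = 1e-12)
  # split-and-shift: each half moves by 1
  a2 <- point_distribution(rbind(c(0, 0, 0), c(10, 0, 0)), c(.5, .5))
  b2 <- point_distribution(rbind(c(1, 0, 0), c(9, 0, 0)), c(.5, .5))
  expect_equal(emd(a2, b2), 1, tolerance = 1e-12)
  # unnormalized input rejected
  bad <- a; bad$weights <- bad$weights * 2
  expect_error(emd(bad, a), "mass 1")
})

test_that("emd equals the scipy linear-program oracle on random instances", {
  set.seed(99)
  instances <- lapply(1:100, function(i)
    list(a = random_distribution(sample(1:6, 1)),
         b = random_distribution(sample(1:6, 1))))
  expected <- lp_emd_oracle(instances)
  got <- vapply(instances, function(ins) emd(ins$a, ins$b), 1)
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("emd satisfies the metric axioms on random triples", {
  set.seed(123)
  for (i in 1:25) {
    a <- random_distribution(4); b <- random_distribution(4)
    c <- random_distribution(4)
    dab <- emd(a, b); dba <- emd(b, a)
    expect_gte(dab, 0)
    expect_equal(dab, dba, tolerance = 1e-9)
    expect_lte(dab, emd(a, c) + emd(c, b) + 1e-6)
  }
})

test_that("the template library covers the anomaly families and round-trips
           through JSON", {
  lib <- default_graph_library()
  expect_s3_class(lib, "graph_library")
  expect_equal(vapply(lib, function(t) t$tag, ""), anomaly_flags())
  expect_equal(vapply(lib, function(t) t$id, 1L), 1:5)
  for (t in lib) {
    expect_equal(sum(t$weights), 1, tolerance = 1e-9)
    expect_true(all(vapply(t$keypoints, function(k)
      k$category %in% vessel_categories(), TRUE)))
    expect_true(all(t$categories %in% vessel_categories()))
  }
  path <- tempfile(fileext = ".json")
  write_graph_library(lib, path)
  lib2 <- read_graph_library(path)
  expect_equal(lib2[[2]]$tag, lib[[2]]$tag)
  expect_equal(lib2[[2]]$positions, lib[[2]]$positions, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(lib2[[2]]$weights, lib[[2]]$weights, tolerance = 1e-12)
  expect_equal(lib2[[2]]$categories, lib[[2]]$categories)
})

test_that("match_graphs recovers a template from its own sampled graph and
           breaks ties deterministically", {
  lib <- default_graph_library()
  # candidate = template 2's own point set wrapped as a one-edge graph
  t2 <- lib[[2]]
  samples <- cbind(t2$positions, r = t2$weights^(1 / 3))
  g <- structure(list(nodes = data.frame(id = 1:2),
                      edges = list(list(u = 1, v = 2, samples = samples)),
                      spacing = c(1, 1, 1), provenance = 1L),
                 class = "vessel_graph")
  m <- match_graphs(list(g), lib)
  expect_equal(m$template_id, 2L)
  expect_lt(m$emd, 0.05)
  # duplicated template: lower id wins on an exact tie
  lib2 <- lib
  lib2[[4]] <- lib[[2]]; lib2[[4]]$id <- 4L; lib2[[4]]$tag <- "copy"
  m2 <- match_graphs(list(g), lib2)
  expect_equal(m2$template_id, 2L)
  expect_error(match_graphs(list(), lib), "vessel pool")
  expect_error(match_graphs(list(g), list()), "library")
})

test_that("transfer_labels assigns nearest-sample categories and resolves
           anomalous components through the chambers", {
  dims <- c(30, 12, 12)
  pool <- array(FALSE, dims)
  pool[3:14, 5:7, 5:7] <- TRUE    # left tube -> Ao
  pool[17:28, 5:7, 5:7] <- TRUE   # right tube -> PA
  samples_ao <- cbind(x = seq(2, 13, 2), y = 5, z = 5, r = 2)
  samples_pa <- cbind(x = seq(16, 27, 2), y = 5, z = 5, r = 2)
  g <- structure(list(nodes = data.frame(id = 1:4),
                      edges = list(list(u = 1, v = 2, samples = samples_ao),
                                   list(u = 3, v = 4, samples = samples_pa)),
                      spacing = c(1, 1, 1), provenance = 1L),
                 class = "vessel_graph")
  match <- structure(list(graph = g, scale = 1L, template_id = 1L,
                          template_tag = "normal", emd = 0,
                          edge_categories = c("Ao", "PA")),
                     class = "match_result")
  lab <- transfer_labels(match, pool)
  smoothed <- smooth_mask(pool, 1L) & pool
  left <- lab$data[1:15, , ]
  expect_true(all(left[smoothed[1:15, , ]] == 6L))
  right <- lab$data[16:30, , ]
  expect_true(all(right[smoothed[16:30, , ]] == 7L))
  expect_true(all(lab$data[!smoothed] == 0L))

  # anomalous category re-coded to the adjacent chamber
  match$edge_categories <- c("anomalous", "PA")
  chamber <- array(0L, dims)
  chamber[1:2, 5:7, 5:7] <- 4L     # RA touching the left tube
  lab2 <- transfer_labels(match, pool, chambers = label_volume(chamber))
  left <- lab2$data[3:14, 5:7, 5:7]
  expect_true(all(left[left != 0] == 4L))
})

test_that("grow_leftovers absorbs reachable voxels and reports isolated
           components", {
  dims <- c(20, 9, 9)
  pool <- array(FALSE, dims)
  pool[2:12, 4:6, 4:6] <- TRUE
  pool[16:19, 4:6, 4:6] <- TRUE          # island, no labelled contact
  lab <- array(0L, dims)
  lab[2:6, 4:6, 4:6] <- 6L               # Ao seed on the main tube
  res <- grow_leftovers(label_volume(lab), pool)
  expect_true(all(res$data[2:12, 4:6, 4:6] == 6L))
  expect_true(all(res$data[16:19, 4:6, 4:6] == 0L))
  expect_equal(attr(res, "unresolved"), sum(pool[16:19, 4:6, 4:6]))

  # competing fronts: tie goes to more adjacent claimed voxels, then lower code
  lab2 <- array(0L, dims)
  lab2[2:3, 4:6, 4:6] <- 7L
  lab2[11:12, 4:6, 4:6] <- 6L
  res2 <- grow_leftovers(label_volume(lab2), pool)
  expect_true(all(res2$data[2:12, 4:6, 4:6] %in% c(6L, 7L)))
  # voxels nearer the PA seed stay PA, nearer the Ao seed stay Ao
  expect_equal(res2$data[4, 5, 5], 7L)
  expect_equal(res2$data[10, 5, 5], 6L)
})
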