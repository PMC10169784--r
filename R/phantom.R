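#' Parametric description of a synthetic CHD phantom heart
#'
#' An anatomy spec lists four chamber ellipsoids (LV, RV, LA, RA), a
#' myocardial shell thickness around the ventricles, and a set of vessels,
#' each a tube swept along spline-interpolated centerline control points with
#' a per-point radius profile. Every vessel attaches to a chamber or to a
#' previously declared vessel (its first control point must lie inside the
#' parent). The anomaly flag records which topology family the anatomy encodes;
#' it is the recovery target for graph matching.
#'
#' @param chambers Named list (`LV`, `RV`, `LA`, `RA`) of
#'   `list(center = mm, semi = mm)` ellipsoid descriptors.
#' @param vessels List of `list(name, category, points, radius, attach)`;
#'   `points` is an n x 3 matrix of control points (mm, n >= 2), `radius` a
#'   length-n positive profile (mm), `category` one of
#'   [vessel_categories()], `attach` a chamber name or earlier vessel name.
#' @param myo_thickness Myocardial shell thickness in mm.
#' @param anomaly One of `"normal"`, `"swapped_origins"`, `"common_trunk"`,
#'   `"anomalous_vein"`, `"sling"`.
#' @param noise_sigma Gaussian intensity noise s.d. (intensity units).
#' @param seed Integer RNG seed for the noise.
#' @return An `anatomy_spec` object.
#' @export
anatomy_spec <- function(chambers, vessels, myo_thickness = 3,
                         anomaly = "normal", noise_sigma = 20, seed = 1L) {
  flags <- anomaly_flags()
  if (!anomaly %in% flags)
    stop("anomaly must be one of: ", paste(flags, collapse = ", "))
  stopifnot(all(c("LV", "RV", "LA", "RA") %in% names(chambers)),
            myo_thickness > 0, noise_sigma >= 0)
  seen <- names(chambers)
  for (v in vessels) {
    stopifnot(is.matrix(v$points), ncol(v$points) == 3)
    if (nrow(v$points) < 2) stop("vessel '", v$name, "' needs >= 2 control points")
    if (length(v$radius) != nrow(v$points) || any(v$radius <= 0))
      stop("vessel '", v$name, "' needs a positive radius per control point")
    if (!v$category %in% vessel_categories())
      stop("vessel '", v$name, "' has unknown category '", v$category, "'")
    if (!v$attach %in% seen)
      stop("vessel '", v$name, "' attaches to undeclared '", v$attach, "'")
    seen <- c(seen, v$name)
  }
  structure(list(chambers = chambers, vessels = vessels,
                 myo_thickness = myo_thickness, anomaly = anomaly,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "anatomy_spec")
}

#' @rdname anatomy_spec
#' @export
anomaly_flags <- function() {
  c("normal", "swapped_origins", "common_trunk", "anomalous_vein", "sling")
}

#' Canonical anatomy for each topology family
#'
#' The unjittered reference geometry of the phantom generator, one per
#' anomaly flag, on a 96 mm cube: normal (Ao from LV, PA from RV),
#' swapped origins (transposition-like: the Ao-category vessel arises from
#' RV and vice versa), common trunk (one thick trunk with a PA branch),
#' anomalous vein (normal plus an anomalous vessel draining to RA), and
#' sling (normal plus a hooked PA branch). The same geometry seeds the
#' template library, so template coordinates and phantom truth agree by
#' construction.
#'
#' @param anomaly Anomaly flag, see [anomaly_flags()].
#' @inheritParams anatomy_spec
#' @return An [anatomy_spec()].
#' @export
canonical_anatomy <- function(anomaly = "normal", noise_sigma = 20, seed = 1L) {
  chambers <- list(
    LV = list(center = c(36, 54, 34), semi = c(13, 12, 15)),
    RV = list(center = c(58, 50, 33), semi = c(12, 11, 13)),
    LA = list(center = c(40, 40, 56), semi = c(9, 8, 8)),
    RA = list(center = c(62, 42, 54), semi = c(10, 9, 9)))
  ao_distal <- rbind(c(43, 55, 58), c(47, 48, 70), c(54, 46, 80), c(64, 48, 84))
  pa_distal <- rbind(c(52, 56, 58), c(46, 58, 68), c(38, 59, 78))
  lv_root <- c(38, 52, 46)
  rv_root <- c(56, 48, 44)
  ao_r <- c(5, 5, 4.7, 4.4, 4)
  pa_r <- c(4.5, 4.2, 3.9, 3.5)
  vessels <- switch(
    anomaly,
    normal = list(
      list(name = "Ao", category = "Ao", points = rbind(lv_root, ao_distal),
           radius = ao_r, attach = "LV"),
      list(name = "PA", category = "PA", points = rbind(rv_root, pa_distal),
           radius = pa_r, attach = "RV")),
    swapped_origins = list(
      list(name = "Ao", category = "Ao",
           points = rbind(rv_root, c(50, 52, 58), c(47, 48, 70),
                          c(54, 46, 80), c(64, 48, 84)),
           radius = ao_r, attach = "RV"),
      list(name = "PA", category = "PA",
           points = rbind(lv_root, c(42, 56, 58), c(46, 58, 68), c(38, 59, 78)),
           radius = pa_r, attach = "LV")),
    common_trunk = list(
      list(name = "trunk", category = "Ao",
           points = rbind(c(42, 51, 45), c(50, 51, 60), c(52, 48, 72),
                          c(58, 48, 82)),
           radius = c(6.5, 6.2, 5.8, 5.5), attach = "LV"),
      list(name = "pa_branch", category = "PA",
           points = rbind(c(51, 49, 66), c(43, 54, 70), c(35, 58, 74)),
           radius = c(3.6, 3.4, 3.2), attach = "trunk")),
    anomalous_vein = list(
      list(name = "Ao", category = "Ao", points = rbind(lv_root, ao_distal),
           radius = ao_r, attach = "LV"),
      list(name = "PA", category = "PA", points = rbind(rv_root, pa_distal),
           radius = pa_r, attach = "RV"),
      list(name = "vein", category = "anomalous",
           points = rbind(c(66, 44, 60), c(74, 48, 68), c(80, 52, 78)),
           radius = c(3, 3, 3), attach = "RA")),
    sling = list(
      list(name = "Ao", category = "Ao", points = rbind(lv_root, ao_distal),
           radius = ao_r, attach = "LV"),
      list(name = "PA", category = "PA", points = rbind(rv_root, pa_distal),
           radius = pa_r, attach = "RV"),
      list(name = "lpa_sling", category = "PA",
           points = rbind(c(46, 58, 68), c(54, 62, 70), c(58, 68, 64),
                          c(50, 72, 58)),
           radius = c(3.2, 3, 3, 3), attach = "PA")))
  anatomy_spec(chambers, vessels, myo_thickness = 3, anomaly = anomaly,
               noise_sigma = noise_sigma, seed = seed)
}

# spline-resample a centerline at roughly `step` mm arc length; returns
# list(points = m x 3, radius = length m)
interp_centerline <- function(points, radius, step = 0.5) {
  n <- nrow(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[n]
  m <- max(2L, ceiling(total / step) + 1L)
  s <- seq(0, total, length.out = m)
  interp1 <- function(y) {
    if (n == 2) stats::approx(arc, y, xout = s)$y
    else stats::spline(arc, y, xout = s, method = "natural")$y
  }
  list(points = cbind(interp1(points[, 1]), interp1(points[, 2]),
                      interp1(points[, 3])),
       radius = pmax(1e-6, interp1(radius)))
}

# rasterize a tube as a union of short open cylinders along the fine polyline
# (flat ends, so a straight vessel voxelises to ~ pi r^2 L)
rasterize_tube <- function(mask, pts, rad, spacing) {
  dims <- dim(mask)
  m <- nrow(pts)
  for (i in seq_len(m - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    u <- b - a
    len <- sqrt(sum(u^2))
    if (len < 1e-9) next
    u <- u / len
    r <- (rad[i] + rad[i + 1]) / 2
    lo <- pmax(1L, floor((pmin(a, b) - r) / spacing) + 1L)
    hi <- pmin(dims, ceiling((pmax(a, b) + r) / spacing) + 1L)
    if (any(lo > hi)) next
    xs <- (seq(lo[1], hi[1]) - 1) * spacing[1]
    ys <- (seq(lo[2], hi[2]) - 1) * spacing[2]
    zs <- (seq(lo[3], hi[3]) - 1) * spacing[3]
    g <- expand.grid(x = xs, y = ys, z = zs)
    d <- cbind(g$x - a[1], g$y - a[2], g$z - a[3])
    t <- d %*% u
    inside <- t >= 0 & t < len
    rad2 <- rowSums(d^2) - t^2
    inside <- inside & rad2 <= r^2
    if (any(inside)) {
      sub <- array(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
                   dim = hi - lo + 1L)
      sub[array(inside, dim = hi - lo + 1L)] <- TRUE
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
    }
  }
  mask
}

ellipsoid_mask <- function(dims, spacing, center, semi) {
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  zs <- (seq_len(dims[3]) - 1) * spacing[3]
  ex <- ((xs - center[1]) / semi[1])^2
  ey <- ((ys - center[2]) / semi[2])^2
  ez <- ((zs - center[3]) / semi[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

#' Generate a synthetic phantom volume pair
#'
#' Rasterizes an [anatomy_spec()] onto a voxel grid: chambers as ellipsoids,
#' myocardium as a shell of the stated thickness around LV and RV, vessels as
#' tubes swept along spline-interpolated centerlines (sampled at half-voxel
#' arc length). Where shapes overlap, chambers take precedence over vessels,
#' which take precedence over myocardium, mimicking blood-pool continuity at
#' the valve planes. Intensities are 300 for blood pool, 150 for myocardium
#' and 0 for background, plus seeded Gaussian noise. Anomalous-category
#' vessels carry the structure code of their attachment in the truth, per the
#' labelling convention that anomalous vessels are coded by their
#' connections.
#'
#' @param spec An [anatomy_spec()].
#' @param shape Grid dimensions (>= 32 per axis).
#' @param spacing Voxel size in mm.
#' @return A `phantom_case`: `spec`, `image` ([intensity_volume()]), `truth`
#'   ([label_volume()]), and `truth_graph` (per-vessel name, category,
#'   attachment, centerline and radii for grading the matching stage).
#' @examples
#' ph <- generate_phantom(canonical_anatomy("normal"), shape = c(48, 48, 48),
#'                        spacing = c(2, 2, 2))
#' table(ph$truth$data)[1:3]
#' @export
generate_phantom <- function(spec, shape = c(96, 96, 96), spacing = c(1, 1, 1)) {
  stopifnot(inherits(spec, "anatomy_spec"))
  shape <- as.integer(shape)
  if (any(shape < 32)) stop("phantom grid must be >= 32 voxels per axis")
  codes <- label_codes()
  labels <- array(0L, shape)

  # myocardium first (lowest precedence): shell around LV and RV
  myo <- array(FALSE, shape)
  for (ch in c("LV", "RV")) {
    c0 <- spec$chambers[[ch]]
    myo <- myo | (ellipsoid_mask(shape, spacing, c0$center,
                                 c0$semi + spec$myo_thickness) &
                  !ellipsoid_mask(shape, spacing, c0$center, c0$semi))
  }
  labels[myo] <- codes[["Myo"]]

  # vessels next; anomalous vessels inherit their attachment's code
  vessel_code <- function(v) {
    if (v$category %in% c("Ao", "PA")) return(codes[[v$category]])
    att <- v$attach
    while (!att %in% names(codes)) {  # attached to another vessel: follow it
      parent <- Filter(function(w) w$name == att, spec$vessels)[[1]]
      if (parent$category %in% c("Ao", "PA")) return(codes[[parent$category]])
      att <- parent$attach
    }
    codes[[att]]
  }
  centerlines <- list()
  anom_mask <- array(FALSE, shape)
  for (v in spec$vessels) {
    if (min(v$radius) < min(spacing))
      stop("vessel '", v$name, "' has radius below one voxel")
    cl <- interp_centerline(v$points, v$radius, step = min(spacing) / 2)
    centerlines[[v$name]] <- cl
    vm <- rasterize_tube(array(FALSE, shape), cl$points, cl$radius, spacing)
    labels[vm] <- vessel_code(v)
    if (v$category == "anomalous") anom_mask <- anom_mask | vm
  }

  # chambers last (highest precedence)
  for (ch in c("LV", "RV", "LA", "RA")) {
    c0 <- spec$chambers[[ch]]
    labels[ellipsoid_mask(shape, spacing, c0$center, c0$semi)] <- codes[[ch]]
  }

  for (v in spec$vessels)
    if (!any(labels == vessel_code(v)))
      stop("vessel '", v$name, "' produced no voxels")

  intens <- array(0, shape)
  intens[labels %in% bloodpool_codes()] <- 300
  intens[labels == codes[["Myo"]]] <- 150
  old <- local_seed(spec$seed)
  intens <- intens + array(rnorm(length(intens), 0, spec$noise_sigma), shape)
  restore_seed(old)

  truth_graph <- lapply(spec$vessels, function(v) {
    cl <- centerlines[[v$name]]
    keep <- seq(1, nrow(cl$points), by = max(1L, round(2 / min(spacing))))
    list(name = v$name, category = v$category, attach = v$attach,
         code = vessel_code(v),
         centerline = cl$points[keep, , drop = FALSE],
         radius = cl$radius[keep])
  })

  # chamber-body truth: the target of the low-resolution 3D stage. Anomalous
  # vessels carry a chamber code in `truth` (labelling convention: coded by
  # their connections) but are *not* chamber bodies — they stay in the blood
  # pool and are recovered through graph matching, so they are blanked here.
  body <- labels
  body[anom_mask] <- 0L
  for (ch in c("LV", "RV", "LA", "RA")) {
    c0 <- spec$chambers[[ch]]
    sel <- anom_mask & ellipsoid_mask(shape, spacing, c0$center, c0$semi)
    body[sel] <- codes[[ch]]
  }

  structure(list(spec = spec,
                 image = intensity_volume(intens, spacing),
                 truth = label_volume(labels, spacing),
                 body_truth = label_volume(body, spacing),
                 truth_graph = truth_graph),
            class = "phantom_case")
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Deterministic suite of phantom cases
#'
#' Cycles round-robin through the five anomaly flags with jittered geometry
#' (chamber centres and control points perturbed by up to ~2 mm, semi-axes by
#' up to 1 mm, radii scaled by up to 10%), emulating inter-patient
#' variability while preserving each family's topology. With `n >= 5` every
#' flag is represented.
#'
#' @param n Number of cases (>= 1).
#' @param seed Integer seed; the same seed reproduces the same suite.
#' @param shape,spacing Passed to [generate_phantom()].
#' @param specs_only If `TRUE`, return the jittered specs without rasterizing.
#' @return List of `phantom_case` (or [anatomy_spec()]) objects.
#' @export
phantom_suite <- function(n, seed = 1L, shape = c(96, 96, 96),
                          spacing = c(1, 1, 1), specs_only = FALSE) {
  stopifnot(n >= 1)
  flags <- anomaly_flags()
  old <- local_seed(seed)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    flag <- flags[((i - 1) %% length(flags)) + 1]
    base <- canonical_anatomy(flag, seed = seed * 1000L + i)
    jit <- function(x, amp) x + runif(length(x), -amp, amp)
    base$chambers <- lapply(base$chambers, function(ch)
      list(center = jit(ch$center, 2), semi = pmax(6, jit(ch$semi, 1))))
    rs <- runif(1, 0.9, 1.1)
    base$vessels <- lapply(base$vessels, function(v) {
      v$points <- v$points + matrix(runif(length(v$points), -1.5, 1.5),
                                    ncol = 3)
      v$radius <- v$radius * rs
      v
    })
    specs[[i]] <- base
  }
  restore_seed(old)
  if (specs_only) return(specs)
  lapply(specs, generate_phantom, shape = shape, spacing = spacing)
}

#' Write / read a phantom case
#'
#' The image and truth are written as paired NIfTI files
#' (`<prefix>_image.nii.gz`, `<prefix>_truth.nii.gz`) with a JSON sidecar
#' (`<prefix>_graph.json`) holding the truth graph and the anomaly flag.
#'
#' @param case A `phantom_case`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_phantom <- function(case, prefix) {
  stopifnot(inherits(case, "phantom_case"))
  paths <- paste0(prefix, c("_image.nii.gz", "_truth.nii.gz", "_graph.json"))
  write_volume(case$image, paths[1])
  write_volume(case$truth, paths[2])
  sidecar <- list(anomaly = case$spec$anomaly,
                  vessels = lapply(case$truth_graph, function(g)
                    list(name = g$name, category = g$category,
                         attach = g$attach, code = g$code,
                         centerline = g$centerline, radius = g$radius)))
  jsonlite::write_json(sidecar, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
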