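#' Segmentation backends
#'
#' The learned stages accept a pluggable backend. An *oracle* backend
#' carries a ground-truth [label_volume()] and answers queries by the
#' deterministic truth-derived rule of each stage, which lets every
#' non-learned stage of the pipeline be exercised without training. A
#' *trained* backend wraps a U-net from [train_unet()].
#'
#' @param truth Ground-truth [label_volume()].
#' @return A `segmenter_backend`.
#' @export
oracle_backend <- function(truth) {
  stopifnot(inherits(truth, "label_volume"))
  structure(list(kind = "oracle", truth = truth),
            class = c("oracle_backend", "segmenter_backend"))
}

#' @rdname oracle_backend
#' @param model A `unet_model` (internal) with finalized weights.
#' @param dimensionality `"3D"` or `"2D"`.
#' @param loss_history,config Training provenance.
#' @export
trained_backend <- function(model, dimensionality, loss_history = numeric(),
                            config = NULL) {
  if (is.null(model)) stop("trained backend requires finalized weights")
  structure(list(kind = "trained", model = model,
                 dimensionality = dimensionality,
                 loss_history = loss_history, config = config),
            class = c("trained_backend", "segmenter_backend"))
}

#' @export
print.segmenter_backend <- function(x, ...) {
  cat("<segmenter_backend>", x$kind,
      if (x$kind == "trained") x$dimensionality else "", "\n")
  invisible(x)
}

crop_volume <- function(vol, offset, size) {
  idx <- Map(function(o, s) (o + 1):(o + s), offset, size)
  out <- vol
  out$data <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out$origin <- vol$origin + offset * vol$spacing
  out
}

#' Region-of-interest cropping
#'
#' The input image is resampled to a coarse 64^3 grid on which the backend
#' produces a binary heart-foreground segmentation; the tight bounding box
#' of that segmentation, padded by `margin` coarse voxels, is mapped back to
#' full resolution and cropped. The oracle backend derives the coarse
#' foreground from the attached truth (any foreground structure).
#'
#' @param image [intensity_volume()].
#' @param backend A segmentation backend from [oracle_backend()] /
#'   [trained_backend()].
#' @param margin Bounding-box padding in coarse (64-grid) voxels.
#' @return List with `roi` (cropped [intensity_volume()], carrying the crop
#'   offset as attribute `offset`) and `offset` (0-based voxel coordinates of
#'   the RoI origin in the original grid).
#' @export
crop_roi <- function(image, backend, margin = 8L) {
  stopifnot(inherits(image, "intensity_volume"),
            inherits(backend, "segmenter_backend"))
  d <- dim(image$data)
  coarse_dim <- c(64L, 64L, 64L)
  fg <- coarse_foreground(image, backend, coarse_dim)
  if (!any(fg)) stop("no heart found: coarse segmentation is empty")
  idx <- which(fg, arr.ind = TRUE)
  lo_c <- pmax(1L, apply(idx, 2, min) - margin)
  hi_c <- pmin(coarse_dim, apply(idx, 2, max) + margin)
  scale <- d / coarse_dim
  lo <- pmax(1L, floor((lo_c - 1) * scale) + 1L)
  hi <- pmin(d, ceiling(hi_c * scale))
  offset <- lo - 1L
  roi <- crop_volume(image, offset, hi - lo + 1L)
  attr(roi, "offset") <- offset
  attr(roi, "full_dim") <- d
  list(roi = roi, offset = offset)
}

coarse_foreground <- function(image, backend, coarse_dim) {
  if (inherits(backend, "oracle_backend")) {
    stop_geometry(image, backend$truth, "crop_roi")
    fgmask <- array(as.integer(backend$truth$data > 0), dim(image$data))
    array(cpp_majority_downsample(fgmask, dim(fgmask), coarse_dim, 1L) == 1L,
          coarse_dim)
  } else {
    x64 <- resample_linear(image$data, coarse_dim)
    pred <- predict_labels(backend$model, x64, c(0L, 1L))
    array(pred == 1L, coarse_dim)
  }
}

# trained inference; 3D models trained on blocks are tiled with the same
# block size so instance-norm statistics match training exactly
predict_labels <- function(model, intens, codes) {
  x <- net_input(intens)
  d0 <- dim(intens)
  if (is.null(model$block) || any(d0 %% model$block != 0)) {
    fwd <- unet_forward(model, x)
    d <- dim(fwd$logits)
    cls <- max.col(matrix(fwd$logits, prod(d[1:3]), d[4]), ties.method = "first")
    return(array(codes[cls], d[1:3]))
  }
  b <- model$block
  out <- array(codes[1], d0)
  nb <- d0 %/% b
  for (oz in seq_len(nb[3]) - 1) for (oy in seq_len(nb[2]) - 1)
    for (ox in seq_len(nb[1]) - 1) {
      ix <- ox * b + seq_len(b); iy <- oy * b + seq_len(b)
      iz <- oz * b + seq_len(b)
      fwd <- unet_forward(model, x[ix, iy, iz, , drop = FALSE])
      d <- dim(fwd$logits)
      cls <- max.col(matrix(fwd$logits, prod(d[1:3]), d[4]),
                     ties.method = "first")
      out[ix, iy, iz] <- codes[cls]
    }
  out
}

#' Low-resolution chambers and myocardium segmentation
#'
#' The RoI is resampled to 64^3 and segmented into LV, RV, LA, RA and Myo
#' (great vessels are left to the 2D blood-pool path). The oracle backend
#' returns the ground truth restricted to those codes and downsampled by
#' per-cell majority vote (background loses ties); a trained backend runs
#' its 3D U-net.
#'
#' @param roi RoI from [crop_roi()] (the `roi` element, which carries the
#'   crop offset).
#' @param backend Segmentation backend.
#' @param grid Output edge length (64).
#' @return [label_volume()] on the coarse grid, spacing scaled accordingly.
#' @export
segment_chambers_3d <- function(roi, backend, grid = 64L) {
  offset <- attr(roi, "offset")
  if (is.null(offset)) stop("roi must come from crop_roi()")
  d <- dim(roi$data)
  out_dim <- rep(as.integer(grid), 3L)
  codes <- chamber_net_codes()
  if (inherits(backend, "oracle_backend")) {
    truth_roi <- crop_volume(backend$truth, offset, d)
    lab <- truth_roi$data
    lab[!(lab %in% codes)] <- 0L
    lab64 <- cpp_majority_downsample(array(as.integer(lab), dim(lab)),
                                     dim(lab), out_dim, 7L)
    label_volume(lab64, spacing = roi$spacing * d / out_dim)
  } else {
    if (backend$dimensionality != "3D")
      stop("backend was trained for ", backend$dimensionality)
    x64 <- resample_linear(roi$data, out_dim)
    lab64 <- predict_labels(backend$model, x64, codes)
    label_volume(lab64, spacing = roi$spacing * d / out_dim)
  }
}

# truth-derived blood-pool map: 0 background, 1 interior, 2 boundary
# (boundary = pool voxel with a background 8-neighbour within its slice)
bloodpool_oracle <- function(truth) {
  pool <- array(truth$data %in% bloodpool_codes(), dim(truth$data))
  boundary <- array(FALSE, dim(pool))
  d <- dim(pool)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    shifted <- array(FALSE, d)  # TRUE where the 8-neighbour is background
    xs_src <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys_src <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs_dst <- xs_src - dx
    ys_dst <- ys_src - dy
    shifted[xs_dst, ys_dst, ] <- !pool[xs_src, ys_src, ]
    # neighbours beyond the grid edge count as background
    if (dx == 1) shifted[d[1], , ] <- TRUE
    if (dx == -1) shifted[1, , ] <- TRUE
    if (dy == 1) shifted[, d[2], ] <- TRUE
    if (dy == -1) shifted[, 1, ] <- TRUE
    boundary <- boundary | (pool & shifted)
  }
  out <- array(0L, d)
  out[pool] <- 1L
  out[boundary] <- 2L
  out
}

#' Per-slice blood-pool segmentation with a boundary class
#'
#' Classifies every axial slice into background, blood-pool interior and
#' blood-pool boundary (the extra boundary class makes the subsequent graph
#' extraction cleaner), then stacks the slices back to 3D. The oracle
#' backend derives the classes from the truth: pool = chambers + great
#' vessels, boundary = pool voxels with at least one background 8-neighbour
#' in their slice.
#'
#' @param image [intensity_volume()] at full resolution.
#' @param backend Segmentation backend (2D-trained or oracle).
#' @return [label_volume()]-shaped integer array wrapped as a volume with
#'   codes of `bloodpool_classes()`.
#' @export
segment_bloodpool_2d <- function(image, backend) {
  stopifnot(inherits(image, "intensity_volume"))
  if (inherits(backend, "oracle_backend")) {
    stop_geometry(image, backend$truth, "segment_bloodpool_2d")
    out <- bloodpool_oracle(backend$truth)
  } else {
    if (backend$dimensionality != "2D")
      stop("backend was trained for ", backend$dimensionality)
    d <- dim(image$data)
    out <- array(0L, d)
    for (z in seq_len(d[3])) {
      sl <- array(image$data[, , z], c(d[1], d[2], 1))
      out[, , z] <- predict_labels(backend$model, sl, c(0L, 1L, 2L))
    }
  }
  v <- new_volume(out, image$spacing, image$origin, "label_volume")
  storage.mode(v$data) <- "integer"
  v
}
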