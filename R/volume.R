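#' 3D volumes with voxel geometry
#'
#' Lightweight containers for image-space data: a 3D array plus per-axis voxel
#' spacing (mm) and a physical origin (mm). `label_volume()` holds integer
#' structure codes from [label_codes()]; `intensity_volume()` holds CT-like
#' real intensities. Voxel indexing is 0-based in the (x, y, z) axis order of
#' the underlying array, and voxel centre `v` maps to physical position
#' `origin + v * spacing`.
#'
#' @param data 3D array (integer codes or finite numeric intensities).
#' @param spacing Numeric length-3, strictly positive voxel size in mm.
#' @param origin Numeric length-3 physical offset in mm.
#' @return An object of class `label_volume` or `intensity_volume`
#'   (both inherit from `volume3d`).
#' @examples
#' lab <- label_volume(array(0L, c(8, 8, 8)))
#' dim(lab$data)
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- new_volume(data, spacing, origin, "label_volume")
  storage.mode(v$data) <- "integer"
  codes <- c(0L, label_codes(), 8L)  # 8 = transient anomalous-vessel code
  bad <- setdiff(unique(as.vector(v$data)), codes)
  if (length(bad) > 0)
    stop("label volume contains codes outside the taxonomy: ",
         paste(bad, collapse = ", "))
  v
}

#' @rdname label_volume
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- new_volume(data, spacing, origin, "intensity_volume")
  storage.mode(v$data) <- "double"
  if (!all(is.finite(v$data))) stop("intensity volume contains non-finite values")
  v
}

new_volume <- function(data, spacing, origin, class) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = c(class, "volume3d"))
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", class(x)[1],
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

stop_geometry <- function(a, b, what) {
  if (!same_geometry(a, b))
    stop(what, ": volumes differ in shape or spacing", call. = FALSE)
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Volumes are exchanged as `.nii`/`.nii.gz`; labels round-trip as integers,
#' intensities as floats. Spacing is taken from the NIfTI pixdim.
#'
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param kind `"label"` or `"intensity"`.
#' @return `read_volume()` returns a [label_volume()] or [intensity_volume()].
#' @export
read_volume <- function(path, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  spc <- attr(img, "pixdim")[1:3]
  arr <- array(as.vector(img), dim = dim(img)[1:3])
  if (kind == "label") label_volume(round(arr), spacing = spc)
  else intensity_volume(arr, spacing = spc)
}

#' @rdname read_volume
#' @param vol Volume to write.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# voxel centres (n x 3, mm) for a logical/integer selection of voxels
voxel_coords_mm <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), ncol = 3))
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

# nearest-neighbour resample of a label array to new dims
resample_labels <- function(arr, out_dims) {
  out <- cpp_resample3d(as.numeric(arr), dim(arr), as.integer(out_dims), 0L)
  array(as.integer(round(out)), dim = out_dims)
}

# trilinear resample of a numeric array
resample_linear <- function(arr, out_dims) {
  array(cpp_resample3d(as.numeric(arr), dim(arr), as.integer(out_dims), 1L),
        dim = out_dims)
}

# soft label upsampling: trilinear per-class indicator, then argmax
# (half the boundary displacement of nearest-neighbour; ties go to the
# lower code, background competing as its own class)
resample_labels_soft <- function(arr, out_dims) {
  codes <- sort(unique(as.vector(arr)))
  if (length(codes) == 1) return(array(as.integer(codes), out_dims))
  best_val <- array(-Inf, out_dims)
  best_code <- array(as.integer(codes[1]), out_dims)
  for (code in codes) {
    ind <- resample_linear(array(as.numeric(arr == code), dim(arr)), out_dims)
    sel <- ind > best_val
    best_val[sel] <- ind[sel]
    best_code[sel] <- as.integer(code)
  }
  best_code
}

#' Write / read per-voxel class probabilities as 4D NIfTI
#'
#' Probabilities are stored as a 4D volume with class as the fourth axis;
#' each voxel's values must sum to 1 within 1e-6.
#'
#' @param probs 4D array (x, y, z, class).
#' @param path `.nii`/`.nii.gz` path.
#' @param spacing Voxel spacing (mm).
#' @export
write_probability_map <- function(probs, path, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(probs)) == 4)
  sums <- apply(probs, 1:3, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("per-voxel class probabilities must sum to 1")
  img <- RNifti::asNifti(probs)
  RNifti::pixdim(img) <- c(spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.vector(img), dim = dim(img))
}
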