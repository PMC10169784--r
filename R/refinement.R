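#' Refine low-resolution chamber labels with the high-resolution blood pool
#'
#' The blood-pool voxels already covered by (upsampled) chamber labels are
#' treated as claimed; the remaining pool is added to its surrounding
#' chambers by `K` rounds of simultaneous 6-connected competitive dilation
#' restricted to the pool (ties go to the label with more adjacent claimed
#' voxels, then the lowest code). Bounding the growth keeps tube-like
#' vessels out of the chambers: whatever is still unclaimed after `K`
#' rounds is the vessel-only pool handed to the graph stage.
#'
#' @param bloodpool 3D logical array (high-resolution blood-pool mask).
#' @param chambers_lowres [label_volume()] on the same grid (upsample with
#'   nearest-neighbour before calling); only the four chamber codes grow,
#'   any Myo voxels are ignored here. Chamber voxels outside the blood pool
#'   are dropped first — chambers are blood pool by definition, and the
#'   high-resolution pool is precisely the boundary information the
#'   low-resolution stage lost.
#' @param K Number of dilation rounds.
#' @return List: `refined` ([label_volume()] of chamber labels),
#'   `vessel_pool` (logical array of unclaimed pool voxels).
#' @export
refine_chambers <- function(bloodpool, chambers_lowres, K = 5L) {
  stopifnot(inherits(chambers_lowres, "label_volume"))
  if (!identical(dim(bloodpool), dim(chambers_lowres$data)))
    stop("refine_chambers: volumes differ in shape or spacing")
  ch <- chambers_lowres$data
  ch[!(ch %in% chamber_codes())] <- 0L
  ch[bloodpool == 0] <- 0L  # chambers are blood pool; drop low-res overshoot
  pool <- array(as.integer(bloodpool != 0), dim(ch))
  grown <- cpp_competitive_grow(array(as.integer(ch), dim(ch)), pool,
                                dim(ch), as.integer(K), 6L)
  grown <- array(grown, dim(ch))
  vessel_pool <- bloodpool & grown == 0L
  list(refined = label_volume(grown, chambers_lowres$spacing),
       vessel_pool = vessel_pool)
}

#' Refine the myocardium against refined chambers
#'
#' Chambers and myocardium share most of their boundary, so once the
#' chambers are refined the myocardium is adjusted by subtraction: any
#' (upsampled) Myo voxel claimed by a refined chamber is removed.
#'
#' @param myo_lowres 3D logical array of the low-resolution Myo mask
#'   (upsampled to the refined grid).
#' @param refined_chambers [label_volume()] from [refine_chambers()].
#' @return Logical Myo mask disjoint from all refined chambers.
#' @export
refine_myocardium <- function(myo_lowres, refined_chambers) {
  stopifnot(inherits(refined_chambers, "label_volume"))
  if (!identical(dim(myo_lowres), dim(refined_chambers$data)))
    stop("refine_myocardium: volumes differ in shape or spacing")
  myo_lowres & !(refined_chambers$data %in% chamber_codes())
}
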