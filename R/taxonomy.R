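#' Cardiovascular label taxonomy
#'
#' Seven foreground structure codes shared by every stage of the pipeline:
#' left/right ventricle (LV, RV), left/right atrium (LA, RA), myocardium
#' (Myo), aorta (Ao) and pulmonary artery (PA), with 0 as background.
#' By convention the vena cavae carry the RA code and the pulmonary veins the
#' LA code (their boundaries are ill-defined on CT and they are contiguous
#' with the atria); anomalous vessels are ultimately coded as the structure
#' they connect to.
#'
#' @return Named integer vector of the seven structure codes (background
#'   excluded).
#' @examples
#' label_codes()
#' @export
label_codes <- function() {
  c(LV = 1L, RV = 2L, LA = 3L, RA = 4L, Myo = 5L, Ao = 6L, PA = 7L)
}

#' @rdname label_codes
#' @export
structure_names <- function() names(label_codes())

# chamber subset used by refinement / RoI stages
chamber_codes <- function() label_codes()[c("LV", "RV", "LA", "RA")]

# blood pool = chambers + great vessels (myocardium excluded)
bloodpool_codes <- function() label_codes()[c("LV", "RV", "LA", "RA", "Ao", "PA")]

# auxiliary classes of the 2D blood-pool stage
bloodpool_classes <- function() {
  c(background = 0L, bloodpool_interior = 1L, bloodpool_boundary = 2L)
}

#' Vessel meta-categories
#'
#' Great-vessel categories used by graph templates and matching: the aorta,
#' the pulmonary artery, and an explicit third category for anomalous vessels
#' (whose voxels are later re-coded to the structure they attach to).
#'
#' @return Character vector of the three categories.
#' @export
vessel_categories <- function() c("Ao", "PA", "anomalous")

#' Taxonomy conventions
#'
#' @return Named list recording the merge conventions applied when labels are
#'   produced: vena cavae are labelled RA, pulmonary veins are labelled LA.
#' @export
taxonomy_conventions <- function() {
  list(VC = "RA", PV = "LA")
}
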