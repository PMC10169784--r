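#' Dice overlap for one structure
#'
#' `2|P intersect T| / (|P| + |T|)` over the voxels carrying `code` in the
#' prediction and the truth. When the structure is absent from both volumes
#' the score is defined as 1.0 (the structure is correctly absent — relevant
#' in CHD where e.g. a pulmonary trunk can be genuinely missing).
#'
#' @param pred,truth [label_volume()]s sharing shape and spacing.
#' @param code Integer structure code (see [label_codes()]).
#' @return Dice fraction in `[0, 1]`.
#' @examples
#' a <- label_volume(array(c(1L, 1L, 0L, 0L), c(4, 1, 1)))
#' b <- label_volume(array(c(0L, 1L, 1L, 0L), c(4, 1, 1)))
#' dice_score(a, b, 1L)  # one shared voxel of two each -> 0.5
#' @export
dice_score <- function(pred, truth, code) {
  stop_geometry(pred, truth, "dice_score")
  p <- pred$data == code
  t <- truth$data == code
  np <- sum(p); nt <- sum(t)
  if (np + nt == 0L) return(1.0)
  2 * sum(p & t) / (np + nt)
}

#' Combined Dice + cross-entropy segmentation loss
#'
#' The training loss of the segmentation stages: a soft multi-class Dice term
#' averaged over classes plus a mean cross-entropy term,
#' \deqn{L = \Big(1 - \frac1C \sum_j
#'   \frac{2\sum_i p_i^j g_i^j}{\sum_i (p_i^j + g_i^j)}\Big)
#'   + \frac{1}{NC} \sum_j \sum_i -g_i^j \log p_i^j,}
#' where \eqn{p_i^j} is the predicted probability and \eqn{g_i^j} the one-hot
#' ground truth of voxel \eqn{i}, class \eqn{j}. A smoothing constant
#' (`eps = 1e-6`) is added to numerator and denominator of each Dice ratio so
#' classes absent from both maps contribute a ratio of 1 (no penalty) instead
#' of 0/0. Probabilities are clamped to `[1e-7, 1]` before the log.
#'
#' @param p N x C matrix of class probabilities, rows summing to 1.
#' @param g N x C one-hot matrix (0/1, rows summing to 1).
#' @param eps Dice smoothing constant.
#' @return Non-negative scalar loss; 0 iff `p` equals `g` exactly.
#' @examples
#' g <- matrix(c(1, 0), 1)
#' combined_loss(g, g)                    # 0
#' combined_loss(matrix(c(.5, .5), 1), g) # ~1.013
#' @export
combined_loss <- function(p, g, eps = 1e-6) {
  p <- as.matrix(p); g <- as.matrix(g)
  if (!all(dim(p) == dim(g))) stop("p and g must share dimensions")
  N <- nrow(p); C <- ncol(p)
  if (N == 0 || C == 0) stop("empty probability map")
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) stop("probabilities outside [0, 1]")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-6)) stop("probability rows must sum to 1")
  if (!all(g %in% c(0, 1)) || any(rowSums(g) != 1))
    stop("g must be one-hot with exactly one 1 per row")
  inter <- colSums(p * g)
  denom <- colSums(p + g)
  dice_term <- 1 - mean((2 * inter + eps) / (denom + eps))
  pc <- pmin(pmax(p, 1e-7), 1)
  ce_term <- sum(-g * log(pc)) / (N * C)
  dice_term + ce_term
}

# one-hot encode a label array over the given codes (class 1 = code codes[1]);
# voxels not matching any code are an error unless a background column (code 0)
# is included
one_hot <- function(labels, codes) {
  lab <- as.vector(labels)
  m <- matrix(0, length(lab), length(codes))
  for (j in seq_along(codes)) m[lab == codes[j], j] <- 1
  if (any(rowSums(m) != 1)) stop("labels contain codes not covered by `codes`")
  m
}
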