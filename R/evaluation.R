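#' Per-structure Dice evaluation of one case
#'
#' Computes the Dice score of the seven structures plus their mean
#' ("overall"). Structures absent from both prediction and truth score 1.0
#' (correctly absent — CHD cases can genuinely lack a structure) and are
#' listed in the `absent` attribute.
#'
#' @param pred,truth [label_volume()]s with shared geometry.
#' @return Named numeric vector `LV, RV, LA, RA, Myo, Ao, PA, overall`.
#' @export
evaluate_case <- function(pred, truth) {
  stop_geometry(pred, truth, "evaluate_case")
  codes <- label_codes()
  d <- vapply(codes, function(code) dice_score(pred, truth, code), 1.0)
  absent <- names(codes)[vapply(codes, function(code)
    !any(pred$data == code) && !any(truth$data == code), TRUE)]
  out <- c(d, overall = mean(d))
  attr(out, "absent") <- absent
  out
}

#' Assemble evaluation rows into a score table
#'
#' @param rows List of vectors from [evaluate_case()] (or a matrix).
#' @param case_ids Optional row names.
#' @return `score_table` data.frame with columns
#'   `LV, RV, LA, RA, Myo, Ao, PA, overall`.
#' @export
score_table <- function(rows, case_ids = NULL) {
  m <- do.call(rbind, lapply(rows, as.numeric))
  colnames(m) <- c(structure_names(), "overall")
  df <- as.data.frame(m)
  if (!is.null(case_ids)) rownames(df) <- case_ids
  stopifnot(all(m >= 0 & m <= 1),
            max(abs(df$overall - rowMeans(df[structure_names()]))) < 1e-9)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Column means and standard deviations of a score table
#'
#' @param table A [score_table()] (>= 1 row).
#' @return data.frame with rows `mean` and `sd` (sample s.d., n-1
#'   denominator; `NA` when n = 1).
#' @export
summarize_scores <- function(table) {
  if (nrow(table) < 1) stop("empty score table")
  data.frame(mean = colMeans(table),
             sd = apply(table, 2, function(x) if (length(x) > 1) sd(x) else NA))
}

#' Paired t test between two methods' per-case scores
#'
#' Two-sided paired t test on the per-case differences `a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#' Identical pairings (zero-variance differences) are reported as an error
#' rather than an infinite statistic.
#'
#' @param a,b Equal-length numeric score vectors paired by case (n >= 2).
#' @return List with `t`, `p` (two-sided), `df`, `mean_diff`.
#' @examples
#' paired_t_test(c(2, 3, 5), c(1, 2, 3))$t  # 4
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  s <- sd(d)
  if (s == 0) stop("degenerate pairing: differences have zero variance")
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  list(t = t, p = p, df = n - 1, mean_diff = mean(d))
}

#' Write a score table (and optional summary) as CSV
#'
#' @param table A [score_table()].
#' @param path CSV output path.
#' @param summary_path Optional path for the mean/sd summary (CSV).
#' @export
write_scores <- function(table, path, summary_path = NULL) {
  write.csv(table, path, row.names = TRUE)
  if (!is.null(summary_path))
    write.csv(summarize_scores(table), summary_path, row.names = TRUE)
  invisible(path)
}

#' Seeded cross-validation over a phantom suite
#'
#' Orchestrates a fold-stratified evaluation of the full pipeline over a
#' generated phantom suite: cases are assigned to folds stratified by anomaly
#' flag (every fold sees every topology family), and each case is segmented
#' with oracle backends and scored against its truth. With oracle backends no
#' training happens, so folds only structure the reporting; the same
#' orchestration applies when trained backends are substituted per fold.
#'
#' @param n Suite size.
#' @param seed Suite seed.
#' @param folds Number of folds (cases are dealt round-robin within each
#'   anomaly flag).
#' @param shape,spacing Phantom grid, see [generate_phantom()].
#' @return A [score_table()] with a `fold` attribute (integer per case).
#' @export
crossval_oracle <- function(n = 20, seed = 1L, folds = 4L,
                            shape = c(96, 96, 96), spacing = c(1, 1, 1)) {
  suite <- phantom_suite(n, seed = seed, shape = shape, spacing = spacing)
  flags <- vapply(suite, function(ph) ph$spec$anomaly, "")
  fold <- integer(n)
  for (fl in unique(flags)) {
    idx <- which(flags == fl)
    fold[idx] <- ((seq_along(idx) - 1) %% folds) + 1L
  }
  lib <- default_graph_library()
  rows <- lapply(suite, function(ph) {
    b3 <- oracle_backend(ph$body_truth)
    b2 <- oracle_backend(ph$truth)
    segment_case(ph$image, b3, b2, lib, truth = ph$truth)$scores
  })
  tab <- score_table(rows, case_ids = sprintf("case%02d_%s", seq_len(n), flags))
  attr(tab, "fold") <- fold
  tab
}
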