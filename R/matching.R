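#' Represent a vessel graph as a weighted point distribution
#'
#' Every edge sample becomes a bin at its position; the bin weight is
#' \eqn{r^3}, the cube of the inscribed-sphere radius, so a bin's mass is
#' proportional to the blood-pool volume around the sample. Before matching,
#' coordinates are mapped to a normalized frame — translated to the weighted
#' centroid and scaled by the weighted RMS radius — making the earth mover's
#' distance invariant to rigid translation and global size, and weights are
#' normalized to total mass 1.
#'
#' @param graph A `vessel_graph` with at least one edge sample.
#' @param normalize Apply frame and mass normalization (default `TRUE`).
#' @return A `point_distribution`: `positions` (n x 3), `weights` (sum 1 when
#'   normalized), plus the `center` and `scale` of the frame map.
#' @export
graph_to_distribution <- function(graph, normalize = TRUE) {
  s <- graph_samples(graph)
  if (nrow(s) == 0) stop("graph has no sample points")
  w <- s[, "r"]^3
  if (all(w <= 0)) stop("degenerate distribution: all sample radii are zero")
  pos <- s[, c("x", "y", "z"), drop = FALSE]
  center <- c(0, 0, 0); scale <- 1
  if (normalize) {
    wn <- w / sum(w)
    center <- colSums(pos * wn)
    pos <- sweep(pos, 2, center)
    scale <- sqrt(sum(wn * rowSums(pos^2)))
    if (scale <= 0) scale <- 1
    pos <- pos / scale
    w <- wn
  }
  structure(list(positions = pos, weights = w, center = center,
                 scale = scale), class = "point_distribution")
}

point_distribution <- function(positions, weights, normalize = TRUE) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  weights <- as.numeric(weights)
  stopifnot(nrow(positions) == length(weights), all(weights >= 0),
            any(weights > 0))
  center <- c(0, 0, 0); scale <- 1
  if (normalize) weights <- weights / sum(weights)
  structure(list(positions = positions, weights = weights, center = center,
                 scale = scale), class = "point_distribution")
}

#' Earth mover's distance between two normalized distributions
#'
#' Minimum-cost transport of one unit of mass under Euclidean ground
#' distance, computed exactly by a successive-shortest-path min-cost-flow
#' solver. A metric on weighted point sets: zero iff the distributions
#' coincide, symmetric, and satisfying the triangle inequality.
#'
#' @param a,b `point_distribution`s with total mass 1 (within 1e-9).
#' @return Non-negative transport cost.
#' @examples
#' p <- point_distribution(rbind(c(0, 0, 0)), 1)
#' q <- point_distribution(rbind(c(3, 4, 0)), 1)
#' emd(p, q)  # 5
#' @export
emd <- function(a, b) {
  stopifnot(inherits(a, "point_distribution"), inherits(b, "point_distribution"))
  if (abs(sum(a$weights) - 1) > 1e-9 || abs(sum(b$weights) - 1) > 1e-9)
    stop("emd requires distributions normalized to total mass 1")
  ka <- a$weights > 0; kb <- b$weights > 0
  pa <- a$positions[ka, , drop = FALSE]; wa <- a$weights[ka]
  pb <- b$positions[kb, , drop = FALSE]; wb <- b$weights[kb]
  cost <- sqrt(pmax(outer(rowSums(pa^2), rep(1, nrow(pb))) +
                      outer(rep(1, nrow(pa)), rowSums(pb^2)) -
                      2 * pa %*% t(pb), 0))
  cpp_emd(wa, wb, cost)
}

.chdseg_cache <- new.env(parent = emptyenv())

#' Build the default template library
#'
#' One template per anomaly family. Each template is produced by running
#' the non-learned half of the pipeline on the canonical (unjittered)
#' anatomy of that family: the canonical truth is rasterized, the chambers
#' are subtracted and grown into the blood pool exactly as at inference
#' time, and the resulting vessel pool is skeletonised and sampled. The
#' template therefore lives in the same representation as any candidate
#' graph — truncated vessel roots, distance-transform radii — so the EMD
#' between a candidate and the templates is dominated by genuine
#' topological/geometric differences between the families. Every sample
#' carries the vessel category (Ao / PA / anomalous) read from the
#' canonical truth; key points (vessel roots and tips) and their
#' connections are recorded from the canonical centerlines.
#'
#' @param K,threshold Refinement / smoothing parameters; match the values
#'   used at inference time.
#' @return A `graph_library`: list of `graph_template`s ordered by id
#'   (id order = [anomaly_flags()] order).
#' @export
default_graph_library <- function(K = 5L, threshold = 14L) {
  key <- paste0("library_", K, "_", threshold)
  if (!is.null(.chdseg_cache[[key]])) return(.chdseg_cache[[key]])
  lib <- lapply(seq_along(anomaly_flags()), function(i) {
    flag <- anomaly_flags()[i]
    spec <- canonical_anatomy(flag, noise_sigma = 0)
    case <- generate_phantom(spec)
    template_from_truth(case, id = i, K = K, threshold = threshold)
  })
  lib <- structure(lib, class = "graph_library")
  .chdseg_cache[[key]] <- lib
  lib
}

# build one template from a phantom case's ground truth
template_from_truth <- function(case, id, K = 5L, threshold = 14L) {
  truth <- case$truth
  body <- if (!is.null(case$body_truth)) case$body_truth else truth
  spacing <- truth$spacing
  pool <- array(truth$data %in% bloodpool_codes(), dim(truth$data))
  ref <- refine_chambers(pool, body, K = K)
  dmap <- radius_map(ref$vessel_pool, spacing)
  sk <- skeletonize_mask(smooth_mask(ref$vessel_pool, 1L, threshold), spacing)
  g <- extract_graph(sk, dmap, spacing, sample_spacing = 2, provenance = 1L)
  s <- graph_samples(g)
  w <- s[, "r"]^3
  wn <- w / sum(w)
  center <- colSums(s[, 1:3, drop = FALSE] * wn)
  pos <- sweep(s[, 1:3, drop = FALSE], 2, center)
  scale <- sqrt(sum(wn * rowSums(pos^2)))
  pos <- pos / scale

  # per-sample category from the truth code at (or nearest to) the sample
  codes <- label_codes()
  vox <- pmin(pmax(round(sweep(s[, 1:3, drop = FALSE], 2, spacing, "/")) + 1, 1),
              matrix(dim(truth$data), nrow(s), 3, byrow = TRUE))
  code_at <- truth$data[vox]
  categories <- ifelse(code_at == codes[["Ao"]], "Ao",
                       ifelse(code_at == codes[["PA"]], "PA", "anomalous"))

  keypoints <- list(); connections <- list()
  for (v in case$truth_graph) {
    n <- nrow(v$centerline)
    keypoints[[length(keypoints) + 1]] <-
      list(xyz = (v$centerline[1, ] - center) / scale, category = v$category,
           name = paste0(v$name, "_root"))
    keypoints[[length(keypoints) + 1]] <-
      list(xyz = (v$centerline[n, ] - center) / scale, category = v$category,
           name = paste0(v$name, "_tip"))
    connections[[length(connections) + 1]] <-
      c(length(keypoints) - 1L, length(keypoints))
  }
  structure(list(id = id, tag = case$spec$anomaly, positions = pos,
                 weights = wn, categories = categories,
                 keypoints = keypoints, connections = connections),
            class = "graph_template")
}

#' @export
print.graph_library <- function(x, ...) {
  cat("<graph_library> templates:",
      paste(vapply(x, function(t) sprintf("%d:%s", t$id, t$tag), ""),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a graph library as JSON
#'
#' @param library A `graph_library`.
#' @param path JSON file path.
#' @export
write_graph_library <- function(library, path) {
  obj <- lapply(library, function(t)
    list(id = t$id, tag = t$tag,
         keypoints = lapply(t$keypoints, function(k)
           list(xyz = as.numeric(k$xyz), category = k$category,
                name = k$name)),
         connections = t$connections,
         samples = lapply(seq_len(nrow(t$positions)), function(i)
           list(xyz = as.numeric(t$positions[i, ]), w = t$weights[i],
                category = if (!is.null(t$categories)) t$categories[i]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph_library
#' @export
read_graph_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lib <- lapply(obj, function(t) {
    pos <- t(vapply(t$samples, function(s) as.numeric(unlist(s$xyz)),
                    numeric(3)))
    w <- vapply(t$samples, function(s) as.numeric(s$w), 1)
    cats <- vapply(t$samples, function(s)
      if (is.null(s$category)) NA_character_ else s$category, "")
    structure(list(id = t$id, tag = t$tag, positions = pos, weights = w,
                   categories = if (!anyNA(cats)) cats,
                   keypoints = lapply(t$keypoints, function(k)
                     list(xyz = as.numeric(unlist(k$xyz)),
                          category = k$category, name = k$name)),
                   connections = lapply(t$connections,
                                        function(cn) as.integer(unlist(cn)))),
              class = "graph_template")
  })
  structure(lib, class = "graph_library")
}

template_distribution <- function(template) {
  structure(list(positions = template$positions, weights = template$weights,
                 center = c(0, 0, 0), scale = 1),
            class = "point_distribution")
}

#' Match candidate graphs against the template library
#'
#' Every (candidate, template) pair is scored by the EMD between their
#' normalized distributions; the minimum-EMD pair wins (ties go to the
#' smaller scale `k`, then the lower template id). Each candidate edge then
#' inherits a vessel category by majority vote of its samples' nearest
#' template key points (in the normalized frame).
#'
#' @param candidates Non-empty list of `vessel_graph`s (e.g. from
#'   [candidate_graphs()]).
#' @param library A `graph_library`.
#' @return A `match_result`: chosen `graph`, `scale`, `template_id`,
#'   `template_tag`, `emd` value, `edge_categories` (one per edge of the
#'   chosen graph), and the full `emd_matrix` (candidate x template).
#' @export
match_graphs <- function(candidates, library) {
  if (length(candidates) == 0) stop("vessel pool vanished: no candidate graphs")
  if (length(library) == 0) stop("configuration error: empty graph library")
  dists <- lapply(candidates, graph_to_distribution)
  tdists <- lapply(library, template_distribution)
  scores <- matrix(NA_real_, length(candidates), length(library))
  for (i in seq_along(candidates))
    for (j in seq_along(library))
      scores[i, j] <- emd(dists[[i]], tdists[[j]])
  best <- which(scores == min(scores), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  ci <- best[1]; tj <- best[2]
  graph <- candidates[[ci]]
  template <- library[[tj]]
  dist <- dists[[ci]]

  # reference points: per-sample categories when the template has them,
  # otherwise its key points
  if (!is.null(template$categories)) {
    ref_pos <- template$positions
    ref_cat <- template$categories
  } else {
    ref_pos <- t(vapply(template$keypoints, function(k) k$xyz, numeric(3)))
    ref_cat <- vapply(template$keypoints, function(k) k$category, "")
  }
  cats <- vessel_categories()
  edge_categories <- vapply(graph$edges, function(e) {
    pos <- sweep(e$samples[, 1:3, drop = FALSE], 2, dist$center) / dist$scale
    nearest <- cpp_nearest_point(pos, ref_pos)
    votes <- table(factor(ref_cat[nearest], levels = cats))
    cats[which.max(votes)]  # ties resolve to the first category in order
  }, "")

  structure(list(graph = graph, scale = graph$provenance,
                 template_id = template$id, template_tag = template$tag,
                 emd = scores[ci, tj], edge_categories = edge_categories,
                 emd_matrix = scores),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> template %d (%s), scale k=%s, EMD %.4f\n",
              x$template_id, x$template_tag, x$scale, x$emd))
  invisible(x)
}

#' Transfer matched categories to vessel-pool voxels
#'
#' Voxels of the vessel pool that survive the chosen smoothing scale take
#' the category of the nearest edge sample of the matched graph (Ao code 6,
#' PA code 7). Anomalous-category voxels are re-coded to the structure they
#' connect to: each anomalous component takes the code of the chamber it
#' touches (or the nearest chamber) when `chambers` is supplied, matching
#' the convention that anomalous vessels are labelled by their connections.
#'
#' @param match A `match_result`.
#' @param vessel_pool Logical array the matched graph was extracted from.
#' @param spacing Voxel spacing (mm).
#' @param chambers Optional [label_volume()] of refined chamber labels used
#'   to resolve anomalous connections.
#' @param threshold Smoothing threshold (must match [candidate_graphs()]).
#' @return [label_volume()] with codes on the smoothed-scale voxels only
#'   (leftovers are handled by [grow_leftovers()]).
#' @export
transfer_labels <- function(match, vessel_pool, spacing = c(1, 1, 1),
                            chambers = NULL, threshold = 14L) {
  codes <- label_codes()
  cat_code <- c(Ao = unname(codes[["Ao"]]), PA = unname(codes[["PA"]]),
                anomalous = 8L)
  sm <- smooth_mask(vessel_pool, match$scale, threshold)
  sm <- sm & vessel_pool
  out <- array(0L, dim(vessel_pool))
  if (any(sm) && length(match$graph$edges) > 0) {
    samples <- graph_samples(match$graph)
    sample_cat <- rep(match$edge_categories,
                      vapply(match$graph$edges, function(e) nrow(e$samples), 1L))
    vox <- voxel_coords_mm(sm, spacing)
    nearest <- cpp_nearest_point(vox, samples[, 1:3, drop = FALSE])
    out[which(sm)] <- cat_code[sample_cat[nearest]]
  }
  out <- resolve_anomalous(out, chambers, spacing)
  label_volume(out, spacing)
}

# re-code transient anomalous components (code 8) to the chamber they touch,
# else the nearest chamber; without chamber labels they stay code 8
resolve_anomalous <- function(labels, chambers, spacing) {
  if (is.null(chambers) || !any(labels == 8L)) return(labels)
  ch_codes <- chamber_codes()
  comp <- cpp_label_components(array(as.integer(labels == 8L), dim(labels)),
                               dim(labels), 26L)
  ch_mask <- array(chambers$data * (chambers$data %in% ch_codes),
                   dim(labels))
  ch_coords <- voxel_coords_mm(ch_mask != 0, spacing)
  ch_vals <- ch_mask[ch_mask != 0]
  for (cid in setdiff(unique(as.vector(comp)), 0L)) {
    sel <- comp == cid
    # chamber adjacency via one dilation step of the component
    grown <- cpp_competitive_grow(array(as.integer(sel), dim(labels)),
                                  array(1L, dim(labels)), dim(labels), 1L, 26L)
    touch <- ch_mask[grown == 1L & !sel]
    touch <- touch[touch != 0]
    code <- if (length(touch) > 0) {
      tt <- table(touch)
      as.integer(names(tt)[which.max(tt)])
    } else if (nrow(ch_coords) > 0) {
      pts <- voxel_coords_mm(sel, spacing)
      ch_vals[cpp_nearest_point(pts[1, , drop = FALSE], ch_coords)[1]]
    } else 8L
    labels[sel] <- code
  }
  labels
}

#' Region-grow labels into leftover vessel voxels
#'
#' Vessel-pool voxels erased by smoothing (hence unlabeled by
#' [transfer_labels()]) are absorbed by iterative 26-connected growth from
#' the labelled voxels until no unlabeled voxel has a labelled neighbour.
#' Simultaneous fronts compete: a voxel takes the label with the most
#' adjacent claimed voxels, ties to the lowest code. Components with no
#' labelled contact are returned unresolved.
#'
#' @param labels [label_volume()] covering a subset of `vessel_pool`.
#' @param vessel_pool Logical array.
#' @return [label_volume()] with an attribute `unresolved` (integer count of
#'   voxels in components that no labelled front could reach).
#' @export
grow_leftovers <- function(labels, vessel_pool) {
  lab <- labels$data
  lab[!vessel_pool] <- 0L  # growth is confined to the pool
  grown <- cpp_competitive_grow(array(lab, dim(lab)),
                                array(as.integer(vessel_pool), dim(lab)),
                                dim(lab), -1L, 26L)
  out <- array(grown, dim(lab))
  unresolved <- sum(vessel_pool & out == 0L)
  res <- labels
  res$data <- array(ifelse(vessel_pool, out, labels$data), dim(lab))
  storage.mode(res$data) <- "integer"
  attr(res, "unresolved") <- unresolved
  res
}
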