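#' End-to-end segmentation of one volume
#'
#' Runs the full pipeline: RoI cropping, low-resolution 3D
#' chambers/myocardium segmentation, per-slice blood-pool segmentation,
#' chamber and myocardium boundary refinement, multi-scale candidate-graph
#' extraction of the vessel pool, EMD template matching, label transfer and
#' region growing of leftover vessels. The final volume combines refined
#' chambers, refined myocardium and classified vessels.
#'
#' @param image [intensity_volume()] to segment.
#' @param backend_3d,backend_2d Backends for the 3D and 2D stages (the same
#'   [oracle_backend()] may serve both).
#' @param library [default_graph_library()] or one read from JSON.
#' @param truth Optional [label_volume()]; when given, a Dice row is
#'   computed.
#' @param K Chamber-growth iterations of [refine_chambers()].
#' @param threshold Smoothing threshold of [smooth_mask()].
#' @param sample_spacing Graph resampling distance (mm).
#' @param margin RoI margin in coarse voxels.
#' @return A `pipeline_result`: `labels` (final [label_volume()]), `match`
#'   (`match_result`), `vessel_pool`, `scores` (or `NULL`), `unresolved`.
#' @export
segment_case <- function(image, backend_3d, backend_2d, library,
                         truth = NULL, K = 5L, threshold = 14L,
                         sample_spacing = 2, margin = 8L) {
  d <- dim(image$data)
  roi <- crop_roi(image, backend_3d, margin = margin)
  ch64 <- segment_chambers_3d(roi$roi, backend_3d)
  bp <- segment_bloodpool_2d(image, backend_2d)

  # upsample coarse labels into the RoI box, then embed at full resolution
  ch_roi <- resample_labels_soft(ch64$data, dim(roi$roi$data))
  ch_full <- array(0L, d)
  idx <- Map(function(o, s) (o + 1):(o + s), roi$offset, dim(roi$roi$data))
  ch_full[idx[[1]], idx[[2]], idx[[3]]] <- ch_roi
  ch_full_vol <- label_volume(ch_full, image$spacing)

  pool <- bp$data > 0L
  ref <- refine_chambers(pool, ch_full_vol, K = K)
  # myocardium = low-res Myo plus low-res chamber voxels the high-resolution
  # pool rejects (non-blood foreground can only be muscle), minus chambers
  myo_lowres <- ch_full == label_codes()[["Myo"]] |
    (array(ch_full %in% chamber_codes(), d) & !pool)
  myo <- refine_myocardium(myo_lowres, ref$refined)

  cand <- candidate_graphs(ref$vessel_pool, spacing = image$spacing,
                           sample_spacing = sample_spacing,
                           threshold = threshold)
  match <- match_graphs(cand, library)
  vlab <- transfer_labels(match, ref$vessel_pool, spacing = image$spacing,
                          chambers = ref$refined, threshold = threshold)
  vlab <- grow_leftovers(vlab, ref$vessel_pool)

  final <- ref$refined$data
  final[myo] <- label_codes()[["Myo"]]
  vmask <- vlab$data > 0L
  final[vmask] <- vlab$data[vmask]
  final_vol <- label_volume(final, image$spacing)

  scores <- if (!is.null(truth)) evaluate_case(final_vol, truth) else NULL
  structure(list(labels = final_vol, match = match,
                 vessel_pool = ref$vessel_pool, scores = scores,
                 unresolved = attr(vlab, "unresolved")),
            class = "pipeline_result")
}

#' Pipeline configuration
#'
#' File-level configuration for [run_pipeline()]; can be written to / read
#' from YAML. Referenced input files must exist.
#'
#' @param image Path to the input volume (`.nii`/`.nii.gz`).
#' @param out_prefix Output path prefix.
#' @param library Path to a graph-library JSON, or `"builtin"` for
#'   [default_graph_library()].
#' @param truth Optional truth volume path.
#' @param backend `"oracle"` (requires `truth`) or `"trained"`.
#' @param weights_3d,weights_2d RDS paths of trained backends when
#'   `backend = "trained"`.
#' @param K,threshold,sample_spacing,margin Stage parameters, see
#'   [segment_case()].
#' @param seed Seed recorded in provenance.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(image, out_prefix, library = "builtin",
                            truth = NULL, backend = c("oracle", "trained"),
                            weights_3d = NULL, weights_2d = NULL, K = 5L,
                            threshold = 14L, sample_spacing = 2, margin = 8L,
                            seed = 1L) {
  backend <- match.arg(backend)
  cfg <- list(image = image, out_prefix = out_prefix, library = library,
              truth = truth, backend = backend, weights_3d = weights_3d,
              weights_2d = weights_2d, K = as.integer(K),
              threshold = as.integer(threshold),
              sample_spacing = sample_spacing, margin = as.integer(margin),
              seed = as.integer(seed))
  for (f in c("image", "truth", "weights_3d", "weights_2d")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configuration error: ", f, " file not found: ", cfg[[f]])
  }
  if (!identical(library, "builtin") && !file.exists(library))
    stop("configuration error: graph library not found: ", library)
  if (backend == "oracle" && is.null(truth))
    stop("configuration error: oracle backend requires a truth volume")
  if (backend == "trained" && (is.null(weights_3d) || is.null(weights_2d)))
    stop("configuration error: trained backend requires weights files")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the pipeline from a configuration
#'
#' Loads the inputs named by the configuration, executes [segment_case()],
#' and writes the label volume (`<prefix>_labels.nii.gz`), the match result
#' and provenance (`<prefix>_match.json`, `<prefix>_provenance.json`) and,
#' when truth is available, a one-row Dice CSV (`<prefix>_scores.csv`).
#' Partial outputs are removed if any stage fails.
#'
#' @param config A [pipeline_config()].
#' @return The `pipeline_result`, invisibly augmented with output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  image <- read_volume(config$image, "intensity")
  truth <- if (!is.null(config$truth)) read_volume(config$truth, "label")
  library <- if (identical(config$library, "builtin")) default_graph_library()
  else read_graph_library(config$library)
  if (config$backend == "oracle") {
    b3 <- oracle_backend(truth); b2 <- b3
  } else {
    b3 <- readRDS(config$weights_3d)
    b2 <- readRDS(config$weights_2d)
  }
  paths <- paste0(config$out_prefix,
                  c("_labels.nii.gz", "_match.json", "_provenance.json",
                    "_scores.csv"))
  res <- tryCatch(
    segment_case(image, b3, b2, library, truth = truth, K = config$K,
                 threshold = config$threshold,
                 sample_spacing = config$sample_spacing,
                 margin = config$margin),
    error = function(e) {
      unlink(paths[file.exists(paths)])
      stop(e)
    })
  write_volume(res$labels, paths[1])
  jsonlite::write_json(
    list(template_id = res$match$template_id,
         template_tag = res$match$template_tag, scale = res$match$scale,
         emd = res$match$emd, edge_categories = res$match$edge_categories,
         unresolved = res$unresolved),
    paths[2], auto_unbox = TRUE, digits = NA)
  cfg_plain <- unclass(config)
  jsonlite::write_json(
    list(config = cfg_plain[!vapply(cfg_plain, is.null, TRUE)],
         config_hash = config_digest(cfg_plain),
         package_version = as.character(utils::packageVersion("chdseg")),
         r_version = R.version.string),
    paths[3], auto_unbox = TRUE, digits = NA)
  if (!is.null(res$scores))
    write_scores(score_table(list(res$scores), basename(config$image)),
                 paths[4])
  res$paths <- paths
  invisible(res)
}

# small deterministic config digest without extra dependencies
config_digest <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}
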