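#' Run the full analysis pipeline on a synthetic dataset
#'
#' Generates (or reuses) a synthetic time-lapse, then runs every analysis
#' stage end to end: drift estimation on the nuclei channel and correction
#' of the stack, contour segmentation of the cell through time, shape
#' descriptors with rounding detection, track kinematics with speed
#' stratification, speed-conditioned protrusion-angle histograms, axial
#' polarity profiles with the rear-enrichment index, apico-basal depth
#' relative to the OPL, and centrosome offset. All result tables plus a
#' run manifest are written to \code{out_dir}.
#'
#' @param config a \code{\link{sim_config}} describing the dataset.
#' @param out_dir output directory.
#' @param seed optional integer overriding \code{config$seed}.
#' @param dataset_dir optional existing dataset directory (from
#'   \code{\link{generate_dataset}}); when given, \code{config} is ignored
#'   and the dataset is loaded instead of simulated.
#' @return invisibly, a list with every intermediate result and
#'   \code{manifest} (path of the manifest file).
#' @export
run_all <- function(config = sim_config(), out_dir, seed = NULL,
                    dataset_dir = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(dataset_dir)) {
    dataset_dir <- file.path(out_dir, "dataset")
    gen <- generate_dataset(config, dataset_dir)
    ds <- list(stack = gen$render$stack, config = config,
               track = gen$kin$track, protrusions = gen$kin$protrusions,
               centrosome = gen$kin$centrosome, contours = gen$kin$contours,
               drift = gen$render$truth_drift, geometry = gen$kin$geometry)
  } else {
    ds <- read_dataset(dataset_dir)
    config <- ds$config
  }
  iv <- config$frame_interval_min

  drift <- estimate_drift(ds$stack, channel = "nuclei", reference_frame = 0L)
  stack_c <- apply_drift_correction(ds$stack, drift)

  seed_xy <- c(ds$track$x_um[ds$track$frame == 0],
               ds$track$y_um[ds$track$frame == 0])
  series <- segment_series(stack_c, seed_xy, channel = "cell")
  shapes <- shape_series_stats(series)

  vel <- velocities(ds$track, iv)
  thr <- speed_thresholds(vel)
  angles <- angle_histograms(ds$track, ds$protrusions, vel, thr)
  prof <- polarity_profiles(stack_c, series, vel)
  enrich <- rear_enrichment(prof$profiles)
  depth <- depth_relative_to_layer(ds$track, ds$geometry, "OPL")
  centro <- centrosome_offset(ds$track, ds$centrosome, vel)

  tables <- list(
    drift = as.data.frame(drift),
    contours = contour_series_df(series),
    shape_series = shapes$records,
    shape_summary = cbind(shapes$summary,
                          rounding_frame = shapes$rounding_frame),
    velocity = as.data.frame(vel),
    speed_thresholds = data.frame(p25_um_min = thr$p25_um_min,
                                  p75_um_min = thr$p75_um_min),
    speed_classes = thr$classes,
    angle_samples = angles$samples,
    angle_histograms = angle_histogram_df(angles),
    polarity_profile = enrich$profile,
    polarity_summary = data.frame(rear_enrichment_index = enrich$index,
                                  rear_enrichment_index_norm = enrich$index_norm,
                                  n_frames = enrich$n_frames),
    depth = as.data.frame(depth),
    depth_summary = data.frame(layer = "OPL",
                               final_depth_um = attr(depth, "final_depth_um"),
                               max_basal_depth_um = attr(depth, "max_basal_depth_um")),
    centrosome_offset = centro,
    track_summary = track_summary(ds$track, iv))
  manifest <- write_results(tables, out_dir,
                            inputs = list(dataset = dataset_dir,
                                          config = unclass(config)),
                            seed = config$seed)
  invisible(list(dataset = ds, drift = drift, series = series,
                 shapes = shapes, vel = vel, thresholds = thr,
                 angles = angles, enrichment = enrich, depth = depth,
                 centrosome = centro, tables = tables, manifest = manifest))
}
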