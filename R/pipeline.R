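#' Run the full post-processing pipeline on one partition
#'
#' Chains the per-partition stages: measure all labeled objects on the
#' prepared image, remove false-positive segmentations, fit ellipses to the
#' kept objects, gate near-circular fits, and correct orientations for
#' layer curvature against the centerline. Returns the per-neuron
#' orientation records plus the filter audit trail.
#'
#' @param image prepared [section_image()] (inverted, somata bright).
#' @param mask label mask matrix of identical dimensions.
#' @param line a [centerline()] for this partition.
#' @param subregion,case_id,slide_id partition metadata.
#' @param config a [filter_config()].
#' @param min_ratio eccentricity gate threshold.
#' @return list with `records` (orientation records of kept neurons),
#'   `filter` (the `filter_result`), and `summary` (one-row collinearity
#'   summary of the partition).
#' @export
analyze_partition <- function(image, mask, line,
                              subregion = NA_character_,
                              case_id = NA_character_,
                              slide_id = NA_character_,
                              config = filter_config(), min_ratio = 1.05) {
  segs <- measure_segments(mask, image)
  if (!nrow(segs)) {
    return(list(records = correct_orientations(
      fit_segment_ellipses(segs, mask, image_pixel_size(image), min_ratio),
      line, subregion, case_id, slide_id),
      filter = NULL, summary = NULL))
  }
  thr <- if (identical(config$grey_rule, "auto_midpoint"))
    grey_threshold(image, mask) else NULL
  fr <- apply_filters(segs, config, thr)
  kept <- fit_segment_ellipses(fr$kept, mask, image_pixel_size(image),
                               min_ratio)
  records <- correct_orientations(kept, line, subregion, case_id, slide_id)
  ok <- !is.na(records$coo_deg)
  summ <- if (any(ok)) data.frame(
    subregion = subregion, case_id = case_id, slide_id = slide_id,
    n = sum(ok),
    dev = mean_angular_deviation(records$coo_deg[ok]),
    var = circular_variance(records$coo_deg[ok])
  ) else NULL
  list(records = records, filter = fr, summary = summ)
}

#' Run the pipeline on a synthetic scene
#'
#' Convenience wrapper for ground-truthed scenes from [generate_scene()]:
#' prepares the raw render (invert + contrast stretch) and calls
#' [analyze_partition()] with the scene's own centerline.
#'
#' @param scene result of [generate_scene()].
#' @param config a [filter_config()].
#' @param min_ratio eccentricity gate threshold.
#' @param subregion,case_id,slide_id metadata attached to the records.
#' @return see [analyze_partition()].
#' @export
analyze_scene <- function(scene, config = filter_config(), min_ratio = 1.05,
                          subregion = "CA1", case_id = "sim",
                          slide_id = "sim") {
  img <- prepare_image(scene$image, pixel_size = scene$spec$pixel_size,
                       id = "synthetic")
  analyze_partition(img, scene$mask, scene$centerline,
                    subregion = subregion, case_id = case_id,
                    slide_id = slide_id, config = config,
                    min_ratio = min_ratio)
}
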