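#' Measure all labeled objects in a partition
#'
#' One record per positive label: pixel count, calibrated area, equivalent
#' circle diameter, centroid (0-based pixel coordinates, pixel-mean of the
#' object's pixels) and mean grey value on the prepared (inverted) image,
#' where neurons are bright.
#'
#' @param mask label mask matrix.
#' @param image a [section_image()] (or grey matrix) of identical dimensions.
#' @param pixel_size micrometres per pixel; taken from the image when it is
#'   a `section_image`.
#' @return data.frame with columns `label`, `pixel_count`, `area_um2`,
#'   `diameter_um`, `x`, `y`, `mean_grey`.
#' @export
measure_segments <- function(mask, image, pixel_size = NULL) {
  px <- image_pixels(image)
  if (!all(dim(px) == dim(mask)))
    stop("mask and image dimensions differ")
  if (is.null(pixel_size)) pixel_size <- image_pixel_size(image)
  idx <- which(mask > 0L)
  if (!length(idx))
    return(data.frame(label = integer(), pixel_count = integer(),
                      area_um2 = numeric(), diameter_um = numeric(),
                      x = numeric(), y = numeric(), mean_grey = numeric()))
  lab <- mask[idx]
  yy <- (idx - 1L) %% nrow(mask)     # 0-based row (y)
  xx <- (idx - 1L) %/% nrow(mask)    # 0-based col (x)
  g <- px[idx]
  n <- tapply(lab, lab, length)
  out <- data.frame(
    label = as.integer(names(n)),
    pixel_count = as.integer(n),
    x = as.numeric(tapply(xx, lab, mean)),
    y = as.numeric(tapply(yy, lab, mean)),
    mean_grey = as.numeric(tapply(g, lab, mean))
  )
  out$area_um2 <- out$pixel_count * pixel_size^2
  out$diameter_um <- 2 * sqrt(out$area_um2 / pi)
  rownames(out) <- NULL
  out[, c("label", "pixel_count", "area_um2", "diameter_um", "x", "y", "mean_grey")]
}

#' Grey-value threshold separating extracellular space from somata
#'
#' Midpoint of the mean grey value over all segmented pixels and the mean
#' grey value over all background pixels of the partition, computed on the
#' prepared (inverted) image where somata are bright and the (lighter in the
#' stain, hence darker after inversion) extracellular space is dim. Objects
#' whose mean grey falls strictly below the threshold are flagged
#' extracellular by [apply_filters()].
#'
#' @param image prepared [section_image()] or grey matrix.
#' @param mask label mask matrix of identical dimensions.
#' @return the threshold grey value (scalar).
#' @export
grey_threshold <- function(image, mask) {
  px <- image_pixels(image)
  stopifnot(all(dim(px) == dim(mask)))
  fg <- mask > 0L
  if (!any(fg)) stop("no segmented pixels")
  if (all(fg)) stop("no background pixels: partition fully covered by objects")
  (mean(px[fg]) + mean(px[!fg])) / 2
}

#' Filter configuration
#'
#' SD multipliers for the size rules and the grey rule mode. Defaults follow
#' the published thresholds: lower cutoff at mean diameter minus 0.75 SD,
#' upper cutoffs at mean diameter plus 1.75 SD and mean area plus 1.75 SD.
#' "Diameter" is operationalized as the equivalent-circle diameter from the
#' object's area (set `diameter = "ellipse_minor"` to use the fitted-ellipse
#' minor axis instead, if ellipse columns are present).
#'
#' @param lower_diam_sd,upper_diam_sd,upper_area_sd non-negative SD
#'   multipliers.
#' @param grey_rule `"auto_midpoint"` (threshold from [grey_threshold()]),
#'   `"off"`, or a fixed numeric threshold.
#' @param diameter which diameter definition the size rules use.
#' @return a `filter_config` list.
#' @export
filter_config <- function(lower_diam_sd = 0.75, upper_diam_sd = 1.75,
                          upper_area_sd = 1.75, grey_rule = "auto_midpoint",
                          diameter = c("equivalent", "ellipse_minor")) {
  stopifnot(lower_diam_sd >= 0, upper_diam_sd >= 0, upper_area_sd >= 0)
  diameter <- match.arg(diameter)
  if (!(identical(grey_rule, "auto_midpoint") || identical(grey_rule, "off") ||
        (is.numeric(grey_rule) && length(grey_rule) == 1L)))
    stop("grey_rule must be 'auto_midpoint', 'off', or a numeric threshold")
  structure(list(lower_diam_sd = lower_diam_sd, upper_diam_sd = upper_diam_sd,
                 upper_area_sd = upper_area_sd, grey_rule = grey_rule,
                 diameter = diameter),
            class = "filter_config")
}

#' Remove the four classes of false-positive segmentations
#'
#' Rules are applied in a fixed order with first-hit reason attribution:
#' (1) `extracellular` — mean grey strictly below the grey threshold;
#' (2) per-partition size statistics (mean, SD of diameter and area) are
#' computed over the survivors of rule 1, so faint speckle cannot corrupt
#' them; (3) `too_small` — diameter strictly below mean − `lower_diam_sd`·SD
#' (glia, partial neuron profiles); (4) `too_large_diameter` — diameter
#' strictly above mean + `upper_diam_sd`·SD; (5) `too_large_area` — area
#' strictly above mean + `upper_area_sd`·SD (merged/overlapping neurons).
#' Objects sitting exactly on a cutoff are kept. With fewer than two
#' survivors of rule 1 the SDs are undefined and the size rules are skipped
#' with a warning.
#'
#' @param segments data.frame from [measure_segments()].
#' @param config a [filter_config()].
#' @param threshold grey threshold from [grey_threshold()]; required when
#'   `config$grey_rule == "auto_midpoint"`.
#' @return a `filter_result` list: `kept` and `excluded` data.frames (the
#'   latter with a `reason` column), and `thresholds_used` recording every
#'   numeric cutoff applied.
#' @export
apply_filters <- function(segments, config = filter_config(), threshold = NULL) {
  if (!nrow(segments)) stop("no segments to filter")
  diam <- if (config$diameter == "ellipse_minor") {
    if (is.null(segments$minor_um)) stop("diameter = 'ellipse_minor' needs a minor_um column")
    segments$minor_um
  } else segments$diameter_um

  reason <- rep(NA_character_, nrow(segments))

  grey_cut <- NA_real_
  if (!identical(config$grey_rule, "off")) {
    grey_cut <- if (is.numeric(config$grey_rule)) config$grey_rule else threshold
    if (is.null(grey_cut) || is.na(grey_cut))
      stop("grey_rule = 'auto_midpoint' requires a threshold (see grey_threshold())")
    reason[segments$mean_grey < grey_cut] <- "extracellular"
  }

  surv <- is.na(reason)
  th <- list(grey = grey_cut, diam_mean = NA_real_, diam_sd = NA_real_,
             diam_lower = NA_real_, diam_upper = NA_real_,
             area_mean = NA_real_, area_sd = NA_real_, area_upper = NA_real_)
  if (sum(surv) < 2L) {
    warning("fewer than 2 objects survive the grey rule; size rules skipped (SD undefined)")
  } else {
    dm <- mean(diam[surv]); ds <- stats::sd(diam[surv])
    am <- mean(segments$area_um2[surv]); as_ <- stats::sd(segments$area_um2[surv])
    th$diam_mean <- dm; th$diam_sd <- ds
    th$diam_lower <- dm - config$lower_diam_sd * ds
    th$diam_upper <- dm + config$upper_diam_sd * ds
    th$area_mean <- am; th$area_sd <- as_
    th$area_upper <- am + config$upper_area_sd * as_
    reason[surv & diam < th$diam_lower] <- "too_small"
    surv <- is.na(reason)
    reason[surv & diam > th$diam_upper] <- "too_large_diameter"
    surv <- is.na(reason)
    reason[surv & segments$area_um2 > th$area_upper] <- "too_large_area"
  }

  keep <- is.na(reason)
  excluded <- segments[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  res <- list(kept = segments[keep, , drop = FALSE],
              excluded = excluded,
              thresholds_used = th,
              config = config)
  class(res) <- "filter_result"
  res
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result: %d kept, %d excluded>\n",
              nrow(x$kept), nrow(x$excluded)))
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}

#' Write a filter result as a per-neuron table plus threshold sidecar
#'
#' @param result a `filter_result` from [apply_filters()].
#' @param path output CSV path; thresholds go to `<path>.thresholds.json`.
#' @export
write_filter_result <- function(result, path) {
  kept <- result$kept; kept$status <- "kept"; kept$reason <- NA_character_
  exc <- result$excluded; exc$status <- "excluded"
  tab <- rbind(kept[, union(names(kept), names(exc))],
               exc[, union(names(kept), names(exc))])
  tab <- tab[order(tab$label), ]
  utils::write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(result$thresholds_used, paste0(path, ".thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
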