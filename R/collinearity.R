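#' Mean angular deviation from perpendicularity
#'
#' Mean axial distance of corrected orientations from the 90-degree
#' reference of perfect orthogonality to the layer, in degrees `[0, 90]`.
#' Low values mean high collinearity.
#'
#' @param coos corrected orientations in degrees (axial; any representation
#'   modulo 180 is accepted).
#' @param reference `"perpendicular"` (default) anchors the deviation to the
#'   fixed 90-degree axis of perfect orthogonality; `"sample_mean"` uses the
#'   axial circular mean of the data instead (the dispersion reading).
#' @param na.rm drop `NA` values first.
#' @return `dev` in degrees.
#' @export
mean_angular_deviation <- function(coos, reference = c("perpendicular",
                                                       "sample_mean"),
                                   na.rm = FALSE) {
  reference <- match.arg(reference)
  if (na.rm) coos <- coos[!is.na(coos)]
  if (!length(coos)) stop("empty input: dev undefined")
  ref <- if (reference == "perpendicular") 90 else axial_circular_mean(coos)
  mean(axial_distance(coos, ref))
}

#' Axial circular mean of orientations
#'
#' Mean direction of the angle-doubled data, halved back to `[0, 180)`.
#'
#' @param coos orientations in degrees.
#' @return mean orientation in degrees `[0, 180)`.
#' @export
axial_circular_mean <- function(coos) {
  th <- deg2rad(2 * coos)
  fold_axial(rad2deg(atan2(mean(sin(th)), mean(cos(th)))) / 2)
}

#' Circular variance of axial orientations
#'
#' Axial data are angle-doubled (`theta = 2 * coo` in radians) before the
#' standard circular variance `1 - Rbar`, with `Rbar` the mean resultant
#' length of the unit vectors at `theta`. 0 means all orientations
#' identical; 1 means axially uniform. Doubling is the standard treatment
#' for period-180 orientation data; `axial = FALSE` computes the variance
#' on the raw angles for strict replication of directional conventions.
#'
#' @param coos orientations in degrees.
#' @param axial double the angles first (default TRUE).
#' @param na.rm drop `NA` values first.
#' @return variance in `[0, 1]`.
#' @examples
#' circular_variance(c(0, 45, 90, 135))  # 1: perfect axial uniformity
#' @export
circular_variance <- function(coos, axial = TRUE, na.rm = FALSE) {
  if (na.rm) coos <- coos[!is.na(coos)]
  if (!length(coos)) stop("empty input: variance undefined")
  theta <- deg2rad(if (axial) 2 * coos else coos)
  1 - sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

#' Rose-histogram bin counts over [0, 180)
#'
#' Half-open bins `[lo, lo + width)`; counts sum to the number of
#' observations.
#'
#' @param coos orientations in degrees (folded into `[0, 180)` first).
#' @param bin_width bin width in degrees; must divide 180.
#' @return data.frame with `lo`, `hi`, `count`.
#' @export
rose_histogram <- function(coos, bin_width = 10) {
  if (bin_width <= 0 || 180 %% bin_width != 0)
    stop("bin_width must be a positive divisor of 180")
  nb <- as.integer(180 / bin_width)
  lo <- (seq_len(nb) - 1L) * bin_width
  counts <- integer(nb)
  if (length(coos)) {
    b <- floor(fold_axial(coos) / bin_width) + 1L
    tab <- tabulate(b, nbins = nb)
    counts <- tab
  }
  data.frame(lo = lo, hi = lo + bin_width, count = counts)
}

#' Rose plot of axial orientations
#'
#' Draws the half-rose of a [rose_histogram()] on the upper semicircle,
#' mirrored to the lower one (axial data), using base graphics.
#'
#' @param coos orientations in degrees.
#' @param bin_width bin width in degrees.
#' @param col fill colour.
#' @param main plot title.
#' @export
plot_rose <- function(coos, bin_width = 10, col = "steelblue", main = "") {
  h <- rose_histogram(coos, bin_width)
  r <- sqrt(h$count / max(1, max(h$count)))       # area-true radii
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  for (i in seq_len(nrow(h))) {
    if (h$count[i] == 0) next
    for (off in c(0, 180)) {
      a <- deg2rad(seq(h$lo[i], h$hi[i], length.out = 16) + off)
      graphics::polygon(c(0, r[i] * cos(a)), c(0, r[i] * sin(a)),
                        col = col, border = "white")
    }
  }
  a <- deg2rad(seq(0, 360, length.out = 181))
  graphics::lines(cos(a), sin(a), col = "grey60")
  invisible(h)
}

#' Plot grid-sampled orientation line segments
#'
#' Draws the segments from [orientation_line_plot_data()] in image
#' coordinates (y axis flipped so the plot matches the section).
#'
#' @param segments data.frame from [orientation_line_plot_data()].
#' @param col segment colour.
#' @param main plot title.
#' @export
plot_orientation_lines <- function(segments, col = "purple", main = "") {
  xr <- range(c(segments$x0, segments$x1))
  yr <- range(c(segments$y0, segments$y1))
  graphics::plot(NA, xlim = xr, ylim = rev(yr), asp = 1,
                 xlab = "x (px)", ylab = "y (px)", main = main)
  graphics::segments(segments$x0, segments$y0, segments$x1, segments$y1,
                     col = col, lwd = 2)
  invisible(segments)
}

#' Per-group collinearity summary
#'
#' Aggregates orientation records into the two collinearity measures per
#' group: `n`, mean angular deviation `dev` and axial circular variance
#' `var`. Records with `NA` corrected orientation (degenerate or gated-out
#' fits) are dropped from the statistics but reported in `n_total`.
#'
#' @param records data.frame with a `coo_deg` column (see
#'   [correct_orientations()]).
#' @param by character vector of grouping columns (default
#'   `"subregion"`).
#' @param axial passed to [circular_variance()].
#' @return data.frame with the grouping columns, `n`, `n_total`, `dev`,
#'   `var`.
#' @export
summarize_collinearity <- function(records, by = "subregion", axial = TRUE) {
  stopifnot(all(by %in% names(records)))
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    ok <- !is.na(g$coo_deg)
    s <- g[1, by, drop = FALSE]
    s$n <- sum(ok)
    s$n_total <- nrow(g)
    s$dev <- if (any(ok)) mean_angular_deviation(g$coo_deg[ok]) else NA_real_
    s$var <- if (any(ok)) circular_variance(g$coo_deg[ok], axial = axial) else NA_real_
    s
  }))
  rownames(out) <- NULL
  out
}

#' Pooled subregion summary with both weighting conventions
#'
#' Subregion-level `dev` can pool neurons directly (neuron-weighted) or
#' average the per-partition `dev` values (partition-weighted); both are
#' reported.
#'
#' @param records orientation records with `subregion` and a partition
#'   identifier column.
#' @param partition_col name of the partition identifier column.
#' @return data.frame with `subregion`, `n`, `n_partitions`,
#'   `dev_neuron_weighted`, `dev_partition_weighted`, `var`.
#' @export
pooled_subregion_summary <- function(records, partition_col = "partition") {
  per_part <- summarize_collinearity(records, by = c("subregion", partition_col))
  pooled <- summarize_collinearity(records, by = "subregion")
  pw <- tapply(per_part$dev, per_part$subregion, mean, na.rm = TRUE)
  np <- tapply(per_part$dev, per_part$subregion, length)
  data.frame(subregion = pooled$subregion,
             n = pooled$n,
             n_partitions = as.integer(np[as.character(pooled$subregion)]),
             dev_neuron_weighted = pooled$dev,
             dev_partition_weighted = as.numeric(pw[as.character(pooled$subregion)]),
             var = pooled$var)
}

#' Grid-sampled orientation line segments for display
#'
#' Reproduces the orientation-line plots: the partition is covered by a
#' square grid (default 220 micrometres), one neuron per occupied grid
#' square is sampled uniformly, and a fixed-length display segment centered
#' at its centroid along the chosen angle is returned.
#'
#' @param records data.frame with `x`, `y` (pixels) and angle columns.
#' @param pixel_size micrometres per pixel.
#' @param grid_size grid square edge, micrometres (default 220).
#' @param angle which angle column to draw: `"coo_deg"` or `"unco_deg"`.
#' @param length_um display length of each segment, micrometres.
#' @param seed optional RNG seed for reproducible sampling.
#' @return data.frame with one row per occupied grid square: `gx`, `gy`
#'   (grid indices), sampled `label`, `x0`, `y0`, `x1`, `y1` segment
#'   endpoints in pixel coordinates (screen convention, y down).
#' @export
orientation_line_plot_data <- function(records, pixel_size = 1,
                                       grid_size = 220,
                                       angle = c("coo_deg", "unco_deg"),
                                       length_um = 40, seed = NULL) {
  angle <- match.arg(angle)
  rec <- records[!is.na(records[[angle]]), , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(gx = integer(), gy = integer(), label = integer(),
                      x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric()))
  if (!is.null(seed)) set.seed(seed)
  step <- grid_size / pixel_size
  gx <- floor(rec$x / step)
  gy <- floor(rec$y / step)
  key <- paste(gx, gy)
  pick <- vapply(split(seq_len(nrow(rec)), key), function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1))
  sel <- rec[pick, , drop = FALSE]
  half <- length_um / pixel_size / 2
  a <- deg2rad(sel[[angle]])
  dx <- half * cos(a)
  dy <- -half * sin(a)                 # back to screen coordinates (y down)
  data.frame(gx = gx[pick], gy = gy[pick], label = sel$label,
             x0 = sel$x - dx, y0 = sel$y - dy,
             x1 = sel$x + dx, y1 = sel$y + dy)
}
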