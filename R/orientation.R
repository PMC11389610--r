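#' Moment-matched ellipse fit of a pixel set
#'
#' Fits the ellipse with the same centroid and second central moments as the
#' object's pixels, each pixel treated as a unit square (which contributes
#' 1/12 to each diagonal moment, so even one-pixel-wide objects get a
#' positive minor axis). The uncorrected orientation `unco` is the axial
#' angle of the major axis versus the x-axis in `[0, 180)`, in the
#' mathematical convention (counter-clockwise, y up — the row axis is
#' sign-flipped). This is the "fit ellipse" convention of common image
#' tools, robust for filled blobs.
#'
#' @param x,y 0-based pixel coordinates of the object's pixels (equal
#'   length, >= 3 pixels for a defined orientation).
#' @param pixel_size micrometres per pixel (scales `major`/`minor` only).
#' @return list with `cx`, `cy` (pixels), `major`, `minor` (full axis
#'   lengths, micrometres), `unco` (degrees in `[0, 180)`), and `valid`
#'   (FALSE when the orientation is undefined: < 3 pixels). Invalid fits
#'   carry `unco = NA` and must be excluded from orientation statistics,
#'   never silently assigned.
#' @examples
#' f <- fit_ellipse(x = 0:20, y = rep(0, 21))  # horizontal bar
#' f$unco  # 0
#' @export
fit_ellipse <- function(x, y, pixel_size = 1) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L)
    return(list(cx = mean(x), cy = mean(y), major = NA_real_,
                minor = NA_real_, unco = NA_real_, valid = FALSE))
  cx <- mean(x); cy <- mean(y)
  u <- x - cx
  v <- -(y - cy)                       # y-up for math-convention angles
  mxx <- mean(u * u) + 1 / 12
  myy <- mean(v * v) + 1 / 12
  mxy <- mean(u * v)
  tr <- (mxx + myy) / 2
  d <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr + d; l2 <- max(tr - d, 0)
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  list(cx = cx, cy = cy,
       major = 4 * sqrt(l1) * pixel_size,
       minor = 4 * sqrt(l2) * pixel_size,
       unco = fold_axial(rad2deg(theta)),
       valid = TRUE)
}

#' Is a fitted ellipse elongated enough for its angle to be meaningful?
#'
#' Near-circular objects have an unstable major-axis direction; their
#' records are excluded from orientation analyses but retained in counts.
#'
#' @param fit list with `major` and `minor` (as from [fit_ellipse()]), or a
#'   data.frame with `major_um`/`minor_um` columns.
#' @param min_ratio minimal major/minor axis ratio (default 1.05).
#' @return logical vector: TRUE iff major/minor >= min_ratio.
#' @export
eccentricity_gate <- function(fit, min_ratio = 1.05) {
  if (is.data.frame(fit)) {
    fit$major_um / fit$minor_um >= min_ratio & !is.na(fit$major_um)
  } else {
    isTRUE(fit$valid) && fit$major / fit$minor >= min_ratio
  }
}

#' Fit ellipses to every object of a label mask
#'
#' Appends `major_um`, `minor_um`, `unco_deg` and `ecc_ok` columns to a
#' segment table.
#'
#' @param segments data.frame from [measure_segments()].
#' @param mask the label mask the segments were measured on.
#' @param pixel_size micrometres per pixel.
#' @param min_ratio eccentricity gate threshold (see [eccentricity_gate()]).
#' @return `segments` with ellipse columns appended; `unco_deg` is `NA` for
#'   degenerate objects (< 3 pixels), with `ecc_ok = FALSE`.
#' @export
fit_segment_ellipses <- function(segments, mask, pixel_size = 1,
                                 min_ratio = 1.05) {
  idx <- which(mask > 0L)
  lab <- mask[idx]
  yy <- (idx - 1L) %% nrow(mask)
  xx <- (idx - 1L) %/% nrow(mask)
  segments$major_um <- NA_real_
  segments$minor_um <- NA_real_
  segments$unco_deg <- NA_real_
  by_lab_x <- split(xx, lab)
  by_lab_y <- split(yy, lab)
  keys <- as.integer(names(by_lab_x))
  m <- match(segments$label, keys)
  for (i in seq_len(nrow(segments))) {
    j <- m[i]
    if (is.na(j)) next
    f <- fit_ellipse(by_lab_x[[j]], by_lab_y[[j]], pixel_size)
    segments$major_um[i] <- f$major
    segments$minor_um[i] <- f$minor
    segments$unco_deg[i] <- f$unco
  }
  segments$ecc_ok <- !is.na(segments$unco_deg) &
    segments$major_um / segments$minor_um >= min_ratio
  segments
}
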