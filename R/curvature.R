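#' Pyramidal-layer centerline
#'
#' Ordered polyline tracing the middle of the pyramidal layer for one
#' partition, in 0-based pixel coordinates. Centerlines are drawn manually
#' in the canonical workflow and supplied as a 2-column table of vertices.
#'
#' @param vertices n x 2 matrix/data.frame of ordered (x, y) vertices,
#'   n >= 2, consecutive vertices distinct.
#' @param partition_ref optional partition identifier.
#' @return object of class `centerline`.
#' @export
centerline <- function(vertices, partition_ref = "") {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2L, nrow(v) >= 2L)
  dd <- rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)
  if (any(dd == 0)) stop("consecutive centerline vertices must be distinct")
  structure(list(vertices = unname(v), partition_ref = partition_ref),
            class = "centerline")
}

#' Read a centerline from a 2-column CSV or a JSON vertex list
#' @param path file path (.csv with x,y columns, or .json array of pairs).
#' @param partition_ref optional partition identifier.
#' @export
read_centerline <- function(path, partition_ref = "") {
  ext <- tolower(tools::file_ext(path))
  v <- if (ext == "json") {
    do.call(rbind, lapply(jsonlite::fromJSON(path, simplifyMatrix = FALSE), as.numeric))
  } else {
    as.matrix(utils::read.csv(path)[, 1:2])
  }
  centerline(v, partition_ref)
}

#' Draft a centerline from a neuron point cloud
#'
#' Proposes a polyline through the middle of a band of kept-neuron
#' centroids by projecting them onto their first principal axis, binning
#' along it and connecting the bin means. This is a drafting aid only:
#' canonical centerlines are drawn manually, and this helper fails badly
#' on strongly re-entrant (hook-shaped) layers where arc position is not
#' monotone along any straight axis.
#'
#' @param segments data.frame with `x`, `y` centroid columns.
#' @param n_vertices number of polyline vertices to propose.
#' @return a [centerline()] flagged with attribute `draft = TRUE`.
#' @export
draft_centerline <- function(segments, n_vertices = 20) {
  p <- cbind(segments$x, segments$y)
  if (nrow(p) < n_vertices * 2) stop("too few centroids to draft a centerline")
  pc <- stats::prcomp(p)
  t <- pc$x[, 1]
  br <- stats::quantile(t, seq(0, 1, length.out = n_vertices + 1))
  bin <- cut(t, unique(br), include.lowest = TRUE)
  v <- cbind(tapply(p[, 1], bin, mean), tapply(p[, 2], bin, mean))
  v <- v[stats::complete.cases(v), , drop = FALSE]
  out <- centerline(v)
  attr(out, "draft") <- TRUE
  out
}

#' Nearest point on a polyline
#'
#' Orthogonal projection of `p` onto every segment (clamped to segment
#' ends), returning the globally closest point; ties are broken by the
#' lowest segment index, so the result is deterministic.
#'
#' @param p length-2 numeric (x, y).
#' @param line a [centerline()] (or n x 2 vertex matrix).
#' @return list with `q` (closest point), `distance`, `segment` (1-based
#'   index of the winning segment) and `t` (position along it in `[0, 1]`).
#' @export
nearest_point_on_polyline <- function(p, line) {
  v <- if (inherits(line, "centerline")) line$vertices else as.matrix(line)
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  t <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) / len2
  t <- pmin(pmax(t, 0), 1)
  qx <- a[, 1] + t * ab[, 1]
  qy <- a[, 2] + t * ab[, 2]
  d2 <- (p[1] - qx)^2 + (p[2] - qy)^2
  i <- which.min(d2)                   # first minimum = lowest segment index
  list(q = c(qx[i], qy[i]), distance = sqrt(d2[i]), segment = i, t = t[i])
}

#' Correction angle of a neuron relative to the layer centerline
#'
#' Direction of the vector from the neuron centroid to the closest point on
#' the centerline, versus the +x axis in the mathematical convention
#' (counter-clockwise, y up), in `[0, 360)` degrees.
#'
#' @param centroid length-2 (x, y) pixel coordinates.
#' @param q closest point on the centerline.
#' @return `corra` in degrees `[0, 360)`.
#' @export
correction_angle <- function(centroid, q) {
  dx <- q[1] - centroid[1]
  dy <- q[2] - centroid[2]
  if (dx == 0 && dy == 0)
    stop("centroid coincides with its nearest centerline point; ",
         "use the local centerline normal instead (see correct_orientations)")
  vector_angle_deg(dx, dy)
}

#' Curvature-corrected orientation
#'
#' `coo = (corra - unco + 90) mod 180`: the uncorrected axial orientation is
#' re-expressed relative to the local layer normal, so a neuron whose major
#' axis points along its centroid-to-centerline direction gets `coo = 90`
#' (perfectly perpendicular to the layer) regardless of where on the curve
#' it sits or on which side of the centerline it lies.
#'
#' @param unco axial orientation in degrees `[0, 180)` (vectorized).
#' @param corra correction angle in degrees `[0, 360)` (vectorized).
#' @return `coo` in degrees `[0, 180)`.
#' @examples
#' corrected_orientation(unco = 45, corra = 120)  # 165
#' corrected_orientation(unco = 130, corra = 10)  # 150 (wrap)
#' @export
corrected_orientation <- function(unco, corra) {
  (corra - unco + 90) %% 180
}

local_normal_angle <- function(line, segment) {
  v <- if (inherits(line, "centerline")) line$vertices else as.matrix(line)
  a <- v[segment, ]; b <- v[segment + 1L, ]
  (vector_angle_deg(b[1] - a[1], b[2] - a[2]) + 90) %% 360
}

#' Correct a table of neuron orientations for layer curvature
#'
#' For each record with a valid, sufficiently elongated ellipse fit, finds
#' the nearest centerline point, computes the correction angle `corra`, the
#' corrected orientation `coo`, and the angular deviation from
#' perpendicularity `dev_i = axial distance of coo from 90` (degrees,
#' `[0, 90]`). Neurons centered exactly on the centerline use the local
#' centerline normal as `corra` and are flagged (`on_centerline`).
#'
#' @param segments data.frame with `x`, `y`, `unco_deg`, `ecc_ok` columns
#'   (see [fit_segment_ellipses()]).
#' @param line a [centerline()].
#' @param subregion,case_id,slide_id partition metadata attached to every
#'   record.
#' @return data.frame of orientation records: the input columns plus
#'   `corra_deg`, `coo_deg`, `dev_i`, `dist_to_line`, `on_centerline`, and
#'   the metadata columns. Rows with `ecc_ok = FALSE` or undefined `unco`
#'   keep `NA` in the derived columns.
#' @export
correct_orientations <- function(segments, line, subregion = NA_character_,
                                 case_id = NA_character_,
                                 slide_id = NA_character_) {
  n <- nrow(segments)
  corra <- coo <- devi <- dist <- rep(NA_real_, n)
  onln <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (is.na(segments$unco_deg[i]) || !isTRUE(segments$ecc_ok[i])) next
    p <- c(segments$x[i], segments$y[i])
    np <- nearest_point_on_polyline(p, line)
    dist[i] <- np$distance
    if (np$distance == 0) {
      corra[i] <- local_normal_angle(line, np$segment)
      onln[i] <- TRUE
    } else {
      corra[i] <- correction_angle(p, np$q)
    }
    coo[i] <- corrected_orientation(segments$unco_deg[i], corra[i])
    devi[i] <- axial_distance(coo[i], 90)
  }
  segments$corra_deg <- corra
  segments$coo_deg <- coo
  segments$dev_i <- devi
  segments$dist_to_line <- dist
  segments$on_centerline <- onln
  segments$subregion <- subregion
  segments$case_id <- case_id
  segments$slide_id <- slide_id
  segments
}
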