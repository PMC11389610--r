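#' Section image container
#'
#' A prepared histology section: single-channel 8-bit scale (values in
#' `[0, 255]`, stored numeric), inverted so that dark Nissl somata are bright,
#' with its pixel calibration. Pixel coordinates used throughout the package
#' are 0-based, `x` = column rightward, `y` = row downward; all angles are
#' reported in the mathematical convention (counter-clockwise from +x with y
#' pointing up), i.e. the row axis is sign-flipped before any angle
#' computation.
#'
#' @param pixels numeric matrix (rows = y, cols = x), values in `[0, 255]`.
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @param id case/slide identifier string.
#' @return an object of class `section_image`.
#' @export
section_image <- function(pixels, pixel_size = 1, id = "") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (length(pixels) == 0L) stop("empty image")
  if (anyNA(pixels) || any(!is.finite(pixels))) stop("image contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 255) stop("pixel values must lie in [0, 255]")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single value > 0 (micrometres per pixel)")
  structure(list(pixels = pixels, pixel_size = pixel_size, id = id),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image '%s': %d x %d px, %.4g um/px, grey range [%.1f, %.1f]>\n",
              x$id, ncol(x$pixels), nrow(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

image_pixels <- function(image) {
  if (inherits(image, "section_image")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected a section_image or a numeric matrix")
}

image_pixel_size <- function(image, default = 1) {
  if (inherits(image, "section_image")) image$pixel_size else default
}

#' Prepare a raw section image for segmentation post-processing
#'
#' Converts a colour or grey image to single-channel 8-bit scale, inverts it
#' (dark Nissl-stained somata become bright), and applies a percentile
#' contrast stretch: the `saturation` quantile at each tail is mapped to
#' 0/255 and values are clipped. A constant image is inverted but not
#' stretched (with a warning), since a stretch is undefined there.
#'
#' @param raw numeric matrix (grey) or 3-d array (rows x cols x channels).
#'   Values either on the unit scale `[0, 1]` (as returned by
#'   [tiff::readTIFF()] / [png::readPNG()]) or already on `[0, 255]`.
#' @param pixel_size micrometres per pixel.
#' @param id identifier carried through to the result.
#' @param saturation fraction of pixels saturated at each tail of the
#'   contrast stretch (default 0.0035, i.e. 0.35 %).
#' @param weights RGB luminance weights used when `raw` has 3+ channels.
#' @param invert logical; invert grey values (default TRUE).
#' @return a [section_image()].
#' @examples
#' ramp <- matrix(rep(0:255, 2), nrow = 2, byrow = TRUE)
#' img <- prepare_image(ramp, pixel_size = 1, saturation = 0)
#' range(img$pixels)  # inverted ramp, 0..255
#' @export
prepare_image <- function(raw, pixel_size = 1, id = "",
                          saturation = 0.0035,
                          weights = c(0.2126, 0.7152, 0.0722),
                          invert = TRUE) {
  if (length(raw) == 0L) stop("empty image")
  if (anyNA(raw) || any(!is.finite(raw))) stop("image contains non-finite values")
  if (is.array(raw) && length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    if (nc >= 3L) {
      w <- weights / sum(weights)
      g <- raw[, , 1] * w[1] + raw[, , 2] * w[2] + raw[, , 3] * w[3]
    } else {
      g <- raw[, , 1]
    }
  } else if (is.matrix(raw)) {
    g <- raw
  } else stop("raw must be a matrix or a rows x cols x channels array")
  g <- g * 1.0
  if (max(g) <= 1 && min(g) >= 0) g <- g * 255      # unit-scale input
  g <- pmin(pmax(g, 0), 255)
  if (invert) g <- 255 - g
  lo <- stats::quantile(g, saturation, names = FALSE)
  hi <- stats::quantile(g, 1 - saturation, names = FALSE)
  if (hi > lo) {
    g <- (g - lo) / (hi - lo) * 255
    g <- pmin(pmax(g, 0), 255)
  } else {
    warning("constant image: contrast stretch skipped")
  }
  section_image(g, pixel_size = pixel_size, id = id)
}

#' Read a TIFF or PNG image from disk
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @return numeric matrix or array on the scale stored in the file.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else if (ext == "png") png::readPNG(path)
  else stop("unsupported image format: .", ext)
}

#' Write a prepared section image (or crop) as an 8-bit TIFF
#'
#' @param image a [section_image()].
#' @param path output TIFF path.
#' @export
write_section_image <- function(image, path) {
  tiff::writeTIFF(image_pixels(image) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Partition region of interest
#'
#' A closed polygon delimiting one subregion partition on a section, with
#' its metadata. Vertices are 0-based pixel coordinates (x, y).
#'
#' @param vertices n x 2 numeric matrix of (x, y) polygon vertices; the
#'   polygon is closed implicitly (last vertex joins the first).
#' @param subregion subregion label, one of [subregion_levels].
#' @param case_id,slide_id case and anterior-posterior level identifiers.
#' @return an object of class `partition_roi`.
#' @export
partition_roi <- function(vertices, subregion, case_id, slide_id) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  if (!subregion %in% subregion_levels)
    stop("unknown subregion '", subregion, "'; expected one of: ",
         paste(subregion_levels, collapse = ", "))
  a <- polygon_area(vertices)
  if (a <= 0) stop("polygon has zero area")
  structure(list(vertices = vertices, subregion = subregion,
                 case_id = as.character(case_id),
                 slide_id = as.character(slide_id)),
            class = "partition_roi")
}

#' Closed vocabulary of subregion labels
#' @export
subregion_levels <- c("CA1", "CA2", "CA3", "CA3prox", "CA3dist", "Sub",
                      "CA1u", "CA2u", "CA3u", "Subu")

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

points_in_polygon <- function(pts, vertices) {
  ## mgcv::in.out wants a closed loop (repeat first vertex)
  bnd <- rbind(vertices, vertices[1, , drop = FALSE])
  mgcv::in.out(bnd, as.matrix(pts))
}

#' Read partition ROIs from a JSON manifest
#'
#' Expects a JSON array of objects with fields `subregion`, `case_id`,
#' `slide_id` and `vertices` (list of `[x, y]` pairs, 0-based pixel
#' coordinates); an optional `centerline` field per entry gives the path of
#' that partition's centerline file.
#'
#' @param path JSON file path.
#' @return list of [partition_roi()] objects; any `centerline` path is
#'   attached as attribute `"centerline"`.
#' @export
read_partition_rois <- function(path) {
  entries <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(entries, function(e) {
    v <- if (is.matrix(e$vertices)) e$vertices
         else do.call(rbind, lapply(e$vertices, as.numeric))
    roi <- partition_roi(v, e$subregion, e$case_id, e$slide_id)
    if (!is.null(e$centerline)) attr(roi, "centerline") <- e$centerline
    roi
  })
}

#' Crop a partition out of a section image and its label mask
#'
#' Crops both image and mask to the polygon's bounding box (intersected with
#' the image bounds). An object is kept iff its centroid lies inside the
#' polygon, so each neuron is attributed to exactly one partition; labels
#' with centroid outside are zeroed entirely, while kept labels retain all
#' their pixels within the crop (boundary-straddling cells are not
#' truncated, which would bias their moments). Mask pixels outside the
#' polygon that belong to no kept object are background.
#'
#' @param image a [section_image()] (or plain matrix).
#' @param mask integer label matrix, same dimensions as the image.
#' @param roi a [partition_roi()].
#' @return list with `image` (cropped [section_image()]), `mask` (cropped
#'   label matrix), `offset` = c(x0, y0) of the crop origin in 0-based
#'   section coordinates, and `roi`.
#' @export
extract_partition <- function(image, mask, roi) {
  px <- image_pixels(image)
  stopifnot(all(dim(px) == dim(mask)))
  v <- roi$vertices
  W <- ncol(px); H <- nrow(px)
  x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(W - 1L, ceiling(max(v[, 1])))
  y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(H - 1L, ceiling(max(v[, 2])))
  if (x1 < x0 || y1 < y0) stop("ROI lies fully outside the image")
  rows <- (y0 + 1L):(y1 + 1L); cols <- (x0 + 1L):(x1 + 1L)
  img_c <- px[rows, cols, drop = FALSE]
  msk_c <- mask[rows, cols, drop = FALSE]

  labs <- sort(unique(msk_c[msk_c > 0]))
  if (length(labs)) {
    idx <- which(msk_c > 0)
    rr <- (idx - 1L) %% nrow(msk_c)        # 0-based y within crop
    cc <- (idx - 1L) %/% nrow(msk_c)       # 0-based x within crop
    lab <- msk_c[idx]
    cx <- tapply(cc, lab, mean) + x0
    cy <- tapply(rr, lab, mean) + y0
    inside <- points_in_polygon(cbind(cx, cy), v)
    drop_labs <- as.integer(names(cx))[!inside]
    if (length(drop_labs)) msk_c[msk_c %in% drop_labs] <- 0L
  }
  out_img <- section_image(img_c, pixel_size = image_pixel_size(image),
                           id = if (inherits(image, "section_image")) image$id else "")
  list(image = out_img, mask = msk_c, offset = c(x0, y0), roi = roi)
}
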