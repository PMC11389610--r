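#' Validate and normalize a label mask
#'
#' A label mask is an integer matrix where 0 is background and each positive
#' value indexes one segmented object. Labels are relabeled to consecutive
#' `1..K`, preserving the order of first appearance in raster scan order
#' (row by row, left to right), so per-object tables have stable join keys.
#'
#' @param mask integer matrix (0 = background).
#' @param provenance free-text tool/version string recorded as an attribute.
#' @return integer matrix with labels `0..K` and attributes `provenance`
#'   and `n_objects`.
#' @export
as_label_mask <- function(mask, provenance = "unknown") {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (is.double(mask)) {
    if (any(mask != round(mask)))
      stop("mask has float values; label masks must be integer ",
           "(re-export the mask as a 16/32-bit integer TIFF)")
    storage.mode(mask) <- "integer"
  }
  if (any(mask < 0)) stop("mask has negative labels")
  ## raster-order first appearance: transpose so row-major scan
  vals <- as.vector(t(mask))
  uniq <- unique(vals[vals > 0L])
  if (length(uniq)) {
    relab <- match(mask, uniq)          # NA for background
    relab[is.na(relab)] <- 0L
    mask <- matrix(as.integer(relab), nrow = nrow(mask))
  }
  attr(mask, "provenance") <- provenance
  attr(mask, "n_objects") <- length(uniq)
  mask
}

#' Number of objects in a label mask
#' @param mask a label mask matrix.
#' @export
n_objects <- function(mask) {
  k <- attr(mask, "n_objects")
  if (is.null(k)) length(unique(mask[mask > 0L])) else k
}

#' Load a label mask from an integer TIFF
#'
#' Reads a 16/32-bit integer TIFF produced by an external segmenter,
#' validates it, and relabels objects to consecutive integers. A JSON
#' sidecar `<path>.json` with a `provenance` field is honoured if present.
#'
#' @param path TIFF file path.
#' @return a validated label mask (see [as_label_mask()]).
#' @export
load_label_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (is.array(m) && length(dim(m)) == 3L) m <- m[, , 1]
  prov <- "file"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    if (!is.null(meta$provenance)) prov <- meta$provenance
  }
  as_label_mask(m, provenance = prov)
}

#' Write a label mask as a 16-bit TIFF (with provenance sidecar)
#'
#' @param mask label mask matrix.
#' @param path output TIFF path.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("more than 65535 labels; not representable in 16-bit")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  prov <- attr(mask, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(list(provenance = prov), paste0(path, ".json"),
                         auto_unbox = TRUE)
  invisible(path)
}

#' Invoke an external pretrained segmenter on a prepared image
#'
#' Runs a Cellpose-style command-line segmenter as a subprocess and loads
#' the resulting label mask. The package never re-implements the network;
#' when the tool is not on the PATH this function stops with a clear error,
#' and the pipeline is fully usable with precomputed masks via
#' [load_label_mask()] instead.
#'
#' @param image a [section_image()].
#' @param params named list of segmenter parameters; must include
#'   `diameter` (expected object diameter in pixels). Passed through as
#'   `--key value` flags, not interpreted here.
#' @param command segmenter executable name (default `"cellpose"`).
#' @return a validated label mask with provenance recording tool + params.
#' @export
run_external_segmenter <- function(image, params = list(), command = "cellpose") {
  if (is.null(params$diameter))
    stop("params must include the expected object 'diameter'")
  exe <- Sys.which(command)
  if (!nzchar(exe)) {
    stop("external segmenter '", command, "' not found on PATH. ",
         "Run the segmenter elsewhere and load its output with ",
         "load_label_mask(); all downstream steps depend only on the ",
         "label mask, not on the tool.")
  }
  dir <- tempfile("seg"); dir.create(dir)
  in_tif <- file.path(dir, "input.tif")
  tiff::writeTIFF(image_pixels(image) / 255, in_tif, bits.per.sample = 8L)
  flags <- unlist(lapply(names(params), function(k) c(paste0("--", k), as.character(params[[k]]))))
  status <- system2(exe, c("--image_path", in_tif, "--save_tif", flags))
  if (status != 0) stop("segmenter exited with status ", status)
  out <- list.files(dir, pattern = "masks", full.names = TRUE)
  if (!length(out)) stop("segmenter produced no mask file")
  m <- load_label_mask(out[1])
  attr(m, "provenance") <- paste0(command, " ", paste(flags, collapse = " "))
  m
}
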