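#' Radiograph objects
#'
#' A radiograph is a light list holding `image_id`, `patient_id`, a
#' numeric `pixels` matrix with intensities in \[0, 1\] (rows = image
#' rows), and an optional binary `mask` of identical shape marking the
#' region of interest (nonzero = ROI).
#'
#' @param pixels Numeric matrix in \[0, 1\].
#' @param image_id,patient_id Identifier strings.
#' @param mask Optional binary matrix, same shape as `pixels`.
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, image_id = "img", patient_id = "pat",
                       mask = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1) {
    abort("Pixel intensities must lie in [0, 1]; normalise first.")
  }
  if (!is.null(mask) && !identical(dim(mask), dim(pixels))) {
    abort("`mask` must have the same shape as `pixels`.")
  }
  structure(list(image_id = image_id, patient_id = patient_id,
                 pixels = pixels, mask = mask),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph %s> %d x %d px, patient %s, mask: %s\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$patient_id,
              if (is.null(x$mask)) "none" else "yes"))
  invisible(x)
}

#' Bounding boxes
#'
#' Boxes are 0-based and half-open on both axes: a box covers pixel rows
#' `row_start .. row_stop - 1` and columns `col_start .. col_stop - 1`.
#'
#' @param row_start,row_stop,col_start,col_stop Integer pixel indices.
#' @return An object of class `bbox` (named integer vector).
#' @export
bbox <- function(row_start, row_stop, col_start, col_stop) {
  b <- c(row_start = as.integer(row_start), row_stop = as.integer(row_stop),
         col_start = as.integer(col_start), col_stop = as.integer(col_stop))
  if (b["row_start"] < 0 || b["col_start"] < 0 ||
      b["row_stop"] <= b["row_start"] || b["col_stop"] <= b["col_start"]) {
    abort("Invalid bounding box: need 0 <= start < stop on both axes.")
  }
  structure(b, class = "bbox")
}

#' Tight bounding box of a binary mask
#'
#' Returns the smallest half-open box containing every nonzero mask
#' pixel.
#'
#' @param mask Binary (or numeric) matrix; nonzero marks the ROI.
#' @return A [bbox].
#' @export
#' @examples
#' m <- matrix(0, 10, 10); m[3:5, 4:8] <- 1
#' mask_to_bbox(m)  # rows [2, 5), cols [3, 8) in 0-based half-open form
mask_to_bbox <- function(mask) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  nz <- which(mask != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) abort("Empty ROI: mask has no nonzero pixel.")
  bbox(min(nz[, 1]) - 1L, max(nz[, 1]), min(nz[, 2]) - 1L, max(nz[, 2]))
}

#' Expand a bounding box by a fractional margin
#'
#' Each side moves outward by `round_half_up(margin * extent)` pixels,
#' where `extent` is the box's height (for the row sides) or width (for
#' the column sides); the result is clipped to the image. The default
#' 15% margin widens a tight tumour box so that all tumour tissue is
#' captured before cropping.
#'
#' @param box A [bbox].
#' @param margin Non-negative fraction of the box extent added per side.
#' @param image_shape Integer `c(n_rows, n_cols)` to clip against.
#' @return A [bbox] containing `box`.
#' @export
#' @examples
#' expand_bbox(bbox(10, 30, 10, 30), 0.15, c(100, 100))  # (7, 33, 7, 33)
expand_bbox <- function(box, margin = 0.15, image_shape) {
  stopifnot(inherits(box, "bbox"))
  if (margin < 0) abort("`margin` must be >= 0.")
  if (box["row_stop"] > image_shape[1] || box["col_stop"] > image_shape[2]) {
    abort("Box exceeds `image_shape`.")
  }
  dr <- round_half_up(margin * (box["row_stop"] - box["row_start"]))
  dc <- round_half_up(margin * (box["col_stop"] - box["col_start"]))
  bbox(max(0L, box["row_start"] - dr),
       min(image_shape[1], box["row_stop"] + dr),
       max(0L, box["col_start"] - dc),
       min(image_shape[2], box["col_stop"] + dc))
}

#' Crop a radiograph to a bounding box
#'
#' Pixel values are preserved bit-exactly; the mask, when present, is
#' cropped identically.
#'
#' @param image A [radiograph] (or bare matrix).
#' @param box A [bbox] lying inside the image.
#' @return A cropped [radiograph] (or matrix, matching the input type).
#' @export
crop_image <- function(image, box) {
  stopifnot(inherits(box, "bbox"))
  px <- if (inherits(image, "radiograph")) image$pixels else image
  if (box["row_stop"] > nrow(px) || box["col_stop"] > ncol(px)) {
    abort("Box lies outside the image.")
  }
  rows <- (box["row_start"] + 1L):box["row_stop"]
  cols <- (box["col_start"] + 1L):box["col_stop"]
  if (!inherits(image, "radiograph")) {
    return(px[rows, cols, drop = FALSE])
  }
  radiograph(px[rows, cols, drop = FALSE],
             image_id = image$image_id, patient_id = image$patient_id,
             mask = if (is.null(image$mask)) NULL else
               image$mask[rows, cols, drop = FALSE])
}

#' ROI pipeline: mask to margin-expanded crop
#'
#' Convenience composition of [mask_to_bbox()], [expand_bbox()] and
#' [crop_image()] on a radiograph that carries its own mask.
#'
#' @param image A [radiograph] with a non-empty mask.
#' @param margin Fractional per-side margin, default 0.15.
#' @return A cropped [radiograph].
#' @export
crop_to_roi <- function(image, margin = 0.15) {
  stopifnot(inherits(image, "radiograph"))
  if (is.null(image$mask)) abort("Radiograph has no mask.")
  box <- expand_bbox(mask_to_bbox(image$mask), margin, dim(image$pixels))
  crop_image(image, box)
}

#' Read a grayscale radiograph from PNG or TIFF
#'
#' Multi-channel images are collapsed to grayscale by channel averaging;
#' intensities are scaled into \[0, 1\].
#'
#' @param path Image file (`.png`, `.tif`, `.tiff`).
#' @param image_id,patient_id Identifiers; default the file name stem.
#' @param mask_path Optional mask image (nonzero = ROI).
#' @return A [radiograph].
#' @export
read_radiograph <- function(path, image_id = NULL, patient_id = "unknown",
                            mask_path = NULL) {
  read_px <- function(p) {
    ext <- tolower(tools::file_ext(p))
    arr <- switch(ext,
      png = png::readPNG(p),
      tif = ,
      tiff = tiff::readTIFF(p),
      abort(paste0("Unsupported image format: .", ext))
    )
    if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
    if (max(arr) > 1) arr <- arr / max(arr)
    arr
  }
  px <- read_px(path)
  mask <- if (!is.null(mask_path)) (read_px(mask_path) != 0) * 1 else NULL
  radiograph(px, image_id = image_id %||% sub("\\.[^.]+$", "", basename(path)),
             patient_id = patient_id, mask = mask)
}

#' Write a radiograph (and optionally its mask) as PNG
#'
#' @param image A [radiograph].
#' @param path Output PNG path.
#' @param mask_path Optional output path for the binary mask.
#' @return `image`, invisibly.
#' @export
write_radiograph <- function(image, path, mask_path = NULL) {
  stopifnot(inherits(image, "radiograph"))
  png::writePNG(image$pixels, path)
  if (!is.null(mask_path)) {
    if (is.null(image$mask)) abort("Radiograph has no mask to write.")
    png::writePNG((image$mask != 0) * 1, mask_path)
  }
  invisible(image)
}
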