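#' Crop an image to the bounding box of its foreground
#'
#' Finds the smallest axis-aligned rectangle containing every pixel whose
#' intensity exceeds `background_level` and returns that subimage. On
#' skull-stripped MRI slices the background is exactly zero, so the default
#' threshold isolates the brain region; raise it for noisy backgrounds.
#'
#' @param img Numeric matrix of pixel intensities.
#' @param background_level Intensity threshold; pixels strictly above it are
#'   treated as foreground. Default 0.
#' @return A numeric matrix, the cropped subimage. Idempotent: cropping a
#'   cropped image returns it unchanged.
#' @examples
#' m <- matrix(0, 10, 10)
#' m[3:6, 4:8] <- 1
#' dim(crop_to_bounding_box(m)) # 4 x 5
#' @export
crop_to_bounding_box <- function(img, background_level = 0) {
  img <- as_gray_image(img)
  if (background_level < 0)
    stop("`background_level` must be >= 0")
  fg <- img > background_level
  if (!any(fg))
    stop("empty foreground: no pixel exceeds the background level")
  rows <- which(rowSums(fg) > 0)
  cols <- which(colSums(fg) > 0)
  img[rows[1]:rows[length(rows)], cols[1]:cols[length(cols)], drop = FALSE]
}

#' Resize an image to a square
#'
#' Bilinear resampling to `side` x `side` pixels. Bilinear interpolation is a
#' convex combination of neighbouring pixels, so the output never leaves the
#' intensity range of the input; nearest-neighbour is available for
#' label-like images where blocky artifacts are preferable to blending.
#'
#' @param img Numeric matrix.
#' @param side Target side length in pixels (>= 2). Default 512, the
#'   standard working size of the pipeline.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A `side` x `side` numeric matrix.
#' @export
resize_image <- function(img, side = 512L, method = c("bilinear", "nearest")) {
  img <- as_gray_image(img)
  method <- match.arg(method)
  side <- as.integer(side)
  if (is.na(side) || side < 2)
    stop("invalid size: `side` must be an integer >= 2")
  if (nrow(img) == side && ncol(img) == side)
    return(img)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(img, w = side, h = side, filter = filt)
  out <- matrix(as.numeric(out), side, side)
  # clamp away float dust so the intensity range is exactly preserved
  pmin(pmax(out, min(img)), max(img))
}

#' Standard preprocessing: bounding-box crop then square resize
#'
#' @inheritParams crop_to_bounding_box
#' @inheritParams resize_image
#' @return A `side` x `side` numeric matrix containing the cropped
#'   foreground, resampled anisotropically (no aspect-ratio padding).
#' @export
preprocess_image <- function(img, background_level = 0, side = 512L) {
  resize_image(crop_to_bounding_box(img, background_level), side = side)
}

# validate/coerce a grayscale image to a plain numeric matrix
as_gray_image <- function(img) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (is.data.frame(img)) img <- as.matrix(img)
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (nrow(img) < 1 || ncol(img) < 1)
    stop("image must have at least one pixel")
  if (any(!is.finite(img)))
    stop("image contains non-finite intensities")
  storage.mode(img) <- "double"
  img
}
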