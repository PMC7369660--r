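#' Read a grayscale image from PNG, TIFF, or NIfTI
#'
#' PNG and TIFF are read as 2D grayscale arrays scaled to \[0, 1\] (8- and
#' 16-bit integer data are already mapped to \[0, 1\] by the readers).
#' Multi-channel images are either rejected or, with `to_gray = TRUE`,
#' converted by channel averaging. NIfTI volumes are sliced with `slice`
#' along `axis` and min-max rescaled to \[0, 1\] when the data leave that
#' range (MRI intensities are in arbitrary units).
#'
#' @param path File path (`.png`, `.tif(f)`, `.nii`, `.nii.gz`).
#' @param slice Slice index for volumes (default: middle slice).
#' @param axis Axis (1-3) along which to slice a volume; default 3
#'   (axial).
#' @param to_gray Average channels of an RGB image instead of erroring.
#' @return Numeric matrix with values in \[0, 1\].
#' @export
read_gray_image <- function(path, slice = NULL, axis = 3L, to_gray = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  arr <-
    if (grepl("\\.png$", lower)) png::readPNG(path)
    else if (grepl("\\.tiff?$", lower)) tiff::readTIFF(path)
    else if (grepl("\\.nii(\\.gz)?$", lower)) {
      vol <- as.array(RNifti::readNifti(path))
      if (length(dim(vol)) == 2L) vol
      else {
        axis <- as.integer(axis)
        if (axis < 1L || axis > length(dim(vol)))
          stop("axis out of range for this volume")
        if (is.null(slice)) slice <- (dim(vol)[axis] + 1L) %/% 2L
        if (slice < 1L || slice > dim(vol)[axis])
          stop("slice index out of range")
        idx <- rep(list(quote(expr = )), length(dim(vol)))
        idx[[axis]] <- slice
        do.call(`[`, c(list(vol), idx, list(drop = TRUE)))
      }
    }
    else stop("unknown format: ", path)
  if (length(dim(arr)) == 3L) {
    if (!to_gray)
      stop("multi-channel image; pass to_gray = TRUE to average channels")
    arr <- apply(arr, c(1, 2), mean)
  }
  arr <- as_gray_image(as.matrix(arr))
  rng <- range(arr)
  if (rng[1] < 0 || rng[2] > 1) {
    if (rng[2] > rng[1]) arr <- (arr - rng[1]) / (rng[2] - rng[1])
    else arr <- matrix(0, nrow(arr), ncol(arr))
  }
  arr
}

#' Write / read a labelled feature table as CSV
#'
#' CSV with a header row and the `label` column last; numeric values are
#' written with full precision so the round trip is lossless to 15
#' significant digits.
#'
#' @param table Data frame of features plus `label`.
#' @param path Output path.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the data frame with `label` as factor.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("refusing to write an empty table")
  if ("label" %in% names(table))
    table <- table[c(setdiff(names(table), "label"), "label")]
  # 17 significant digits round-trip IEEE doubles exactly
  out <- table
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- as.data.frame(data.table::fread(path))
  if ("label" %in% names(tab)) tab$label <- factor(tab$label)
  tab
}

#' Write phantom images and a manifest to a directory
#'
#' Saves each image as a 16-bit grayscale PNG plus a `manifest.csv` with
#' columns `path,label`, the on-disk interface of the extraction CLI.
#'
#' @param phantoms Result of [generate_phantoms()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_phantom_dir <- function(phantoms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(phantoms$images)
  paths <- file.path(dir, sprintf("phantom_%03d_%s.png", seq_len(n),
                                  phantoms$labels))
  for (k in seq_len(n))
    png::writePNG(phantoms$images[[k]], paths[k])
  manifest <- data.frame(path = paths, label = as.character(phantoms$labels))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
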