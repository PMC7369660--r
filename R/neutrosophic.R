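#' Local mean filter with symmetric reflection padding
#'
#' Mean of the `window` x `window` neighbourhood around each pixel, the
#' smoothing that underlies the truth map of the neutrosophic transform.
#' Borders are handled by half-sample symmetric reflection (the edge row or
#' column is duplicated), which avoids the artificial dark frame that
#' zero-padding would inject into the membership maps.
#'
#' @param img Numeric matrix.
#' @param window Odd integer window side, at most `min(dim(img))`.
#' @return Numeric matrix of local means, same shape as `img`.
#' @examples
#' local_mean(matrix(c(0, 3, 6), 1, 3), 3) # 1, 3, 5
#' @export
local_mean <- function(img, window = 5L) {
  img <- as_gray_image(img)
  window <- as.integer(window)
  if (is.na(window) || window < 1 || window %% 2L == 0L)
    stop("invalid window: must be a positive odd integer")
  if (window == 1L) return(img)
  k <- (window - 1L) %/% 2L
  p <- sym_pad(img, k)
  # box mean via a summed-area table
  S <- apply(apply(p, 2, cumsum), 1, cumsum)
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  h <- nrow(img); w <- ncol(img)
  r1 <- 1:h; r2 <- r1 + window - 1L
  c1 <- 1:w; c2 <- c1 + window - 1L
  tot <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  matrix(tot / (window * window), h, w)
}

# half-sample symmetric extension index: 1..n reflected with edge
# duplication, periodic with period 2n, valid for any pad width
sym_idx <- function(p, n) {
  m <- (p - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

sym_pad <- function(m, k) {
  ri <- sym_idx((1L - k):(nrow(m) + k), nrow(m))
  ci <- sym_idx((1L - k):(ncol(m) + k), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Map a grayscale image into the neutrosophic domain
#'
#' Each pixel is assigned three membership degrees in \[0, 1\]:
#' * `T` (truth): the min-max normalised local mean, the degree to which the
#'   pixel belongs to the bright/object set;
#' * `I` (indeterminacy): the min-max normalised homogeneity
#'   `delta = |g - local_mean(g)|`, large where the pixel disagrees with its
#'   neighbourhood;
#' * `F` (falsity): `1 - T`.
#'
#' Normalisation bounds are taken per image (the minimum and maximum of the
#' local-mean and homogeneity maps of this image), so each map attains both
#' 0 and 1 exactly. A constant image has degenerate (zero-range) maps and
#' raises an error, since every downstream texture statistic would be
#' undefined on it.
#'
#' @param img Numeric matrix.
#' @param window Odd local-mean window side; default 5.
#' @return An object of class `neutrosophic_image`: list with matrices `T`,
#'   `I`, `F`, the `window`, and `stats` (the normalisation bounds
#'   `gbar_min`, `gbar_max`, `delta_min`, `delta_max`).
#' @examples
#' ns <- to_neutrosophic(matrix(c(0, 3, 6), 1, 3), 3)
#' ns$T # 0, 0.5, 1
#' @export
to_neutrosophic <- function(img, window = 5L) {
  img <- as_gray_image(img)
  gbar <- local_mean(img, window)
  gmin <- min(gbar); gmax <- max(gbar)
  if (gmax <= gmin)
    stop("degenerate truth map: local-mean range is zero (constant image?)")
  delta <- abs(img - gbar)
  dmin <- min(delta); dmax <- max(delta)
  if (dmax <= dmin)
    stop("degenerate indeterminacy map: homogeneity range is zero")
  Tm <- (gbar - gmin) / (gmax - gmin)
  Im <- (delta - dmin) / (dmax - dmin)
  structure(
    list(T = Tm, I = Im, F = 1 - Tm, window = window,
         stats = c(gbar_min = gmin, gbar_max = gmax,
                   delta_min = dmin, delta_max = dmax)),
    class = "neutrosophic_image")
}

#' @export
print.neutrosophic_image <- function(x, ...) {
  cat(sprintf("neutrosophic image: %d x %d, window %d\n",
              nrow(x$T), ncol(x$T), x$window))
  cat(sprintf("  T in [%.3f, %.3f], I in [%.3f, %.3f], F = 1 - T\n",
              min(x$T), max(x$T), min(x$I), max(x$I)))
  invisible(x)
}

#' Write the T/I/F maps of a neutrosophic image as PNG files
#'
#' Debug/inspection helper; writes `<prefix>_T.png`, `_I.png`, `_F.png`.
#'
#' @param ns A `neutrosophic_image`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_ns_maps <- function(ns, prefix) {
  stopifnot(inherits(ns, "neutrosophic_image"))
  paths <- paste0(prefix, "_", c("T", "I", "F"), ".png")
  maps <- list(ns$T, ns$I, ns$F)
  for (i in 1:3) png::writePNG(maps[[i]], paths[i])
  invisible(paths)
}
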