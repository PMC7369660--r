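#' Seeded two-class texture phantoms
#'
#' Generates grayscale phantom images emulating the textural contrast
#' between benign (low-grade) and malignant (high-grade) tumor slices:
#' both classes are smoothed Gaussian random fields, but the benign class
#' uses a wide smoothing kernel (long gray-level runs, low local contrast)
#' while the malignant class uses a narrow kernel and superimposes a few
#' higher-contrast elliptical blobs (short runs, rough texture). Kernel
#' width maps monotonically to run-length and co-occurrence structure, so
#' `separation` acts as a dial from statistically identical classes
#' (`0`) to well-separated ones (`1`).
#'
#' Each image has a zero background margin (so bounding-box cropping is
#' exercised) and foreground intensities in (0, 1]; everything is
#' reproducible from `seed`.
#'
#' @param n_per_class Images per class (default 20).
#' @param side Image side in pixels; must be a multiple of
#'   `2^slt_scales` so the images feed the Slantlet stage directly.
#'   Default 128.
#' @param separation In \[0, 1\]: textural separation between the classes.
#' @param benign_sigma,malignant_sigma Gaussian smoothing standard
#'   deviations (pixels) of the two classes at full separation; at
#'   `separation = s` the malignant width is interpolated toward the
#'   benign one.
#' @param blob_count,blob_contrast Number and amplitude of malignant
#'   blobs; amplitude is in units of the texture field's standard
#'   deviation and scales with `separation`.
#' @param noise_sd Standard deviation of white sensor noise added after
#'   smoothing, relative to the unit-variance texture field.
#' @param margin Zero-background border width in pixels (default
#'   `side %/% 8`).
#' @param imbalance If `TRUE`, use a 2.8:1 malignant:benign ratio
#'   (`2.8 * n_per_class` malignant images) instead of balanced classes.
#' @param slt_scales Dyadic compatibility check for `side`.
#' @param seed Integer seed.
#' @return List with `images` (list of `side` x `side` matrices) and
#'   `labels` (factor, levels benign/malignant).
#' @export
generate_phantoms <- function(n_per_class = 20L, side = 128L, separation = 1,
                              benign_sigma = 4, malignant_sigma = 1,
                              blob_count = 3L, blob_contrast = 2,
                              noise_sd = 0.05, margin = NULL,
                              imbalance = FALSE, slt_scales = 2L, seed = 1L) {
  side <- as.integer(side)
  if (side %% 2L^slt_scales != 0L || side < 2L^(slt_scales + 1L))
    stop("invalid size: `side` must be a multiple of 2^slt_scales")
  stopifnot(n_per_class >= 1, separation >= 0, separation <= 1, noise_sd >= 0)
  if (is.null(margin)) margin <- side %/% 8L
  n_ben <- as.integer(n_per_class)
  n_mal <- if (imbalance) as.integer(round(2.8 * n_per_class)) else n_ben
  sig_mal <- benign_sigma + (malignant_sigma - benign_sigma) * separation
  set.seed(seed)
  make_one <- function(sigma, blobs) {
    base <- gaussian_smooth(matrix(stats::rnorm(side * side), side, side),
                            sigma)
    # standardize the field so its amplitude does not depend on the kernel
    # width; noise_sd is then relative to texture amplitude for both classes
    base <- (base - mean(base)) / stats::sd(base)
    base <- base + matrix(stats::rnorm(side * side, sd = noise_sd),
                          side, side)
    if (blobs > 0) {
      ctr <- cbind(stats::runif(blobs, 0.25, 0.75) * side,
                   stats::runif(blobs, 0.25, 0.75) * side)
      ax <- stats::runif(blobs, side / 16, side / 8)
      ay <- stats::runif(blobs, side / 16, side / 8)
      rot <- stats::runif(blobs, 0, pi)
      rr <- row(base); cc <- col(base)
      for (b in seq_len(blobs)) {
        dx <- (rr - ctr[b, 1]); dy <- (cc - ctr[b, 2])
        u <- cos(rot[b]) * dx + sin(rot[b]) * dy
        v <- -sin(rot[b]) * dx + cos(rot[b]) * dy
        base <- base + blob_contrast * separation *
          exp(-((u / ax[b])^2 + (v / ay[b])^2))
      }
    }
    rng <- range(base)
    img <- 0.02 + 0.98 * (base - rng[1]) / (rng[2] - rng[1])
    if (margin > 0) {
      frame <- matrix(0, side, side)
      inner <- (margin + 1L):(side - margin)
      frame[inner, inner] <- img[inner, inner]
      img <- frame
    }
    img
  }
  images <- c(
    lapply(seq_len(n_ben), function(k) make_one(benign_sigma, 0L)),
    lapply(seq_len(n_mal), function(k) make_one(sig_mal, blob_count)))
  labels <- factor(rep(c("benign", "malignant"), c(n_ben, n_mal)),
                   levels = c("benign", "malignant"))
  list(images = images, labels = labels)
}

# separable Gaussian smoothing with symmetric reflection padding
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-k):k
  w <- exp(-x^2 / (2 * sigma^2)); w <- w / sum(w)
  p <- sym_pad(m, k)
  smooth_dim <- function(mat) {
    # convolve each column with w (valid region only)
    out <- matrix(0, nrow(mat) - 2 * k, ncol(mat))
    for (d in seq_along(x))
      out <- out + w[d] * mat[(k + 1 + x[d]):(nrow(mat) - k + x[d]), ,
                              drop = FALSE]
    out
  }
  res <- smooth_dim(p)
  res <- t(smooth_dim(t(res)))
  res
}
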