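#' Construct the Slantlet filter bank
#'
#' Builds the `l`-scale Slantlet analysis filter bank: a parallel
#' (non-iterated) orthonormal filter bank whose filters are piecewise linear
#' over the two halves of their support. The bank has `2l` channels:
#'
#' * the coarsest-scale lowpass/slant pair `(h_l, f_l)`, each with
#'   `2^(l+1)` taps, advanced by `2^l` samples per output (adjacent basis
#'   vectors overlap by half their support, wrapping periodically at the
#'   signal boundary);
#' * for each scale `i = 1, ..., l-1`, the bandpass filter `g_i`
#'   (`2^(i+1)` taps) and its time reverse, each advanced by `2^(i+1)`
#'   samples (non-overlapping blocks).
#'
#' The filter parameters are obtained by solving the defining constraint
#' system exactly: unit norm, mutual orthogonality of all basis vectors and
#' their admissible shifts, two zero moments on every bandpass filter
#' (`sum g = 0`, `sum n*g = 0`, so constants and ramps are annihilated),
#' and zero mean plus zero first moment on `f_l` so that constant and linear
#' trends are carried entirely by the `(h_l, f_l)` pair. Within the
#' piecewise-linear family these constraints reduce to one scalar quadratic
#' per scale, which is solved in closed form; signs and root choices are
#' fixed deterministically (largest root for `g_i`; for the lowpass pair the
#' root maximising `|sum h|`; first nonzero tap of each filter positive,
#' `sum h > 0`).
#'
#' @param l Number of channel pairs (scales), >= 1.
#' @return An object of class `slt_filter_bank`: list with `l`, `h`, `f`
#'   (numeric vectors of length `2^(l+1)`), and `g` (list of bandpass
#'   filters for scales `1..l-1`; empty when `l = 1`).
#' @examples
#' bank <- slt_filter_bank(2)
#' sapply(bank$g, length) # 4
#' sum(bank$g[[1]])       # ~0: first zero moment
#' @export
slt_filter_bank <- function(l) {
  l <- as.integer(l)
  if (is.na(l) || l < 1)
    stop("invalid scale count: `l` must be an integer >= 1")
  g <- list()
  if (l > 1) for (i in 1:(l - 1)) g[[i]] <- slt_solve_g(i)
  hf <- slt_solve_hf(l)
  structure(list(l = l, h = hf$h, f = hf$f, g = g),
            class = "slt_filter_bank")
}

# bandpass filter g_i: support 2^(i+1), piecewise linear on each half,
# two zero moments, unit norm, orthogonal to its time reverse
slt_solve_g <- function(i) {
  m <- 2L^i
  n1 <- 0:(m - 1); n2 <- m:(2L * m - 1L)
  # write g = a0 + a1*n on the first half, b0 + b1*n on the second; the two
  # moment conditions fix (b0, b1) linearly given (a0, a1)
  A <- rbind(c(m, sum(n2)), c(sum(n2), sum(n2^2)))
  B <- rbind(c(m, sum(n1)), c(sum(n1), sum(n1^2)))
  basis <- lapply(list(c(1, 0), c(0, 1)), function(a) {
    b <- solve(A, -B %*% a)
    c(a[1] + a[2] * n1, b[1] + b[2] * n2)
  })
  u <- basis[[1]]; v <- basis[[2]]
  quu <- sum(u * rev(u)); quv <- sum(u * rev(v)); qvv <- sum(v * rev(v))
  # <g, rev g> = 0 is a quadratic in t = alpha/beta for g = alpha*u + beta*v
  disc <- quv^2 - quu * qvv
  t0 <- (-quv + sqrt(disc)) / quu   # deterministic: larger root
  g <- t0 * u + v
  g <- g / sqrt(sum(g^2))
  if (g[which(g != 0)[1]] < 0) g <- -g
  g
}

# coarsest-scale pair (h_l, f_l): support 2^(l+1), advanced by 2^l.
# Each half of h and f is an affine sequence, i.e. lies in the plane
# V = span{1, n}. Orthogonality of overlapping shifts forces the second
# half of each filter to be perpendicular (in V) to the first half of the
# other and of itself, which collapses the system to one direction angle;
# the two moment conditions on f pin that angle via a scalar quadratic.
slt_solve_hf <- function(l) {
  m <- 2L^l
  e <- rep(1, m); r <- 0:(m - 1)
  v1 <- e / sqrt(m)
  v2 <- r - sum(r * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  a1 <- sum(e * v1); a2 <- sum(e * v2)
  b1 <- sum(r * v1); b2 <- sum(r * v2)
  # u = cos*v1 + sin*v2 is the common direction of the first halves;
  # w = -sin*v1 + cos*v2 that of the second halves. Requiring f to have
  # zero 0th and 1st moments leaves one homogeneous quadratic in (cos, sin).
  quad <- function(c_, s_) {
    u0 <- c_ * a1 + s_ * a2; w0 <- -s_ * a1 + c_ * a2
    m1u <- c_ * b1 + s_ * b2; m1w <- -s_ * b1 + c_ * b2
    -w0 * m1u + u0 * m1w + m * u0 * w0
  }
  A <- quad(1, 0); B <- quad(0, 1); C <- quad(1, 1) - A - B
  disc <- C^2 - 4 * A * B
  roots <- c((-C + sqrt(disc)) / (2 * A), (-C - sqrt(disc)) / (2 * A))
  build <- function(t0) {
    c_ <- 1 / sqrt(1 + t0^2); s_ <- t0 / sqrt(1 + t0^2)
    u <- c_ * v1 + s_ * v2; w <- -s_ * v1 + c_ * v2
    u0 <- sum(u); w0 <- sum(w)
    nr <- sqrt(u0^2 + w0^2)
    list(h = c(u0 * u, w0 * w) / nr, f = c(-w0 * u, u0 * w) / nr)
  }
  cand <- lapply(roots, build)
  hf <- cand[[which.max(vapply(cand, function(x) abs(sum(x$h)), 0))]]
  if (sum(hf$h) < 0) hf$h <- -hf$h
  if (hf$f[which(hf$f != 0)[1]] < 0) hf$f <- -hf$f
  hf
}

#' @export
print.slt_filter_bank <- function(x, ...) {
  cat(sprintf("Slantlet filter bank: l = %d (%d channels)\n", x$l, 2L * x$l))
  cat(sprintf("  h%d, f%d: %d taps; ", x$l, x$l, length(x$h)))
  if (length(x$g))
    cat(paste0("g", seq_along(x$g), ": ", vapply(x$g, length, 0L), " taps",
               collapse = "; "))
  cat("\n")
  invisible(x)
}

#' Slantlet transform matrix
#'
#' Assembles the `n` x `n` orthonormal matrix whose rows are the shifted
#' filter-bank basis vectors, ordered coarse to fine: the `n / 2^l` shifts
#' of `h_l`, then of `f_l`, then for `i = l-1, ..., 1` the `n / 2^(i+1)`
#' shifts of `g_i` and of its time reverse. Lowpass rows wrap periodically;
#' bandpass rows tile the signal in disjoint blocks.
#'
#' @param bank An `slt_filter_bank`, or an integer scale count.
#' @param n Signal length: a multiple of `2^l`, at least the filter length
#'   `2^(l+1)`.
#' @return A list of class `slt_matrix` with the orthonormal `matrix` and a
#'   `channels` data frame (one row per transform row: channel name, scale,
#'   shift).
#' @export
slt_matrix <- function(bank, n) {
  if (!inherits(bank, "slt_filter_bank")) bank <- slt_filter_bank(bank)
  l <- bank$l; n <- as.integer(n)
  m <- as.integer(2^l)
  if (is.na(n) || n %% m != 0L || n < 2L * m)
    stop(sprintf(
      "invalid length: n must be a multiple of 2^l = %d and >= %d", m, 2L * m))
  G <- matrix(0, n, n)
  chan <- character(n); scale <- integer(n); shift <- integer(n)
  row <- 0L
  place_wrapped <- function(filt, k) ((k * m) + seq_along(filt) - 1L) %% n + 1L
  for (nm in c("h", "f")) {
    filt <- bank[[nm]]
    for (k in 0:(n / m - 1L)) {
      row <- row + 1L
      G[row, place_wrapped(filt, k)] <- filt
      chan[row] <- nm; scale[row] <- l; shift[row] <- k * m
    }
  }
  if (l > 1L) for (i in (l - 1L):1L) {
    filt <- bank$g[[i]]; L <- as.integer(2^(i + 1))
    for (nm in c("g", "gr")) {
      fv <- if (nm == "g") filt else rev(filt)
      for (k in 0:(n / L - 1L)) {
        row <- row + 1L
        G[row, k * L + 1:L] <- fv
        chan[row] <- nm; scale[row] <- i; shift[row] <- k * L
      }
    }
  }
  structure(list(matrix = G, l = l, n = n,
                 channels = data.frame(channel = chan, scale = scale,
                                       shift = shift)),
            class = "slt_matrix")
}

#' 2D Slantlet transform
#'
#' Separable forward transform: the Slantlet matrix is applied to the
#' columns and then the rows of the image (`C = G X t(G)`). Orthonormality
#' gives exact energy preservation and the coefficient array partitions
#' into `(2l)^2` subbands indexed by the row/column channel pair; the
#' `h`/`h` block is the LL approximation, everything else carries detail.
#' Images whose sides are not multiples of `2^l` (or are shorter than the
#' filter support) are first reflection-padded symmetrically on both sides
#' to the next admissible size.
#'
#' @param img Numeric matrix.
#' @param l Scale count; default 2.
#' @return Object of class `slt_coefficients`: list with the coefficient
#'   `matrix`, `l`, the padded size `n` x `n2`, row/column `channels`
#'   tables, and the original image dimensions.
#' @export
slt2d_forward <- function(img, l = 2L) {
  img <- as_gray_image(img)
  od <- dim(img)
  l <- as.integer(l)
  if (is.na(l) || l < 1) stop("invalid scale count")
  need <- function(d) {
    m <- as.integer(2^l)
    max(2L * m, as.integer(m * ceiling(d / m)))
  }
  n1 <- need(nrow(img)); n2 <- need(ncol(img))
  if (n1 != nrow(img) || n2 != ncol(img))
    img <- pad_reflect_to(img, n1, n2)
  G1 <- slt_matrix(l, n1); G2 <- if (n2 == n1) G1 else slt_matrix(l, n2)
  co <- G1$matrix %*% img %*% t(G2$matrix)
  structure(list(matrix = co, l = l, n = c(n1, n2),
                 row_channels = G1$channels, col_channels = G2$channels,
                 orig_dim = od),
            class = "slt_coefficients")
}

pad_reflect_to <- function(img, n1, n2) {
  grow <- function(idx, target) {
    while (length(idx) < target) {
      k <- min(length(idx), target - length(idx))
      lo <- rev(idx[seq_len(ceiling(k / 2))])
      hi <- rev(idx)[seq_len(floor(k / 2))]
      idx <- c(lo, idx, rev(hi))
    }
    idx
  }
  img[grow(seq_len(nrow(img)), n1), grow(seq_len(ncol(img)), n2), drop = FALSE]
}

#' Inverse 2D Slantlet transform
#'
#' Exact left-inverse of [slt2d_forward()] (up to float round-off), by
#' orthonormality: `X = t(G) C G`.
#'
#' @param coeffs An `slt_coefficients` object.
#' @return The reconstructed image (padded size).
#' @export
slt2d_inverse <- function(coeffs) {
  if (!inherits(coeffs, "slt_coefficients"))
    stop("malformed coefficient object")
  G1 <- slt_matrix(coeffs$l, coeffs$n[1])
  G2 <- if (coeffs$n[2] == coeffs$n[1]) G1 else slt_matrix(coeffs$l, coeffs$n[2])
  t(G1$matrix) %*% coeffs$matrix %*% G2$matrix
}

#' Suppress small Slantlet coefficients
#'
#' Coefficients with magnitude below `eps * max(|c|)` are zeroed; small
#' coefficients carry noise-like detail and can be discarded before texture
#' statistics are computed. `eps = 0` leaves the array untouched.
#'
#' @param coeffs An `slt_coefficients` object.
#' @param eps Relative threshold, >= 0.
#' @return The thresholded `slt_coefficients`.
#' @export
slt_suppress <- function(coeffs, eps) {
  if (!inherits(coeffs, "slt_coefficients"))
    stop("malformed coefficient object")
  if (!is.numeric(eps) || length(eps) != 1 || is.na(eps) || eps < 0)
    stop("invalid threshold: `eps` must be a single number >= 0")
  if (eps > 0) {
    cut <- eps * max(abs(coeffs$matrix))
    coeffs$matrix[abs(coeffs$matrix) < cut] <- 0
  }
  coeffs
}

#' Extract one subband of a 2D Slantlet decomposition
#'
#' @param coeffs An `slt_coefficients` object.
#' @param row_channel,col_channel Channel names (`"h"`, `"f"`, `"g"`,
#'   `"gr"`); `row_scale`/`col_scale` select the scale for bandpass
#'   channels.
#' @param row_scale,col_scale Scale indices (defaults: the channel's only
#'   scale for `h`/`f`, finest scale for `g`/`gr`).
#' @return Numeric matrix holding that subband's coefficients.
#' @export
slt_subband <- function(coeffs, row_channel = "h", col_channel = "h",
                        row_scale = NULL, col_scale = NULL) {
  if (!inherits(coeffs, "slt_coefficients"))
    stop("malformed coefficient object")
  pick <- function(tab, ch, sc) {
    if (is.null(sc)) sc <- if (ch %in% c("h", "f")) coeffs$l else 1L
    idx <- which(tab$channel == ch & tab$scale == sc)
    if (!length(idx)) stop("no such subband")
    idx
  }
  coeffs$matrix[pick(coeffs$row_channels, row_channel, row_scale),
                pick(coeffs$col_channels, col_channel, col_scale),
                drop = FALSE]
}

#' @export
print.slt_coefficients <- function(x, ...) {
  cat(sprintf("2D Slantlet coefficients: %d x %d, l = %d (%d x %d subbands)\n",
              x$n[1], x$n[2], x$l, 2L * x$l, 2L * x$l))
  invisible(x)
}
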