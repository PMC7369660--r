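#' Quantize an image to integer gray levels
#'
#' Uniformly bins the intensity range `[min, max]` into `n_levels` levels
#' labelled `1..n_levels` (the minimum maps to level 1, the maximum to
#' `n_levels`). Gray-level matrices are computed on these labels, so the
#' level count bounds the size of every co-occurrence and run-length
#' matrix.
#'
#' @param img Numeric matrix.
#' @param n_levels Number of gray levels, >= 2. Default 8.
#' @param allow_constant If `TRUE`, a constant image maps to all level 1
#'   instead of raising an error.
#' @return Integer matrix of levels with attribute `n_levels`.
#' @export
quantize_image <- function(img, n_levels = 8L, allow_constant = FALSE) {
  img <- as_gray_image(img)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2)
    stop("invalid level count: `n_levels` must be >= 2")
  lo <- min(img); hi <- max(img)
  if (hi <= lo) {
    if (!allow_constant) stop("cannot quantize a constant image")
    q <- matrix(1L, nrow(img), ncol(img))
  } else {
    breaks <- seq(lo, hi, length.out = n_levels + 1L)
    q <- matrix(findInterval(img, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE),
                nrow(img), ncol(img))
    storage.mode(q) <- "integer"
  }
  attr(q, "n_levels") <- n_levels
  q
}

q_levels <- function(q) {
  nl <- attr(q, "n_levels")
  if (is.null(nl)) nl <- max(q)
  as.integer(nl)
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels `(q[r, c], q[r + dr, c + dc])` over
#' every position where both pixels fall inside the image, normalised to
#' sum 1. The matrix is directional: it is not symmetrised, because the
#' symmetry descriptor and the odd difference moments vanish identically on
#' a symmetrised matrix.
#'
#' @param q Quantized image from [quantize_image()].
#' @param offset Integer displacement `c(dr, dc)`, nonzero.
#' @return Object of class `glcm`: list with the normalised `P`
#'   (`n_levels` x `n_levels`), the `offset`, and `n_pairs`.
#' @export
compute_glcm <- function(q, offset = c(0L, 1L)) {
  nl <- q_levels(q)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  if (dr == 0L && dc == 0L) stop("offset must be nonzero")
  h <- nrow(q); w <- ncol(q)
  r0 <- seq_len(h); c0 <- seq_len(w)
  r1 <- r0[r0 + dr >= 1L & r0 + dr <= h]
  c1 <- c0[c0 + dc >= 1L & c0 + dc <= w]
  if (!length(r1) || !length(c1))
    stop("empty pairs: offset exceeds the image extent")
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  P <- matrix(0, nl, nl)
  tab <- table(factor(a, levels = 1:nl), factor(b, levels = 1:nl))
  P[] <- as.numeric(tab)
  n_pairs <- sum(P)
  structure(list(P = P / n_pairs, offset = c(dr, dc), n_pairs = n_pairs),
            class = "glcm")
}

#' Co-occurrence texture descriptors
#'
#' The ten descriptors of the co-occurrence family, evaluated on the
#' normalised matrix with gray levels as indices: homogeneity (inverse
#' difference moment), energy, entropy (natural log, with `0 log 0 = 0`),
#' contrast, symmetry (`sum |P(i,j) - P(j,i)|`), correlation, and the
#' first four difference moments `sum (i-j)^k P(i,j)`.
#'
#' When a marginal standard deviation is zero (all mass on one row or
#' column) the correlation is reported as 0 and the result carries a
#' `degenerate_correlation` attribute rather than propagating `NaN`.
#'
#' @param co A `glcm` object.
#' @return Named numeric vector of length 10: `glcm_hom`, `glcm_enr`,
#'   `glcm_ent`, `glcm_con`, `glcm_sym`, `glcm_cor`, `glcm_mom1` ..
#'   `glcm_mom4`.
#' @export
glcm_features <- function(co) {
  stopifnot(inherits(co, "glcm"))
  P <- co$P
  nl <- nrow(P)
  i <- row(P); j <- col(P)
  hom <- sum(P / (1 + (i - j)^2))
  enr <- sum(P^2)
  ent <- -sum(ifelse(P > 0, P * log(P), 0))
  con <- sum((i - j)^2 * P)
  sym <- sum(abs(P - t(P)))
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(nl)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  degen <- sx == 0 || sy == 0
  cor <- if (degen) 0 else (sum(i * j * P) - mux * muy) / (sx * sy)
  out <- c(glcm_hom = hom, glcm_enr = enr, glcm_ent = ent, glcm_con = con,
           glcm_sym = sym, glcm_cor = cor,
           glcm_mom1 = sum((i - j) * P), glcm_mom2 = sum((i - j)^2 * P),
           glcm_mom3 = sum((i - j)^3 * P), glcm_mom4 = sum((i - j)^4 * P))
  if (degen) attr(out, "degenerate_correlation") <- TRUE
  out
}

# index offsets of one step along a run-length/co-occurrence direction
.dir_step <- function(direction) {
  switch(as.character(direction),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135 (degrees)"))
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along one of the four standard
#' directions. Entry `P[i, j]` is the number of maximal runs of level `i`
#' with length `j`; both indices are 1-based so low/high gray-level
#' emphases (`1/i^2`, `i^2`) are defined.
#'
#' @param q Quantized image.
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @return Object of class `glrlm`: list with the count matrix `P`
#'   (`n_levels` rows, max-run-length columns), `n_runs`, `n_pixels`, and
#'   `direction`.
#' @export
compute_glrlm <- function(q, direction = 0) {
  nl <- q_levels(q)
  h <- nrow(q); w <- ncol(q)
  lines <- switch(as.character(direction),
    "0"   = lapply(seq_len(h), function(r) q[r, ]),
    "90"  = lapply(seq_len(w), function(cc) q[, cc]),
    "45"  = split(q[cbind(c(row(q)), c(col(q)))],
                  c(row(q)) + c(col(q))),
    "135" = split(q[cbind(c(row(q)), c(col(q)))],
                  c(col(q)) - c(row(q))),
    stop("direction must be one of 0, 45, 90, 135 (degrees)"))
  # for the diagonal cases the split above groups by anti-diagonal
  # (r + c) or diagonal (c - r) index; within a group the elements are in
  # increasing row order, i.e. consecutive along the direction
  runs <- lapply(lines, function(v) {
    rl <- rle(as.integer(v))
    cbind(rl$values, rl$lengths)
  })
  runs <- do.call(rbind, runs)
  maxlen <- max(runs[, 2])
  P <- matrix(0, nl, maxlen)
  for (k in seq_len(nrow(runs)))
    P[runs[k, 1], runs[k, 2]] <- P[runs[k, 1], runs[k, 2]] + 1
  structure(list(P = P, n_runs = sum(P), n_pixels = h * w,
                 direction = direction),
            class = "glrlm")
}

#' Run-length texture descriptors
#'
#' The seven run-length descriptors: short- and long-run emphasis, gray-
#' level nonuniformity, run percentage, run-length nonuniformity, and low/
#' high gray-level run emphasis, each normalised by the total number of
#' runs (run percentage by the pixel count).
#'
#' @param rl A `glrlm` object.
#' @return Named numeric vector of length 7: `glrlm_sre`, `glrlm_lre`,
#'   `glrlm_gln`, `glrlm_rp`, `glrlm_rln`, `glrlm_lgre`, `glrlm_hgre`.
#' @export
glrlm_features <- function(rl) {
  stopifnot(inherits(rl, "glrlm"))
  P <- rl$P; nr <- rl$n_runs
  if (nr < 1) stop("empty runs")
  i <- row(P); j <- col(P)
  c(glrlm_sre  = sum(P / j^2) / nr,
    glrlm_lre  = sum(P * j^2) / nr,
    glrlm_gln  = sum(rowSums(P)^2) / nr,
    glrlm_rp   = nr / rl$n_pixels,
    glrlm_rln  = sum(colSums(P)^2) / nr,
    glrlm_lgre = sum(P / i^2) / nr,
    glrlm_hgre = sum(P * i^2) / nr)
}

#' Gray-level difference histogram
#'
#' Normalised histogram of absolute gray-level differences
#' `|q[r, c] - q[r + dr, c + dc]|` over all positions where both pixels are
#' inside the image. Differences range over `0 .. n_levels - 1`.
#'
#' @param q Quantized image.
#' @param displacement Integer displacement `c(dr, dc)`, nonzero. Default
#'   `c(1, 1)`.
#' @return Object of class `glds`: list with probabilities `P_g` (named by
#'   difference value `0..n_levels-1`), the `displacement`, and `n_pairs`.
#' @export
compute_glds <- function(q, displacement = c(1L, 1L)) {
  nl <- q_levels(q)
  dr <- as.integer(displacement[1]); dc <- as.integer(displacement[2])
  if (dr == 0L && dc == 0L) stop("displacement must be nonzero")
  h <- nrow(q); w <- ncol(q)
  r1 <- seq_len(h); c1 <- seq_len(w)
  r1 <- r1[r1 + dr >= 1L & r1 + dr <= h]
  c1 <- c1[c1 + dc >= 1L & c1 + dc <= w]
  if (!length(r1) || !length(c1))
    stop("empty pairs: displacement exceeds the image extent")
  d <- abs(q[r1, c1, drop = FALSE] - q[r1 + dr, c1 + dc, drop = FALSE])
  counts <- tabulate(as.integer(d) + 1L, nbins = nl)
  P_g <- counts / sum(counts)
  names(P_g) <- 0:(nl - 1L)
  structure(list(P_g = P_g, displacement = c(dr, dc), n_pairs = sum(counts)),
            class = "glds")
}

#' Difference-statistics descriptors
#'
#' Four descriptors of the gray-level difference histogram: angular second
#' moment, contrast (`sum g^2 P_g`), mean (`sum g P_g`), and entropy
#' (natural log, `0 log 0 = 0`).
#'
#' @param dh A `glds` object.
#' @return Named numeric vector of length 4: `glds_asm`, `glds_con`,
#'   `glds_men`, `glds_ent`.
#' @export
glds_features <- function(dh) {
  stopifnot(inherits(dh, "glds"))
  p <- dh$P_g
  g <- as.numeric(names(p))
  c(glds_asm = sum(p^2),
    glds_con = sum(g^2 * p),
    glds_men = sum(g * p),
    glds_ent = -sum(ifelse(p > 0, p * log(p), 0)))
}

#' Aggregate feature vectors over the three neutrosophic channels
#'
#' The neutrosophic version of every descriptor is the sum of its values on
#' the T, I, and F channels; this is the elementwise sum of identically
#' named feature vectors.
#'
#' @param ft,fi,ff Named numeric vectors with identical name sets.
#' @return Named numeric vector, the elementwise sum.
#' @export
aggregate_ns <- function(ft, fi, ff) {
  if (!identical(names(ft), names(fi)) || !identical(names(ft), names(ff)))
    stop("feature name sets differ between channels")
  out <- as.numeric(ft) + as.numeric(fi) + as.numeric(ff)
  names(out) <- names(ft)
  out
}

#' All texture descriptors of one (quantized) channel image
#'
#' Convenience wrapper computing the selected descriptor families on one
#' image channel. Co-occurrence and run-length descriptors are averaged
#' over the four distance-1 directions (0, 45, 90, 135 degrees) for
#' rotation robustness; the difference statistics use a single
#' displacement.
#'
#' @param img Numeric matrix (any real-valued channel; quantized
#'   internally).
#' @param technique Character subset of `c("glcm", "glrlm", "glds")` or
#'   `"all"`.
#' @param n_levels Gray levels for quantization.
#' @param glds_displacement Displacement for the difference histogram.
#' @param allow_constant Passed to [quantize_image()].
#' @return Named numeric vector (10, 7, and/or 4 entries, concatenated in
#'   co-occurrence, run-length, difference order).
#' @export
texture_features <- function(img, technique = "all", n_levels = 8L,
                             glds_displacement = c(1L, 1L),
                             allow_constant = FALSE) {
  technique <- match_techniques(technique)
  q <- quantize_image(img, n_levels, allow_constant = allow_constant)
  dirs <- c(0, 45, 90, 135)
  out <- numeric(0)
  if ("glcm" %in% technique) {
    per <- lapply(dirs, function(d) glcm_features(compute_glcm(q, .dir_step(d))))
    out <- c(out, Reduce(`+`, per) / length(per))
  }
  if ("glrlm" %in% technique) {
    per <- lapply(dirs, function(d) glrlm_features(compute_glrlm(q, d)))
    out <- c(out, Reduce(`+`, per) / length(per))
  }
  if ("glds" %in% technique)
    out <- c(out, glds_features(compute_glds(q, glds_displacement)))
  out
}

match_techniques <- function(technique) {
  technique <- tolower(technique)
  if (identical(technique, "all")) technique <- c("glcm", "glrlm", "glds")
  bad <- setdiff(technique, c("glcm", "glrlm", "glds"))
  if (length(bad) || !length(technique))
    stop("technique must be a subset of glcm/glrlm/glds or 'all'")
  # canonical order
  c("glcm", "glrlm", "glds")[c("glcm", "glrlm", "glds") %in% technique]
}
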