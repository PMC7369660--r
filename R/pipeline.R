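#' Configuration of a feature-extraction scenario
#'
#' Bundles the knobs of the extraction pipeline. Four scenarios are
#' supported:
#' * `"spatial"` — descriptors on the raw image (baseline);
#' * `"ns"` — descriptors on each of the T/I/F membership maps, summed;
#' * `"slt"` — descriptors on the 2D Slantlet coefficient array of the raw
#'   image;
#' * `"ns-slt"` — the composite: Slantlet transform of each membership
#'   map, descriptors per map, summed over T/I/F.
#'
#' Coefficient arrays are affinely rescaled to \[0, 1\] (after optional
#' small-coefficient suppression) before quantization, since the quantizer
#' needs a bounded range.
#'
#' @param scenario One of `"ns-slt"`, `"ns"`, `"slt"`, `"spatial"`.
#' @param technique Descriptor families: subset of
#'   `c("glcm", "glrlm", "glds")` or `"all"`.
#' @param ns_window Odd window for the neutrosophic local mean (default 5).
#' @param slt_scales Slantlet scale count `l` (default 2).
#' @param n_levels Gray levels for quantization (default 8).
#' @param glds_displacement Displacement for difference statistics.
#' @param slt_eps Relative threshold for coefficient suppression
#'   (default 0 = off).
#' @param preprocess If `TRUE`, crop to the foreground bounding box and
#'   resize to `side` before extraction.
#' @param side Working image side when `preprocess = TRUE` (default 512).
#' @param background_level Foreground threshold for cropping.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("ns-slt", "ns", "slt", "spatial"),
                            technique = "all",
                            ns_window = 5L, slt_scales = 2L, n_levels = 8L,
                            glds_displacement = c(1L, 1L), slt_eps = 0,
                            preprocess = FALSE, side = 512L,
                            background_level = 0) {
  scenario <- match.arg(scenario)
  technique <- match_techniques(technique)
  stopifnot(ns_window >= 1, slt_scales >= 1, n_levels >= 2, slt_eps >= 0)
  structure(list(scenario = scenario, technique = technique,
                 ns_window = as.integer(ns_window),
                 slt_scales = as.integer(slt_scales),
                 n_levels = as.integer(n_levels),
                 glds_displacement = as.integer(glds_displacement),
                 slt_eps = slt_eps, preprocess = isTRUE(preprocess),
                 side = as.integer(side),
                 background_level = background_level),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario %s | technique %s | ns_window %d | slt l=%d | levels %d\n",
              x$scenario, paste(x$technique, collapse = "+"), x$ns_window,
              x$slt_scales, x$n_levels))
  invisible(x)
}

scenario_prefix <- function(scenario) {
  switch(scenario, "ns" = "ns_", "slt" = "slt_", "ns-slt" = "nsslt_",
         "spatial" = "")
}

# one channel image -> descriptor vector under cfg
channel_features <- function(chan, cfg, allow_constant = FALSE) {
  texture_features(chan, technique = cfg$technique, n_levels = cfg$n_levels,
                   glds_displacement = cfg$glds_displacement,
                   allow_constant = allow_constant)
}

# Slantlet-transform a channel and rescale coefficients to [0, 1]
slt_channel <- function(chan, cfg) {
  co <- slt2d_forward(chan, cfg$slt_scales)
  co <- slt_suppress(co, cfg$slt_eps)
  m <- co$matrix
  rng <- range(m)
  if (rng[2] > rng[1]) m <- (m - rng[1]) / (rng[2] - rng[1])
  m
}

#' Extract the texture feature vector of one image
#'
#' Runs the configured scenario on a single grayscale image and returns the
#' named descriptor vector (scenario-specific name prefix, families in
#' co-occurrence / run-length / difference order).
#'
#' @param img Numeric matrix.
#' @param cfg A [scenario_config()].
#' @return Named numeric vector (10 entries per co-occurrence family, 7
#'   run-length, 4 difference statistics).
#' @export
extract_features <- function(img, cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  img <- as_gray_image(img)
  if (cfg$preprocess)
    img <- preprocess_image(img, cfg$background_level, cfg$side)
  feats <- switch(cfg$scenario,
    "spatial" = channel_features(img, cfg),
    "slt" = channel_features(slt_channel(img, cfg), cfg, allow_constant = TRUE),
    "ns" = {
      ns <- to_neutrosophic(img, cfg$ns_window)
      aggregate_ns(channel_features(ns$T, cfg),
                   channel_features(ns$I, cfg),
                   channel_features(ns$F, cfg))
    },
    "ns-slt" = {
      ns <- to_neutrosophic(img, cfg$ns_window)
      aggregate_ns(
        channel_features(slt_channel(ns$T, cfg), cfg, allow_constant = TRUE),
        channel_features(slt_channel(ns$I, cfg), cfg, allow_constant = TRUE),
        channel_features(slt_channel(ns$F, cfg), cfg, allow_constant = TRUE))
    })
  names(feats) <- paste0(scenario_prefix(cfg$scenario), names(feats))
  feats
}

#' Extract a labelled feature table from a set of images
#'
#' Applies [extract_features()] to each image, in input order, and binds
#' the results with the class labels into a data frame. Images whose
#' extraction fails (e.g. degenerate membership maps of a constant image)
#' are skipped with a warning naming the image; they are never silently
#' dropped.
#'
#' @param images List of numeric matrices.
#' @param labels Vector of class labels, one per image (coerced to factor;
#'   for tumor data use levels benign/malignant).
#' @param cfg A [scenario_config()].
#' @return Data frame: one row per successfully processed image, feature
#'   columns followed by a `label` factor column. Attribute `failed` lists
#'   indices of skipped images.
#' @export
extract_dataset <- function(images, labels, cfg = scenario_config()) {
  stopifnot(length(images) == length(labels))
  if (length(images) < 2 || length(unique(labels)) < 2)
    stop("need at least two images and two classes")
  rows <- vector("list", length(images))
  failed <- integer(0)
  for (k in seq_along(images)) {
    res <- tryCatch(extract_features(images[[k]], cfg),
                    error = function(e) {
      warning(sprintf("image %d skipped: %s", k, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failed <- c(failed, k) else rows[[k]] <- res
  }
  ok <- setdiff(seq_along(images), failed)
  if (!length(ok)) stop("empty table: every image failed extraction")
  tab <- as.data.frame(do.call(rbind, rows[ok]))
  tab$label <- factor(labels[ok])
  attr(tab, "failed") <- failed
  tab
}
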