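test_that("quantization bins min-max uniformly into 1..n_levels", {
  q <- quantize_image(matrix(c(0, 0.26, 0.51, 1.0), 1, 4), 4)
  expect_identical(as.integer(q), c(1L, 2L, 3L, 4L))
  set.seed(41)
  x <- matrix(runif(100), 10, 10)
  for (nl in c(2, 8, 16)) {
    q <- quantize_image(x, nl)
    expect_identical(min(q), 1L)
    expect_identical(max(q), as.integer(nl))
  }
  expect_error(quantize_image(x, 1), "invalid level count")
  expect_error(quantize_image(matrix(1, 3, 3), 8), "constant")
  qc <- quantize_image(matrix(1, 3, 3), 8, allow_constant = TRUE)
  expect_true(all(qc == 1L))
})

toy_q <- function() {
  q <- matrix(as.integer(c(1, 1, 2, 1, 2, 2, 2, 2, 2)), 3, 3, byrow = TRUE)
  attr(q, "n_levels") <- 2L
  q
}

test_that("co-occurrence counts and features match the worked 3x3 example", {
  co <- compute_glcm(toy_q(), c(0, 1))
  expect_equal(co$P, matrix(c(1, 0, 2, 3) / 6, 2, 2))
  expect_equal(sum(co$P), 1, tolerance = 1e-12)
  f <- glcm_features(co)
  expect_equal(unname(f["glcm_hom"]), 5 / 6)
  expect_equal(unname(f["glcm_mom1"]), -1 / 3)
  expect_equal(unname(f["glcm_mom2"]), 1 / 3)
  expect_equal(unname(f["glcm_sym"]), 2 / 3)
  expect_equal(unname(f["glcm_con"]), 1 / 3)
})

test_that("point-mass co-occurrence matrices give the degenerate values", {
  q <- matrix(2L, 4, 4); attr(q, "n_levels") <- 3L
  co <- compute_glcm(q, c(0, 1))
  expect_equal(co$P[2, 2], 1)
  f <- glcm_features(co)
  expect_equal(unname(f[c("glcm_hom", "glcm_enr", "glcm_ent", "glcm_con",
                          "glcm_sym", "glcm_mom1", "glcm_mom4")]),
               c(1, 1, 0, 0, 0, 0, 0))
  # zero marginal variance: correlation reported 0, flagged
  expect_equal(unname(f["glcm_cor"]), 0)
  expect_true(isTRUE(attr(f, "degenerate_correlation")))
  expect_error(compute_glcm(q, c(0, 0)), "nonzero")
  expect_error(compute_glcm(q, c(0, 9)), "empty pairs")
})

test_that("run-length matrix enumerates maximal runs in all directions", {
  r <- matrix(as.integer(c(1, 1, 2, 2, 2, 3)), 1, 6)
  attr(r, "n_levels") <- 3L
  rl <- compute_glrlm(r, 0)
  expect_identical(rl$n_runs, 3)
  expect_identical(rl$n_pixels, 6L)
  expect_equal(rl$P[1, 2], 1); expect_equal(rl$P[2, 3], 1)
  expect_equal(rl$P[3, 1], 1)
  f <- glrlm_features(rl)
  expect_equal(unname(f["glrlm_sre"]), 49 / 108)
  expect_equal(unname(f["glrlm_lre"]), 14 / 3)
  expect_equal(unname(f["glrlm_gln"]), 1)
  expect_equal(unname(f["glrlm_rln"]), 1)
  expect_equal(unname(f["glrlm_rp"]), 0.5)
  expect_equal(unname(f["glrlm_lgre"]), 49 / 108)
  expect_equal(unname(f["glrlm_hgre"]), 14 / 3)
  # checkerboard: every run has length 1 in the horizontal direction
  cb <- matrix(1L, 4, 4); cb[(row(cb) + col(cb)) %% 2 == 0] <- 2L
  attr(cb, "n_levels") <- 2L
  expect_identical(compute_glrlm(cb, 0)$n_runs, 16)
  # constant row: single maximal run
  cr <- matrix(1L, 1, 7); attr(cr, "n_levels") <- 2L
  rlc <- compute_glrlm(cr, 0)
  expect_identical(rlc$n_runs, 1)
  fc <- glrlm_features(rlc)
  expect_equal(unname(fc["glrlm_rp"]), 1 / 7)
  expect_equal(unname(fc["glrlm_sre"]), 1 / 49)
  expect_equal(unname(fc["glrlm_lre"]), 49)
})

test_that("difference histogram and features match direct enumeration", {
  r <- matrix(as.integer(c(1, 3, 1, 3)), 1, 4); attr(r, "n_levels") <- 3L
  dh <- compute_glds(r, c(0, 1))
  expect_equal(unname(dh$P_g), c(0, 0, 1))
  cb <- matrix(1L, 4, 4); cb[(row(cb) + col(cb)) %% 2 == 0] <- 2L
  attr(cb, "n_levels") <- 2L
  f <- glds_features(compute_glds(cb, c(0, 1)))
  expect_equal(unname(f), c(1, 1, 1, 0))
  # P_g = {0: .5, 2: .5}
  dh$P_g <- c("0" = 0.5, "1" = 0, "2" = 0.5)
  f2 <- glds_features(dh)
  expect_equal(unname(f2), c(0.5, 2, 1, log(2)))
})

test_that("all three families agree with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:20) {
    nl <- sample(3:8, 1)
    q <- random_quantized(8, 8, nl)
    off <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))[[sample(4, 1)]]
    P <- oracle_glcm(q, nl, off)
    expect_equal(compute_glcm(q, off)$P, P, tolerance = 1e-14)
    expect_equal(glcm_features(compute_glcm(q, off)),
                 oracle_glcm_features(P), tolerance = 1e-10,
                 ignore_attr = TRUE)
    dir <- sample(c(0, 45, 90, 135), 1)
    Pr <- oracle_glrlm(q, nl, dir)
    rl <- compute_glrlm(q, dir)
    expect_equal(rl$P, Pr, tolerance = 0)
    expect_equal(glrlm_features(rl), oracle_glrlm_features(Pr, 64),
                 tolerance = 1e-10)
    d <- c(sample(0:2, 1), sample(0:2, 1))
    if (all(d == 0)) d <- c(1, 1)
    pg <- oracle_glds(q, nl, d)
    dh <- compute_glds(q, d)
    expect_equal(unname(dh$P_g), pg, tolerance = 1e-14)
    expect_equal(glds_features(dh), oracle_glds_features(pg),
                 tolerance = 1e-10)
  }
})

test_that("descriptors are invariant to row permutations for horizontal stats", {
  # permuting whole rows preserves every horizontal pair and run, so all
  # horizontal-direction statistics must be unchanged
  set.seed(17)
  q1 <- random_quantized(6, 6, 4)
  q2 <- q1[sample(6), , drop = FALSE]
  attr(q2, "n_levels") <- 4L
  expect_equal(glcm_features(compute_glcm(q1, c(0, 1))),
               glcm_features(compute_glcm(q2, c(0, 1))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(glrlm_features(compute_glrlm(q1, 0)),
               glrlm_features(compute_glrlm(q2, 0)), tolerance = 1e-12)
  expect_equal(glds_features(compute_glds(q1, c(0, 1))),
               glds_features(compute_glds(q2, c(0, 1))), tolerance = 1e-12)
})

test_that("feature ranges obey their analytic bounds", {
  set.seed(55)
  for (rep in 1:10) {
    q <- random_quantized(12, 12, 6)
    f <- glcm_features(compute_glcm(q, c(0, 1)))
    expect_gt(f[["glcm_enr"]], 0); expect_lte(f[["glcm_enr"]], 1)
    expect_gte(f[["glcm_ent"]], 0)
    expect_gt(f[["glcm_hom"]], 0); expect_lte(f[["glcm_hom"]], 1)
    r <- glrlm_features(compute_glrlm(q, 0))
    expect_lte(r[["glrlm_sre"]], 1)
    expect_gte(r[["glrlm_lre"]], 1)
    expect_gt(r[["glrlm_rp"]], 0); expect_lte(r[["glrlm_rp"]], 1)
    g <- glds_features(compute_glds(q, c(1, 1)))
    expect_gte(g[["glds_men"]], 0)
    expect_lte(g[["glds_men"]], g[["glds_con"]] + 1e-12)
  }
})

test_that("neutrosophic aggregation is an elementwise three-way sum", {
  f <- c(a = 1, b = 2)
  zero <- c(a = 0, b = 0)
  expect_equal(aggregate_ns(f, zero, zero), f)
  g <- c(a = 10, b = 20); h <- c(a = 0.5, b = 0.25)
  expect_equal(aggregate_ns(f, g, h), aggregate_ns(h, f, g))
  expect_equal(aggregate_ns(f, g, h), c(a = 11.5, b = 22.25))
  expect_error(aggregate_ns(f, g, c(a = 1, c = 2)), "name sets")
})

test_that("a one-hot GLCM per channel aggregates homogeneity to 3", {
  q <- matrix(1L, 3, 3); attr(q, "n_levels") <- 2L
  f1 <- glcm_features(compute_glcm(q, c(0, 1)))
  ns <- aggregate_ns(f1, f1, f1)
  expect_equal(unname(ns["glcm_hom"]), 3)
})
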