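# Independent brute-force oracles: plain nested-loop evaluation of the
# texture-descriptor formulas, kept deliberately naive and separate from
# the vectorized package implementations.

oracle_glcm <- function(q, nl, offset) {
  dr <- offset[1]; dc <- offset[2]
  P <- matrix(0, nl, nl)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q))
      P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
  }
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  nl <- nrow(P)
  hom <- enr <- ent <- con <- sym <- 0
  mom <- numeric(4)
  for (i in 1:nl) for (j in 1:nl) {
    p <- P[i, j]
    hom <- hom + p / (1 + (i - j)^2)
    enr <- enr + p^2
    if (p > 0) ent <- ent - p * log(p)
    sym <- sym + abs(P[i, j] - P[j, i])
    for (k in 1:4) mom[k] <- mom[k] + (i - j)^k * p
  }
  for (n in 0:(nl - 1)) {
    s <- 0
    for (i in 1:nl) for (j in 1:nl) if (abs(i - j) == n) s <- s + P[i, j]
    con <- con + n^2 * s
  }
  mux <- muy <- 0
  for (i in 1:nl) for (j in 1:nl) { mux <- mux + i * P[i, j]; muy <- muy + j * P[i, j] }
  sx2 <- sy2 <- 0
  for (i in 1:nl) for (j in 1:nl) {
    sx2 <- sx2 + (i - mux)^2 * P[i, j]; sy2 <- sy2 + (j - muy)^2 * P[i, j]
  }
  cor <- 0
  if (sx2 > 0 && sy2 > 0) {
    s <- 0
    for (i in 1:nl) for (j in 1:nl) s <- s + i * j * P[i, j]
    cor <- (s - mux * muy) / sqrt(sx2 * sy2)
  }
  c(glcm_hom = hom, glcm_enr = enr, glcm_ent = ent, glcm_con = con,
    glcm_sym = sym, glcm_cor = cor, glcm_mom1 = mom[1], glcm_mom2 = mom[2],
    glcm_mom3 = mom[3], glcm_mom4 = mom[4])
}

# enumerate maximal runs along a direction by walking each line
oracle_glrlm <- function(q, nl, direction) {
  h <- nrow(q); w <- ncol(q)
  step <- switch(as.character(direction),
                 "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                 "135" = c(-1, -1))
  starts <- list()
  for (r in 1:h) for (cc in 1:w) {
    pr <- r - step[1]; pc <- cc - step[2]
    if (pr < 1 || pr > h || pc < 1 || pc > w)
      starts[[length(starts) + 1]] <- c(r, cc)
  }
  runs <- list()
  for (s in starts) {
    r <- s[1]; cc <- s[2]
    cur <- q[r, cc]; len <- 0
    while (r >= 1 && r <= h && cc >= 1 && cc <= w) {
      if (q[r, cc] == cur) len <- len + 1
      else {
        runs[[length(runs) + 1]] <- c(cur, len)
        cur <- q[r, cc]; len <- 1
      }
      r <- r + step[1]; cc <- cc + step[2]
    }
    runs[[length(runs) + 1]] <- c(cur, len)
  }
  runs <- do.call(rbind, runs)
  P <- matrix(0, nl, max(runs[, 2]))
  for (k in seq_len(nrow(runs))) P[runs[k, 1], runs[k, 2]] <-
      P[runs[k, 1], runs[k, 2]] + 1
  P
}

oracle_glrlm_features <- function(P, n_pixels) {
  nr <- sum(P)
  sre <- lre <- gln <- rln <- lgre <- hgre <- 0
  for (i in seq_len(nrow(P))) {
    rowsum <- 0
    for (j in seq_len(ncol(P))) {
      p <- P[i, j]
      sre <- sre + p / j^2; lre <- lre + p * j^2
      lgre <- lgre + p / i^2; hgre <- hgre + p * i^2
      rowsum <- rowsum + p
    }
    gln <- gln + rowsum^2
  }
  for (j in seq_len(ncol(P))) {
    colsum <- 0
    for (i in seq_len(nrow(P))) colsum <- colsum + P[i, j]
    rln <- rln + colsum^2
  }
  c(glrlm_sre = sre / nr, glrlm_lre = lre / nr, glrlm_gln = gln / nr,
    glrlm_rp = nr / n_pixels, glrlm_rln = rln / nr,
    glrlm_lgre = lgre / nr, glrlm_hgre = hgre / nr)
}

oracle_glds <- function(q, nl, d) {
  counts <- numeric(nl)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + d[1]; c2 <- cc + d[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      g <- abs(q[r, cc] - q[r2, c2])
      counts[g + 1] <- counts[g + 1] + 1
    }
  }
  counts / sum(counts)
}

oracle_glds_features <- function(pg) {
  asm <- con <- men <- ent <- 0
  for (i in seq_along(pg)) {
    g <- i - 1; p <- pg[i]
    asm <- asm + p^2; con <- con + g^2 * p; men <- men + g * p
    if (p > 0) ent <- ent - p * log(p)
  }
  c(glds_asm = asm, glds_con = con, glds_men = men, glds_ent = ent)
}

# Mann-Whitney pair statistic with ties counted 1/2
oracle_auc_mw <- function(y_pos, scores) {
  pos <- scores[y_pos]; neg <- scores[!y_pos]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# random quantized test image with level attribute
random_quantized <- function(h, w, nl) {
  q <- matrix(sample.int(nl, h * w, replace = TRUE), h, w)
  attr(q, "n_levels") <- as.integer(nl)
  q
}
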