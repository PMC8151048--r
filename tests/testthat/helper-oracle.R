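# Brute-force texture oracles: independent, loop-based enumeration used to
# validate the package's matrix construction and feature formulas. Slow by
# design; only run on tiny volumes.

oracle_dirs13 <- function() {
  out <- NULL
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (dk > 0 || (dk == 0 && dj > 0) || (dk == 0 && dj == 0 && di > 0)) {
      out <- rbind(out, c(di, dj, dk))
    }
  }
  storage.mode(out) <- "integer"
  out
}

in_bounds <- function(v, d) all(v >= 1) && all(v <= d)

oracle_glcm_matrix <- function(levels, ng, dirs = oracle_dirs13()) {
  d <- dim(levels)
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
      a <- levels[i, j, k]
      if (a == 0) next
      v2 <- c(i, j, k) + off
      if (!in_bounds(v2, d)) next
      b <- levels[v2[1], v2[2], v2[3]]
      if (b == 0) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts
}

oracle_glcm_features <- function(levels, ng, dirs = oracle_dirs13()) {
  counts <- oracle_glcm_matrix(levels, ng, dirs)
  p <- counts / sum(counts)
  px <- rowSums(p)
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  acc <- function(f) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j) * p[i, j]
    s
  }
  jvar <- acc(function(i, j) (i - mu)^2)
  pd <- numeric(ng)            # |i-j| = k, k index 0..ng-1
  psum <- numeric(2 * ng - 1)  # i+j = k, k index 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
  }
  kd <- 0:(ng - 1)
  ks <- 2:(2 * ng)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- H(p)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pp <- px[i] * px[j]
    if (p[i, j] > 0 && pp > 0) hxy1 <- hxy1 - p[i, j] * log2(pp)
    if (pp > 0) hxy2 <- hxy2 - pp * log2(pp)
  }
  hx <- H(px)
  da <- sum(kd * pd)
  sa <- sum(ks * psum)
  ivar <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (i != j) ivar <- ivar + p[i, j] / (i - j)^2
  }
  c(cooc_joint_max = max(p),
    cooc_joint_avg = mu,
    cooc_joint_var = jvar,
    cooc_joint_entropy = hxy,
    cooc_diff_avg = da,
    cooc_diff_var = sum((kd - da)^2 * pd),
    cooc_diff_entropy = H(pd),
    cooc_sum_avg = sa,
    cooc_sum_var = sum((ks - sa)^2 * psum),
    cooc_sum_entropy = H(psum),
    cooc_energy = acc(function(i, j) p[i, j]),
    cooc_contrast = acc(function(i, j) (i - j)^2),
    cooc_dissimilarity = acc(function(i, j) abs(i - j)),
    cooc_inv_diff = acc(function(i, j) 1 / (1 + abs(i - j))),
    cooc_inv_diff_norm = acc(function(i, j) 1 / (1 + abs(i - j) / ng)),
    cooc_inv_diff_mom = acc(function(i, j) 1 / (1 + (i - j)^2)),
    cooc_inv_diff_mom_norm = acc(function(i, j) 1 / (1 + (i - j)^2 / ng^2)),
    cooc_inv_var = ivar,
    cooc_correlation = if (jvar > 0)
      (acc(function(i, j) i * j) - mu^2) / jvar else 1,
    cooc_autocorr = acc(function(i, j) i * j),
    cooc_cluster_tendency = acc(function(i, j) (i + j - 2 * mu)^2),
    cooc_cluster_shade = acc(function(i, j) (i + j - 2 * mu)^3),
    cooc_cluster_prominence = acc(function(i, j) (i + j - 2 * mu)^4),
    cooc_info_corr1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    cooc_info_corr2 = if (ng == 1) 0 else
      if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0)
}

# enumerate maximal runs per direction by walking each run once
oracle_runs <- function(levels, dirs = oracle_dirs13()) {
  d <- dim(levels)
  runs <- list()
  for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ]
    for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
      a <- levels[i, j, k]
      if (a == 0) next
      prev <- c(i, j, k) - off
      if (in_bounds(prev, d) && levels[prev[1], prev[2], prev[3]] == a) next
      len <- 1
      cur <- c(i, j, k) + off
      while (in_bounds(cur, d) && levels[cur[1], cur[2], cur[3]] == a) {
        len <- len + 1
        cur <- cur + off
      }
      runs[[length(runs) + 1]] <- c(a, len)
    }
  }
  do.call(rbind, runs)
}

oracle_glrlm_features <- function(levels, ng, dirs = oracle_dirs13()) {
  runs <- oracle_runs(levels, dirs)
  i <- runs[, 1]; l <- runs[, 2]
  nr <- nrow(runs)
  nv <- sum(levels > 0)
  gl_tot <- tapply(rep(1, nr), i, sum)
  rl_tot <- tapply(rep(1, nr), l, sum)
  mu_i <- mean(i); mu_l <- mean(l)
  pcell <- as.numeric(table(paste(i, l))) / nr
  c(rlm_sre = mean(1 / l^2),
    rlm_lre = mean(l^2),
    rlm_lgre = mean(1 / i^2),
    rlm_hgre = mean(i^2),
    rlm_srlge = mean(1 / (i^2 * l^2)),
    rlm_srhge = mean(i^2 / l^2),
    rlm_lrlge = mean(l^2 / i^2),
    rlm_lrhge = mean(i^2 * l^2),
    rlm_glnu = sum(gl_tot^2) / nr,
    rlm_glnu_norm = sum(gl_tot^2) / nr^2,
    rlm_rlnu = sum(rl_tot^2) / nr,
    rlm_rlnu_norm = sum(rl_tot^2) / nr^2,
    rlm_run_pct = nr / (nv * nrow(dirs)),
    rlm_gl_var = mean((i - mu_i)^2),
    rlm_rl_var = mean((l - mu_l)^2),
    rlm_run_entropy = -sum(pcell * log2(pcell)))
}

# flood fill zones of equal level, 26-connectivity
oracle_zones <- function(levels) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  zones <- list()
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (levels[i, j, k] == 0 || seen[i, j, k]) next
    lev <- levels[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        w <- v + c(di, dj, dk)
        if (!in_bounds(w, d)) next
        if (!seen[w[1], w[2], w[3]] &&
            levels[w[1], w[2], w[3]] == lev) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(levels, ng) {
  z <- oracle_zones(levels)
  i <- z[, 1]; s <- z[, 2]
  nz <- nrow(z)
  nv <- sum(levels > 0)
  gl_tot <- tapply(rep(1, nz), i, sum)
  sz_tot <- tapply(rep(1, nz), s, sum)
  pcell <- as.numeric(table(paste(i, s))) / nz
  c(szm_sze = mean(1 / s^2),
    szm_lze = mean(s^2),
    szm_lgze = mean(1 / i^2),
    szm_hgze = mean(i^2),
    szm_szlge = mean(1 / (i^2 * s^2)),
    szm_szhge = mean(i^2 / s^2),
    szm_lzlge = mean(s^2 / i^2),
    szm_lzhge = mean(i^2 * s^2),
    szm_glnu = sum(gl_tot^2) / nz,
    szm_glnu_norm = sum(gl_tot^2) / nz^2,
    szm_zsnu = sum(sz_tot^2) / nz,
    szm_zsnu_norm = sum(sz_tot^2) / nz^2,
    szm_zone_pct = nz / nv,
    szm_gl_var = mean((i - mean(i))^2),
    szm_zs_var = mean((s - mean(s))^2),
    szm_zone_entropy = -sum(pcell * log2(pcell)))
}

oracle_ngtdm_features <- function(levels, ng, cap = 1e6) {
  d <- dim(levels)
  nvec <- numeric(ng); svec <- numeric(ng)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    a <- levels[i, j, k]
    if (a == 0) next
    nb <- c()
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      w <- c(i + di, j + dj, k + dk)
      if (!in_bounds(w, d)) next
      b <- levels[w[1], w[2], w[3]]
      if (b > 0) nb <- c(nb, b)
    }
    if (length(nb)) {
      nvec[a] <- nvec[a] + 1
      svec[a] <- svec[a] + abs(a - mean(nb))
    }
  }
  nvc <- sum(nvec)
  if (nvc == 0) {
    return(c(ngt_coarseness = cap, ngt_contrast = 0, ngt_busyness = 0,
             ngt_complexity = 0, ngt_strength = 0))
  }
  p <- nvec / nvc
  act <- which(p > 0)
  ngp <- length(act)
  ps <- sum(p * svec)
  coarse <- if (ps > 0) min(1 / ps, cap) else cap
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  if (ngp > 1) {
    for (i in act) for (j in act) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p[i] - j * p[j])
      complexity <- complexity +
        abs(i - j) * (p[i] * svec[i] + p[j] * svec[j]) / (p[i] + p[j])
      strength <- strength + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(svec) / nvc
    complexity <- complexity / nvc
    strength <- if (sum(svec) > 0) strength / sum(svec) else 0
  }
  c(ngt_coarseness = coarse,
    ngt_contrast = contrast,
    ngt_busyness = if (ngp > 1 && busy_den > 0) ps / busy_den else 0,
    ngt_complexity = complexity,
    ngt_strength = strength)
}

oracle_texture_features <- function(levels, ng) {
  c(oracle_glcm_features(levels, ng),
    oracle_glrlm_features(levels, ng),
    oracle_glszm_features(levels, ng),
    oracle_ngtdm_features(levels, ng))
}

# pairwise-concordance AUC with 0.5 credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exhaustive Youden maximum over all candidate thresholds
oracle_best_youden <- function(scores, labels) {
  su <- sort(unique(scores))
  cand <- c(su - 1e-9, su + 1e-9)
  best <- -Inf
  for (t in cand) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}
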