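#' Grey-level co-occurrence (GLCM) features
#'
#' Co-occurrence is accumulated symmetrically over the 13 unique 3D
#' directions at Chebyshev distance 1, merged into a single matrix and
#' normalized ("merged" aggregation). 25 features are returned.
#'
#' A ROI with no valid voxel pair (e.g. a single isolated voxel) is handled
#' by the documented fallback: the matrix is taken as a point mass at the
#' modal grey level, which yields the same values as a uniform ROI
#' (energy 1, entropies 0, correlation 1, ...), and the result is flagged
#' with attribute `degenerate = TRUE`.
#'
#' @param glv A `grey_level_volume` from [discretize_fbw()].
#' @param dirs Integer matrix of direction offsets; defaults to all 13.
#' @return Named numeric vector of 25 `cooc_*` features.
#' @export
glcm_features <- function(glv, dirs = texture_directions()) {
  counts <- cpp_glcm_counts(glv$levels, glv$ng, dirs)
  degenerate <- FALSE
  if (sum(counts) == 0) {
    degenerate <- TRUE
    lv <- glv$levels[glv$levels > 0]
    g <- as.integer(names(which.max(table(lv))))
    counts[g, g] <- 1
  }
  p <- counts / sum(counts)
  ng <- glv$ng
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)                       # joint average (symmetric)
  joint_var <- sum((i - mu)^2 * p)

  # diagonal (difference) and cross-diagonal (sum) marginals
  kd <- 0:(ng - 1)
  p_diff <- numeric(ng)
  pd <- rowsum(as.vector(p), as.vector(abs(i - j)))
  p_diff[as.integer(rownames(pd)) + 1] <- pd[, 1]
  ks <- 2:(2 * ng)
  p_sum <- numeric(2 * ng - 1)
  ps <- rowsum(as.vector(p), as.vector(i + j))
  p_sum[as.integer(rownames(ps)) - 1] <- ps[, 1]

  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  hxy <- ent(p)
  pxy_prod <- outer(px, px)
  sel <- p > 0 & pxy_prod > 0
  hxy1 <- -sum(p[sel] * log2(pxy_prod[sel]))
  hxy2 <- ent(pxy_prod)
  hx <- ent(px)

  diff_avg <- sum(kd * p_diff)
  sum_avg <- sum(ks * p_sum)

  corr <- if (joint_var > 0) (sum(i * j * p) - mu^2) / joint_var else 1
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  if (ng == 1 || degenerate) ic2 <- 0

  out <- c(
    cooc_joint_max = max(p),
    cooc_joint_avg = mu,
    cooc_joint_var = joint_var,
    cooc_joint_entropy = hxy,
    cooc_diff_avg = diff_avg,
    cooc_diff_var = sum((kd - diff_avg)^2 * p_diff),
    cooc_diff_entropy = ent(p_diff),
    cooc_sum_avg = sum_avg,
    cooc_sum_var = sum((ks - sum_avg)^2 * p_sum),
    cooc_sum_entropy = ent(p_sum),
    cooc_energy = sum(p^2),
    cooc_contrast = sum((i - j)^2 * p),
    cooc_dissimilarity = sum(abs(i - j) * p),
    cooc_inv_diff = sum(p / (1 + abs(i - j))),
    cooc_inv_diff_norm = sum(p / (1 + abs(i - j) / ng)),
    cooc_inv_diff_mom = sum(p / (1 + (i - j)^2)),
    cooc_inv_diff_mom_norm = sum(p / (1 + (i - j)^2 / ng^2)),
    cooc_inv_var = sum((p / pmax((i - j)^2, 1))[i != j]),
    cooc_correlation = corr,
    cooc_autocorr = sum(i * j * p),
    cooc_cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    cooc_cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cooc_cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    cooc_info_corr1 = ic1,
    cooc_info_corr2 = ic2
  )
  structure(out, degenerate = degenerate)
}

#' Grey-level run-length (GLRLM) features
#'
#' Runs are maximal straight segments of equal grey level along a direction;
#' voxels outside the ROI break runs. Matrices from the 13 directions are
#' merged by summation. 16 features are returned.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 `rlm_*` features.
#' @export
glrlm_features <- function(glv, dirs = texture_directions()) {
  rmat <- cpp_glrlm_counts(glv$levels, glv$ng, dirs)
  nr <- sum(rmat)
  nv <- sum(glv$levels > 0)
  i <- row(rmat); l <- col(rmat)
  p <- rmat / nr
  mu_i <- sum(i * p)
  mu_l <- sum(l * p)
  pr <- p[p > 0]
  c(
    rlm_sre = sum(rmat / l^2) / nr,
    rlm_lre = sum(rmat * l^2) / nr,
    rlm_lgre = sum(rmat / i^2) / nr,
    rlm_hgre = sum(rmat * i^2) / nr,
    rlm_srlge = sum(rmat / (i^2 * l^2)) / nr,
    rlm_srhge = sum(rmat * i^2 / l^2) / nr,
    rlm_lrlge = sum(rmat * l^2 / i^2) / nr,
    rlm_lrhge = sum(rmat * i^2 * l^2) / nr,
    rlm_glnu = sum(rowSums(rmat)^2) / nr,
    rlm_glnu_norm = sum(rowSums(rmat)^2) / nr^2,
    rlm_rlnu = sum(colSums(rmat)^2) / nr,
    rlm_rlnu_norm = sum(colSums(rmat)^2) / nr^2,
    rlm_run_pct = nr / (nv * nrow(dirs)),
    rlm_gl_var = sum((i - mu_i)^2 * p),
    rlm_rl_var = sum((l - mu_l)^2 * p),
    rlm_run_entropy = -sum(pr * log2(pr))
  )
}

#' Grey-level size-zone (GLSZM) features
#'
#' Zones are 26-connected components of equal grey level; a single matrix is
#' built for the whole volume. 16 features are returned, including zone-size
#' non-uniformity (ZSNU), high grey level zone emphasis (HGLZE) and grey
#' level non-uniformity (GLNU).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 `szm_*` features.
#' @export
glszm_features <- function(glv) {
  z <- cpp_glszm_zones(glv$levels, glv$ng)
  i <- z$level
  s <- z$size
  nz <- length(i)
  nv <- sum(glv$levels > 0)
  # marginal sums over zones sharing a level / a size
  gl_sum <- tapply(rep(1, nz), i, sum)
  sz_sum <- tapply(rep(1, nz), s, sum)
  p <- rep(1 / nz, nz)
  mu_i <- sum(i * p)
  mu_s <- sum(s * p)
  # zone-count probabilities per distinct (level, size) cell
  cell <- table(paste(i, s))
  pc <- as.numeric(cell) / nz
  c(
    szm_sze = sum(1 / s^2) / nz,
    szm_lze = sum(s^2) / nz,
    szm_lgze = sum(1 / i^2) / nz,
    szm_hgze = sum(i^2) / nz,
    szm_szlge = sum(1 / (i^2 * s^2)) / nz,
    szm_szhge = sum(i^2 / s^2) / nz,
    szm_lzlge = sum(s^2 / i^2) / nz,
    szm_lzhge = sum(i^2 * s^2) / nz,
    szm_glnu = sum(gl_sum^2) / nz,
    szm_glnu_norm = sum(gl_sum^2) / nz^2,
    szm_zsnu = sum(sz_sum^2) / nz,
    szm_zsnu_norm = sum(sz_sum^2) / nz^2,
    szm_zone_pct = nz / nv,
    szm_gl_var = sum((i - mu_i)^2 * p),
    szm_zs_var = sum((s - mu_s)^2 * p),
    szm_zone_entropy = -sum(pc * log2(pc))
  )
}

#' Neighbourhood grey-tone difference (NGTDM) features
#'
#' For each grey level \eqn{i}, \eqn{s_i} sums, over ROI voxels of level
#' \eqn{i}, the absolute difference between \eqn{i} and the mean level of
#' the voxel's valid 26-neighbourhood. Coarseness is capped at `1e6` when
#' \eqn{\sum p_i s_i = 0} (perfectly uniform ROI).
#'
#' @inheritParams glcm_features
#' @param coarseness_cap Value returned for coarseness on a uniform ROI.
#' @return Named numeric vector of 5 `ngt_*` features.
#' @export
ngtdm_features <- function(glv, coarseness_cap = 1e6) {
  st <- cpp_ngtdm_stats(glv$levels, glv$ng)
  nvec <- st$n
  svec <- st$s
  nvc <- sum(nvec)
  lev <- seq_len(glv$ng)
  if (nvc == 0) {
    return(c(ngt_coarseness = coarseness_cap, ngt_contrast = 0,
             ngt_busyness = 0, ngt_complexity = 0, ngt_strength = 0))
  }
  p <- nvec / nvc
  act <- p > 0
  ngp <- sum(act)
  pi_ <- p[act]; si <- svec[act]; li <- lev[act]

  ps <- sum(pi_ * si)
  coarse <- if (ps > 0) min(1 / ps, coarseness_cap) else coarseness_cap

  if (ngp > 1) {
    dif2 <- outer(li, li, function(a, b) (a - b)^2)
    ppij <- outer(pi_, pi_)
    contrast <- sum(ppij * dif2) / (ngp * (ngp - 1)) * sum(svec) / nvc
    busy_den <- sum(abs(outer(li * pi_, li * pi_, "-")))
    busyness <- if (busy_den > 0) ps / busy_den else 0
    absdif <- outer(li, li, function(a, b) abs(a - b))
    psi <- pi_ * si
    complexity <- sum(absdif * (outer(psi, rep(1, ngp)) +
                                outer(rep(1, ngp), psi)) /
                      (outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_))) / nvc
    s_all <- sum(svec)
    strength <- if (s_all > 0) {
      sum((outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_)) * dif2) / s_all
    } else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngt_coarseness = coarse, ngt_contrast = contrast, ngt_busyness = busyness,
    ngt_complexity = complexity, ngt_strength = strength)
}
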