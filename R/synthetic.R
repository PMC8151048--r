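#' Generate a synthetic EBRT-like dose grid
#'
#' Produces a smooth non-negative dose field whose in-field plateau sits at
#' the prescription dose with a small multiplicative jitter (default ±2%,
#' smooth at scale `smoothness` mm), plus optional Gaussian hotspots. This
#' emulates a pelvic external-beam plan at 45-50.4 Gy with localized
#' overdosage; it makes no claim of anatomical realism.
#'
#' @param shape 3 positive integers (voxels per axis).
#' @param spacing 3 positive voxel spacings (mm).
#' @param prescription Prescription dose in Gy, in \[30, 60\].
#' @param hotspot_spec List of hotspots, each
#'   `list(center = c(x, y, z) mm, radius = r mm, peak = Gy)`; peaks must
#'   not exceed 1.2 x prescription. A hotspot adds a Gaussian bump
#'   (sd = radius/2) whose centre reaches `peak`.
#' @param smoothness Correlation length (mm) of the plateau jitter;
#'   `Inf` disables jitter entirely.
#' @param jitter Relative jitter amplitude (sd as fraction of prescription).
#' @param origin World coordinate of the first voxel centre (mm).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   grids.
#' @return A [dose_grid()].
#' @export
gen_dose_grid <- function(shape, spacing, prescription = 45,
                          hotspot_spec = list(), smoothness = 15,
                          jitter = 0.02, origin = c(0, 0, 0), seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0)) {
    abort("`shape` must be 3 positive integers.",
          class = "dosiomics_invalid_argument")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive lengths.",
          class = "dosiomics_invalid_argument")
  }
  if (prescription < 30 || prescription > 60) {
    abort("`prescription` must lie in [30, 60] Gy.",
          class = "dosiomics_invalid_argument")
  }
  peaks <- vapply(hotspot_spec, function(h) h$peak, numeric(1))
  if (any(peaks > 1.2 * prescription + 1e-9)) {
    abort("hotspot peaks must not exceed 1.2 x prescription.",
          class = "dosiomics_invalid_argument")
  }
  values <- withr::with_seed(seed, {
    v <- array(prescription, shape)
    if (is.finite(smoothness) && jitter > 0) {
      noise <- array(rnorm(prod(shape)), shape)
      noise <- smooth_gaussian(noise, smoothness / spacing)
      s <- sd(noise)
      if (s > 0) noise <- noise / s
      v <- v * (1 + jitter * noise)
    }
    if (length(hotspot_spec)) {
      co <- voxel_centers(shape, spacing, origin)
      for (h in hotspot_spec) {
        sig <- h$radius / 2
        d2 <- (co$x - h$center[1])^2
        d2 <- outer(d2, (co$y - h$center[2])^2, "+")
        d2 <- outer(d2, (co$z - h$center[3])^2, "+")
        v <- v + (h$peak - prescription) * exp(-d2 / (2 * sig^2))
      }
    }
    pmax(v, 0)
  })
  dose_grid(values, spacing, origin)
}

voxel_centers <- function(shape, spacing, origin) {
  list(x = origin[1] + (seq_len(shape[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(shape[3]) - 1) * spacing[3])
}

# Separable Gaussian smoothing; sigma in voxels per axis.
smooth_gaussian <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dim(a)[ax]
    half <- min(n - 1, max(1L, ceiling(3 * s)))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    # banded smoothing matrix, truncated at the boundary and renormalized
    sm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - half):min(n, i + half)
      w <- k[j - i + half + 1]
      sm[i, j] <- w / sum(w)
    }
    a <- apply_along(a, ax, sm)
  }
  a
}

apply_along <- function(a, ax, sm) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[ax])
  m <- sm %*% m
  ap <- array(m, dim(ap))
  aperm(ap, order(perm))
}

#' Generate a synthetic organ-at-risk mask
#'
#' Organ archetypes differ by label: rectum and vagina are tubular (a disk
#' swept along a smoothed random centerline in z), the bladder a randomly
#' anisotropic ellipsoid. The realized volume is within ±20% of
#' `target_volume` and the mask is a single 26-connected component.
#'
#' @inheritParams gen_dose_grid
#' @param organ_label `"rectum"`, `"bladder"` or `"vagina"`.
#' @param target_volume Target organ volume in cc.
#' @return An [organ_mask()].
#' @export
gen_organ_mask <- function(shape, spacing, organ_label = "rectum",
                           target_volume = 50, origin = c(0, 0, 0),
                           seed = 1) {
  shape <- as.integer(shape)
  extent <- shape * spacing
  grid_cc <- prod(extent) / 1000
  if (target_volume > 0.5 * grid_cc) {
    abort("`target_volume` too large for the grid.",
          class = "dosiomics_invalid_argument")
  }
  ind <- withr::with_seed(seed, {
    if (organ_label %in% c("rectum", "vagina")) {
      tube_mask(shape, spacing, target_volume)
    } else {
      blob_mask(shape, spacing, target_volume)
    }
  })
  organ_mask(ind, spacing, origin, organ_label)
}

tube_mask <- function(shape, spacing, target_volume) {
  ext <- shape * spacing
  len <- 0.7 * ext[3]
  r <- sqrt(target_volume * 1000 / (pi * len))
  rcap <- 0.30 * min(ext[1], ext[2])
  if (r > rcap) {
    len <- min(0.9 * ext[3], target_volume * 1000 / (pi * rcap^2))
    r <- sqrt(target_volume * 1000 / (pi * len))
    if (r > 0.45 * min(ext[1], ext[2])) {
      abort("`target_volume` not achievable with a tubular organ.",
            class = "dosiomics_invalid_argument")
    }
  }
  z0 <- (ext[3] - len) / 2
  zc <- (seq_len(shape[3]) - 1) * spacing[3]
  inz <- zc >= z0 & zc <= z0 + len
  # smoothed random-walk centerline in (x, y)
  nz <- shape[3]
  wob <- cbind(cumsum(rnorm(nz, 0, 0.5)), cumsum(rnorm(nz, 0, 0.5)))
  wob <- apply(wob, 2, function(w) stats::filter(w, rep(1 / 5, 5),
                                                 sides = 2))
  wob[is.na(wob)] <- 0
  cx <- ext[1] / 2 + wob[, 1] - mean(wob[, 1])
  cy <- ext[2] / 2 + wob[, 2] - mean(wob[, 2])
  cx <- pmin(pmax(cx, r + spacing[1]), ext[1] - r - spacing[1])
  cy <- pmin(pmax(cy, r + spacing[2]), ext[2] - r - spacing[2])
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2]
  ind <- array(FALSE, shape)
  for (k in which(inz)) {
    d2 <- outer((xs - cx[k])^2, (ys - cy[k])^2, "+")
    ind[, , k] <- d2 <= r^2
  }
  ind
}

blob_mask <- function(shape, spacing, target_volume) {
  ext <- shape * spacing
  r0 <- (3 * target_volume * 1000 / (4 * pi))^(1 / 3)
  f <- runif(3, 0.8, 1.25)
  f <- f / prod(f)^(1 / 3)           # volume-preserving anisotropy
  ax <- r0 * f
  if (any(2 * ax > 0.95 * ext)) {
    abort("`target_volume` not achievable with a blob organ.",
          class = "dosiomics_invalid_argument")
  }
  ctr <- ext / 2 + runif(3, -0.05, 0.05) * ext
  ctr <- pmin(pmax(ctr, ax + spacing), ext - ax - spacing)
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2]
  zs <- (seq_len(shape[3]) - 1) * spacing[3]
  d2 <- outer(((xs - ctr[1]) / ax[1])^2, ((ys - ctr[2]) / ax[2])^2, "+")
  d2 <- outer(d2, ((zs - ctr[3]) / ax[3])^2, "+")
  d2 <= 1
}

#' Generate a synthetic brachytherapy DVH
#'
#' Emulates the steep dose falloff of intracavitary HDR brachytherapy
#' around a 7 Gy x 3-4 fraction prescription: the dose at volume fraction
#' u is \eqn{D_{max} (1-u)^{s}} with falloff exponent `falloff_scale` and
#' \eqn{D_{max}} drawn near the total prescription (at most 1.5 x). A
#' falloff of 0 degenerates to a uniform (step) DVH.
#'
#' @param prescription_per_fraction Prescribed dose per fraction (Gy).
#' @param n_fractions 3 or 4.
#' @param falloff_scale Non-negative falloff exponent (dimensionless).
#' @param organ_volume Organ volume in cc.
#' @param n_points Number of pseudo-voxels used to tabulate the curve.
#' @param edge_step Output tabulation step (Gy).
#' @param seed Integer seed.
#' @return A `dvh_curve`.
#' @export
gen_bt_dvh <- function(prescription_per_fraction = 7, n_fractions = 3,
                       falloff_scale = 3, organ_volume = 50,
                       n_points = 1000, edge_step = 0.1, seed = 1) {
  if (!n_fractions %in% c(3, 4)) {
    abort("`n_fractions` must be 3 or 4.",
          class = "dosiomics_invalid_argument")
  }
  if (prescription_per_fraction <= 0) {
    abort("`prescription_per_fraction` must be positive.",
          class = "dosiomics_invalid_argument")
  }
  total <- n_fractions * prescription_per_fraction
  withr::with_seed(seed, {
    dmax <- total * runif(1, 0.9, 1.45)
    u <- (seq_len(n_points) - 0.5) / n_points
    ds <- sort(dmax * (1 - u)^falloff_scale)
    edges <- seq(0, (floor(max(ds) / edge_step) + 1) * edge_step,
                 by = edge_step)
    below <- findInterval(edges, ds, left.open = TRUE)
    vf <- (n_points - below) / n_points
    dvh_curve(edges, vf, total_volume = organ_volume,
              voxel_volume = organ_volume / n_points)
  })
}

#' Planted outcome model for synthetic cohorts
#'
#' Ground truth for parameter-recovery simulations: a logistic model on
#' standardized (cohort z-scored) feature values, so planted effect sizes
#' are scale-free.
#'
#' @param endpoint One of the six endpoint labels
#'   (`"rectal_acute"`, `"rectal_late"`, `"gu_acute"`, `"gu_late"`,
#'   `"vaginal_acute"`, `"vaginal_late"`).
#' @param intercept Intercept on the logit scale.
#' @param coefficients Named numeric vector: logit change per standardized
#'   unit of the named feature columns (may be empty for an intercept-only
#'   endpoint).
#' @return A `planted_model` object.
#' @export
planted_model <- function(endpoint, intercept,
                          coefficients = numeric(0)) {
  endpoint <- match.arg(endpoint, endpoint_labels())
  structure(list(endpoint = endpoint, intercept = intercept,
                 coefficients = coefficients),
            class = "planted_model")
}

#' @rdname run_endpoint_analysis
#' @export
endpoint_labels <- function() {
  c("rectal_acute", "rectal_late", "gu_acute", "gu_late",
    "vaginal_acute", "vaginal_late")
}

endpoint_organ <- function(endpoint) {
  c(rectal = "rectum", gu = "bladder", vaginal = "vagina")[
    sub("_(acute|late)$", "", endpoint)]
}

# Default grade >= 2 toxicity prevalences used for intercept-only endpoints
# (training-cohort rates of a two-centre LACC chemoradiotherapy series).
default_prevalence <- function() {
  c(gu_acute = 0.39, gu_late = 0.14, rectal_acute = 0.26, rectal_late = 0.10,
    vaginal_acute = 0.24, vaginal_late = 0.24)
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles the geometry and dosimetry settings used by [gen_cohort()]. The
#' defaults emulate the study conditions of a two-centre locally advanced
#' cervical cancer series: EBRT prescriptions drawn in 45-50.4 Gy with 0-3
#' hotspots per organ peaking at up to 1.2 x prescription, ±2% plateau
#' jitter, BT at 7 Gy x 3-4 fractions, and organ volumes of roughly 60 cc
#' (rectum), 180 cc (bladder) and 40 cc (vagina).
#'
#' @param shape,spacing Grid geometry (voxels, mm).
#' @param organs Organs to synthesize; may be empty (clinical covariates
#'   and outcomes only).
#' @param target_volumes Named organ volumes (cc).
#' @param prescription_range EBRT prescription range (Gy).
#' @param n_hotspots_max Maximum hotspots per organ (drawn uniformly from
#'   0..max).
#' @param hotspot_radius_range Hotspot radius range (mm).
#' @param smoothness,jitter Plateau jitter parameters (see
#'   [gen_dose_grid()]).
#' @param bt_prescription,bt_falloff_range BT per-fraction dose (Gy) and
#'   falloff exponent range.
#' @param bin_width Radiomics discretization width (Gy).
#' @param include_dvh Compute DVH/EQD2 metric columns (slower; needed for
#'   DVH-family modelling).
#' @param edge_step DVH tabulation step (Gy).
#' @param covariate_shift Relative mean shift applied to the testing split's
#'   clinical covariates (emulates a second centre).
#' @return A list of settings.
#' @export
cohort_config <- function(shape = c(48, 48, 48), spacing = c(2.5, 2.5, 2.5),
                          organs = c("rectum", "bladder", "vagina"),
                          target_volumes = c(rectum = 60, bladder = 180,
                                             vagina = 40),
                          prescription_range = c(45, 50.4),
                          n_hotspots_max = 3,
                          hotspot_radius_range = c(8, 20),
                          smoothness = 15, jitter = 0.02,
                          bt_prescription = 7,
                          bt_falloff_range = c(2, 5),
                          bin_width = 1,
                          include_dvh = TRUE, edge_step = 0.1,
                          covariate_shift = 0.05) {
  as.list(environment())
}

gen_clinical <- function(n, shift = 0) {
  stages <- c(1, 1.5, 2, 2.5, 3, 3.5, 4)
  tibble(
    figo_stage = sample(stages, n, replace = TRUE,
                        prob = c(.08, .07, .25, .20, .20, .10, .10)),
    age = pmin(pmax(rnorm(n, 54 * (1 + shift), 11), 18), 100),
    baseline_symptoms = rbinom(n, 1, min(.30 * (1 + shift), 1)),
    prior_abdominal_surgery = rbinom(n, 1, min(.25 * (1 + shift), 1)),
    rectal_comorbidities = rbinom(n, 1, min(.15 * (1 + shift), 1)),
    tnm_n_positive = rbinom(n, 1, min(.45 * (1 + shift), 1))
  )
}

#' Generate a complete synthetic cohort
#'
#' For every patient: clinical covariates, per-organ dose grids and masks,
#' radiomic feature extraction (`RA_<organ>_*` columns), optional DVH/EQD2
#' metric columns (`DVH_<organ>_*`), a BT DVH per organ, and six binary
#' toxicity endpoints. The endpoint named in `planted` is drawn
#' Bernoulli(expit(intercept + sum beta_k z_k)) on split-wise standardized
#' feature values; all other endpoints are intercept-only at the default
#' prevalences. The testing split is generated from a shifted seed stream
#' with a +5% covariate mean shift, emulating a second centre.
#'
#' @param n_patients Total cohort size (>= 10).
#' @param planted A [planted_model()], or `NULL` for all-intercept-only
#'   outcomes.
#' @param config A [cohort_config()].
#' @param seed Integer seed; the full cohort is a pure function of
#'   (arguments, seed).
#' @param n_test Patients in the testing split (default: 49% of the cohort,
#'   i.e. 50 of 102).
#' @return An object of class `dosio_cohort`: list with `table` (tibble,
#'   one row per patient), `bt_dvhs`, `planted`, `config`.
#' @export
gen_cohort <- function(n_patients = 102, planted = NULL,
                       config = cohort_config(), seed = 1,
                       n_test = round(0.49 * n_patients)) {
  if (n_patients < 10) {
    abort("`n_patients` must be at least 10.",
          class = "dosiomics_invalid_argument")
  }
  n_train <- n_patients - n_test
  train <- withr::with_seed(seed, {
    gen_split(n_train, config, shift = 0, id_offset = 0)
  })
  test <- if (n_test > 0) {
    withr::with_seed(seed + 131071L, {
      gen_split(n_test, config, shift = config$covariate_shift,
                id_offset = n_train)
    })
  } else NULL
  tab <- dplyr::bind_rows(
    dplyr::mutate(train$table, split = "training", .after = "id"),
    if (!is.null(test)) dplyr::mutate(test$table, split = "testing",
                                      .after = "id")
  )
  # outcomes
  tab <- withr::with_seed(seed + 262143L, {
    draw_outcomes(tab, planted)
  })
  structure(list(table = tab,
                 bt_dvhs = c(train$bt_dvhs, if (!is.null(test))
                             test$bt_dvhs),
                 planted = planted, config = config),
            class = "dosio_cohort")
}

gen_split <- function(n, config, shift, id_offset) {
  clin <- gen_clinical(n, shift)
  ebrt_fx <- function(presc) round(presc / 1.8)
  rows <- vector("list", n)
  bt_store <- list()
  for (p in seq_len(n)) {
    presc <- runif(1, config$prescription_range[1],
                   config$prescription_range[2])
    rec <- list(id = sprintf("P%04d", id_offset + p))
    for (org in config$organs) {
      mseed <- sample.int(.Machine$integer.max - 1L, 1)
      gseed <- sample.int(.Machine$integer.max - 1L, 1)
      mask <- gen_organ_mask(config$shape, config$spacing, org,
                             config$target_volumes[[org]], seed = mseed)
      nh <- sample(0:config$n_hotspots_max, 1)
      hs <- list()
      if (nh > 0) {
        vox <- which(mask, arr.ind = TRUE)
        pick <- vox[sample.int(nrow(vox), nh, replace = TRUE), ,
                    drop = FALSE]
        for (hi in seq_len(nh)) {
          hs[[hi]] <- list(
            center = (pick[hi, ] - 1) * config$spacing,
            radius = runif(1, config$hotspot_radius_range[1],
                           config$hotspot_radius_range[2]),
            peak = presc * runif(1, 1.02, 1.2))
        }
      }
      dose <- gen_dose_grid(config$shape, config$spacing, presc, hs,
                            config$smoothness, config$jitter, seed = gseed)
      fv <- extract_feature_vector(dose, mask, config$bin_width)
      names(fv) <- paste0("RA_", org, "_", names(fv))
      rec <- c(rec, as.list(fv))
      bt_fracs <- sample(3:4, 1)
      bt <- gen_bt_dvh(config$bt_prescription, bt_fracs,
                       runif(1, config$bt_falloff_range[1],
                             config$bt_falloff_range[2]),
                       organ_volume = mask_volume_cc(mask),
                       seed = sample.int(.Machine$integer.max - 1L, 1))
      bt$organ_label <- org
      bt_store[[paste0(rec$id, "_", org)]] <- bt
      if (config$include_dvh) {
        dm <- organ_dvh_metrics(dose, mask, bt, bt_fracs,
                                ebrt_fx(presc), config$edge_step)
        names(dm) <- paste0("DVH_", org, "_", names(dm))
        rec <- c(rec, as.list(dm))
      }
    }
    rows[[p]] <- as_tibble(rec)
  }
  tab <- dplyr::bind_cols(
    dplyr::bind_rows(rows)[, "id", drop = FALSE],
    clin,
    dplyr::select(dplyr::bind_rows(rows), -"id")
  )
  list(table = tab, bt_dvhs = bt_store)
}

# EBRT physical metrics plus EQD2-summed EBRT+BT metrics at alpha/beta 10
# (acute) and 3 (late).
organ_dvh_metrics <- function(dose, mask, bt_dvh, bt_fracs, ebrt_fracs,
                              edge_step) {
  ebrt <- compute_dvh(dose, mask, edge_step)
  m1 <- dvh_to_metrics(ebrt, seq(5, 55, by = 5))
  out <- setNames(m1$value, paste0(m1$metric, "_EBRT"))
  for (ab in c(10, 3)) {
    ea <- eqd2_dvh(ebrt, ebrt_fracs, ab)
    ba <- eqd2_dvh(bt_dvh, bt_fracs, ab)
    sm <- sum_dvh_hotspot_aligned(ea, ba, n_points = 500,
                                  edge_step = edge_step)
    m2 <- dvh_to_metrics(sm, seq(5, 140, by = 5))
    out <- c(out, setNames(m2$value,
                           paste0(m2$metric, "_EBRTBT_ab", ab)))
  }
  out
}

draw_outcomes <- function(tab, planted) {
  prev <- default_prevalence()
  n <- nrow(tab)
  for (ep in endpoint_labels()) {
    if (!is.null(planted) && planted$endpoint == ep &&
        length(planted$coefficients) > 0) {
      feats <- names(planted$coefficients)
      missing <- setdiff(feats, names(tab))
      if (length(missing)) {
        abort(paste0("planted feature(s) not computable: ",
                     paste(missing, collapse = ", ")),
              class = "dosiomics_config_error")
      }
      eta <- rep(planted$intercept, n)
      for (sp in unique(tab$split)) {
        idx <- tab$split == sp
        for (f in feats) {
          z <- scale(tab[[f]][idx])[, 1]
          z[is.na(z)] <- 0
          eta[idx] <- eta[idx] + planted$coefficients[[f]] * z
        }
      }
      tab[[ep]] <- rbinom(n, 1, plogis(eta))
    } else if (!is.null(planted) && planted$endpoint == ep) {
      tab[[ep]] <- rbinom(n, 1, plogis(planted$intercept))
    } else {
      tab[[ep]] <- rbinom(n, 1, prev[[ep]])
    }
  }
  tab
}

#' Redraw the toxicity outcomes of a cohort
#'
#' Keeps the generated design (covariates, dose features) fixed and redraws
#' the six endpoints from the same planted/intercept-only models under a
#' new seed. Used for outcome-randomness simulations (e.g. coverage of
#' planted-coefficient confidence intervals conditional on the design).
#'
#' @param cohort A `dosio_cohort`.
#' @param seed Integer seed for the outcome draw.
#' @return The cohort with new endpoint columns.
#' @export
redraw_outcomes <- function(cohort, seed) {
  cohort$table <- withr::with_seed(seed, {
    draw_outcomes(cohort$table, cohort$planted)
  })
  cohort
}

#' @export
print.dosio_cohort <- function(x, ...) {
  cat("<dosio_cohort> ", nrow(x$table), " patients (",
      sum(x$table$split == "training"), " training / ",
      sum(x$table$split == "testing"), " testing), ",
      ncol(x$table), " columns\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' The patient table goes to `cohort.csv`; each stored BT DVH to
#' `bt_dvh/<id>_<organ>.csv`.
#'
#' @param cohort A `dosio_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_table(cohort$table, file.path(dir, "cohort.csv"))
  if (length(cohort$bt_dvhs)) {
    bd <- file.path(dir, "bt_dvh")
    dir.create(bd, showWarnings = FALSE)
    for (nm in names(cohort$bt_dvhs)) {
      write_dvh(cohort$bt_dvhs[[nm]], file.path(bd, paste0(nm, ".csv")))
    }
  }
  invisible(dir)
}
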