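#' Construct a cumulative DVH curve
#'
#' @param dose_edges Increasing dose values (Gy) at which the curve is
#'   tabulated; must start at 0.
#' @param volume_fraction Fraction of the organ receiving at least each edge
#'   dose; non-increasing, starting at 1.
#' @param total_volume Organ volume in cc.
#' @param voxel_volume Volume of one voxel (cc), if the curve came from a
#'   voxel grid.
#' @param organ_label Optional organ name carried through summation checks.
#' @return A `dvh_curve` object.
#' @export
dvh_curve <- function(dose_edges, volume_fraction, total_volume,
                      voxel_volume = NA_real_, organ_label = NA_character_) {
  dose_edges <- as.numeric(dose_edges)
  volume_fraction <- as.numeric(volume_fraction)
  if (length(dose_edges) != length(volume_fraction)) {
    abort("edges and fractions must have equal length.",
          class = "dosiomics_invalid_argument")
  }
  if (is.unsorted(dose_edges, strictly = TRUE)) {
    abort("`dose_edges` must be strictly increasing.",
          class = "dosiomics_invalid_argument")
  }
  if (any(diff(volume_fraction) > 1e-12)) {
    abort("`volume_fraction` must be non-increasing.",
          class = "dosiomics_invalid_argument")
  }
  if (abs(dose_edges[1]) > 1e-9 || abs(volume_fraction[1] - 1) > 1e-9) {
    abort("curve must start at (0 Gy, fraction 1).",
          class = "dosiomics_invalid_argument")
  }
  structure(
    list(dose_edges = dose_edges, volume_fraction = volume_fraction,
         total_volume = total_volume, voxel_volume = voxel_volume,
         organ_label = organ_label),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("<dvh_curve> ", if (!is.na(x$organ_label)) paste0(x$organ_label, ", "),
      signif(x$total_volume, 4), " cc, edges 0-",
      max(x$dose_edges), " Gy\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.dvh_curve <- function(x, ...) {
  tibble(dose_gy = x$dose_edges, volume_fraction = x$volume_fraction)
}

#' Compute the cumulative DVH of a dose grid inside a mask
#'
#' `volume_fraction(d)` is the fraction of in-mask voxels with dose `>= d`,
#' tabulated on edges `0, edge_step, 2 edge_step, ...` up to just above the
#' maximum dose.
#'
#' @param dose A [dose_grid()].
#' @param mask An [organ_mask()] on the same lattice.
#' @param edge_step Dose bin width of the curve tabulation (Gy).
#' @return A `dvh_curve`.
#' @export
compute_dvh <- function(dose, mask, edge_step = 0.1) {
  check_aligned(dose, mask)
  ds <- sort(as.numeric(dose[mask]))
  n <- length(ds)
  if (n == 0) abort("empty ROI.", class = "dosiomics_empty_roi")
  edges <- seq(0, (floor(max(ds) / edge_step) + 1) * edge_step, by = edge_step)
  # count of doses < e, exact on the sorted vector
  below <- findInterval(edges, ds, left.open = TRUE)
  vf <- (n - below) / n
  vox <- prod(attr(dose, "spacing")) / 1000
  dvh_curve(edges, vf, total_volume = n * vox, voxel_volume = vox,
            organ_label = attr(mask, "organ_label"))
}

#' Dose at a given volume fraction (inverse DVH lookup)
#'
#' The minimum dose received by the hottest fraction `q` of the organ:
#' the largest dose `d` with `volume_fraction(d) >= q`, linearly
#' interpolated between tabulated edges.
#'
#' @param dvh A `dvh_curve`.
#' @param q Volume fraction(s) in (0, 1].
#' @return Dose(s) in Gy.
#' @export
dose_at_fraction <- function(dvh, q) {
  vf <- dvh$volume_fraction
  e <- dvh$dose_edges
  vapply(q, function(qi) {
    if (qi <= 0) {
      idx <- which(vf > 0)
      return(if (length(idx)) e[max(idx)] else 0)
    }
    idx <- which(vf >= qi)
    if (!length(idx)) return(e[1])
    i <- max(idx)
    if (i == length(e) || vf[i] <= qi) return(e[i])
    # vf[i] > qi > vf[i + 1]: interpolate
    e[i] + (vf[i] - qi) / (vf[i] - vf[i + 1]) * (e[i + 1] - e[i])
  }, numeric(1))
}

#' Evaluate the volume fraction at given doses
#'
#' @param dvh A `dvh_curve`.
#' @param x Dose(s) in Gy.
#' @return Fraction(s) of organ receiving at least `x` Gy.
#' @export
volume_at_dose <- function(dvh, x) {
  f <- approx(dvh$dose_edges, dvh$volume_fraction, xout = x,
              yleft = 1, yright = 0, ties = "ordered")$y
  f
}

#' DVH summary metrics (Vx / Dx families)
#'
#' Computes the standard metric families from a cumulative DVH: percentage
#' and absolute volumes receiving at least x Gy (`Vx_pct`, `Vx_cc`), the
#' mean/min/max dose implied by the curve, minimum dose to the hottest 1 and
#' 2 cc (`D1cc`, `D2cc`) and to the hottest 1 and 2 percent (`D1pct`,
#' `D2pct`).
#'
#' @param dvh A `dvh_curve`.
#' @param x_grid Doses (Gy) at which Vx is evaluated; default 5-55 Gy in
#'   5 Gy steps.
#' @return A tibble with columns `metric` and `value`. If a requested
#'   absolute volume exceeds the organ volume the corresponding Dxcc falls
#'   back to Dmin and a warning is raised.
#' @export
dvh_to_metrics <- function(dvh, x_grid = seq(5, 55, by = 5)) {
  vf <- dvh$volume_fraction
  e <- dvh$dose_edges
  step <- diff(e)
  dmean <- sum((vf[-1] + vf[-length(vf)]) / 2 * step)   # integral of vf
  dmin <- dose_at_fraction(dvh, 1)
  dmax <- dose_at_fraction(dvh, 1e-12)
  dcc <- function(cc) {
    if (cc > dvh$total_volume) {
      warn(sprintf("requested %g cc exceeds organ volume %.3g cc; using Dmin",
                   cc, dvh$total_volume))
      return(dmin)
    }
    dose_at_fraction(dvh, cc / dvh$total_volume)
  }
  vx <- volume_at_dose(dvh, x_grid)
  tibble(
    metric = c(paste0("V", x_grid, "pct"), paste0("V", x_grid, "cc"),
               "Dmean", "Dmin", "Dmax", "D1cc", "D2cc", "D1pct", "D2pct"),
    value = c(100 * vx, vx * dvh$total_volume,
              dmean, dmin, dmax, dcc(1), dcc(2),
              dose_at_fraction(dvh, 0.01), dose_at_fraction(dvh, 0.02))
  )
}

#' EQD2 conversion under the linear-quadratic model
#'
#' Converts a physical dose delivered in `n_fractions` equal fractions to
#' the equieffective dose in 2 Gy fractions:
#' \eqn{EQD2 = D\,(d + \alpha/\beta)/(2 + \alpha/\beta)} with per-fraction
#' dose \eqn{d = D/n}. Use \eqn{\alpha/\beta = 10} Gy for acute-responding
#' and 3 Gy for late-responding tissue.
#'
#' @param dose_value Total physical dose(s) in Gy (vectorized).
#' @param n_fractions Number of fractions the dose is delivered in.
#' @param alpha_beta Tissue alpha/beta ratio in Gy; must be positive.
#' @return EQD2 dose(s) in Gy.
#' @examples
#' eqd2_convert(45, 25, 3)  # 43.2
#' eqd2_convert(21, 3, 3)   # 42.0
#' @export
eqd2_convert <- function(dose_value, n_fractions, alpha_beta) {
  if (!is.numeric(alpha_beta) || alpha_beta <= 0) {
    abort("`alpha_beta` must be positive.",
          class = "dosiomics_invalid_argument")
  }
  if (any(dose_value < 0)) {
    abort("doses must be non-negative.", class = "dosiomics_invalid_argument")
  }
  d <- dose_value / n_fractions
  dose_value * (d + alpha_beta) / (2 + alpha_beta)
}

#' EQD2-transform a DVH curve
#'
#' Applies [eqd2_convert()] edge-wise: every tabulated dose edge is treated
#' as a total dose delivered in the same number of fractions. The transform
#' is monotone, so volume fractions are unchanged.
#'
#' @param dvh A `dvh_curve` of physical dose.
#' @param n_fractions,alpha_beta See [eqd2_convert()].
#' @return A `dvh_curve` on the EQD2 scale.
#' @export
eqd2_dvh <- function(dvh, n_fractions, alpha_beta) {
  dvh_curve(eqd2_convert(dvh$dose_edges, n_fractions, alpha_beta),
            dvh$volume_fraction, dvh$total_volume, dvh$voxel_volume,
            dvh$organ_label)
}

#' Hotspot-aligned summation of two DVH curves
#'
#' Sums an EBRT and a BT DVH under the assumption that the hotspots of both
#' plans are co-located: each curve is inverted to dose-at-volume-fraction
#' on a shared grid of `n_points` volume fractions, doses are added at equal
#' volume fraction (hottest with hottest), and the result is re-expressed as
#' a cumulative DVH.
#'
#' @param dvh_a,dvh_b `dvh_curve` objects for the same organ (labels must
#'   match when both are set).
#' @param n_points Size of the shared volume-fraction grid.
#' @param edge_step Tabulation step of the output curve (Gy).
#' @return A `dvh_curve` for the summed dose distribution.
#' @export
sum_dvh_hotspot_aligned <- function(dvh_a, dvh_b, n_points = 1000,
                                    edge_step = 0.1) {
  la <- dvh_a$organ_label; lb <- dvh_b$organ_label
  if (!is.na(la) && !is.na(lb) && la != lb) {
    abort("cannot sum DVHs of different organs.",
          class = "dosiomics_invalid_argument")
  }
  u <- (seq_len(n_points) - 0.5) / n_points
  dsum <- dose_at_fraction(dvh_a, u) + dose_at_fraction(dvh_b, u)
  # dsum is non-increasing in u; treat as n_points equal-volume pseudo-voxels
  ds <- sort(dsum)
  edges <- seq(0, (floor(max(ds) / edge_step) + 1) * edge_step, by = edge_step)
  below <- findInterval(edges, ds, left.open = TRUE)
  vf <- (n_points - below) / n_points
  dvh_curve(edges, vf, total_volume = dvh_a$total_volume,
            voxel_volume = dvh_a$total_volume / n_points,
            organ_label = if (!is.na(la)) la else lb)
}

#' @rdname plot_dvh
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$dose_gy, y = .data$volume_fraction)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume fraction ≥ dose",
                  title = object$organ_label) +
    ggplot2::theme_minimal()
}

#' Plot a cumulative DVH curve
#'
#' @param object,x A `dvh_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_dvh <- function(x, ...) autoplot.dvh_curve(x, ...)
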