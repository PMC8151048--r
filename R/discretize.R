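#' Fixed-bin-width grey-level discretization of a dose map
#'
#' Doses inside the mask are mapped to integer grey levels with a fixed bin
#' width, the discretization used for all texture features: level
#' \eqn{g(v) = \lfloor (D(v) - b_0)/w \rfloor + 1}, so level \eqn{g} covers
#' the half-open dose interval \eqn{[b_0 + (g-1)w,\; b_0 + g w)}. The bin
#' origin is anchored at 0 Gy by default (not the ROI minimum): dose has a
#' meaningful absolute zero, and anchoring keeps grey levels comparable
#' across patients.
#'
#' @param dose A [dose_grid()].
#' @param mask An [organ_mask()] on the same lattice.
#' @param bin_width Bin width in Gy (default 1 Gy). `Inf` collapses the ROI
#'   to a single grey level.
#' @param bin_origin Dose (Gy) at the lower edge of the first bin.
#' @return A `grey_level_volume`: list with `levels` (integer 3D array, 0
#'   outside the mask), `ng` (number of grey levels = max level), `bin_width`
#'   and `bin_origin`.
#' @examples
#' d <- dose_grid(array(45, c(3, 3, 3)))
#' m <- organ_mask(array(TRUE, c(3, 3, 3)))
#' discretize_fbw(d, m, bin_width = 1)$ng  # 46
#' @export
discretize_fbw <- function(dose, mask, bin_width = 1, bin_origin = 0) {
  check_aligned(dose, mask)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    abort("`bin_width` must be a single positive value (Gy).",
          class = "dosiomics_invalid_argument")
  }
  if (!any(mask)) {
    abort("empty ROI: mask selects no voxels.", class = "dosiomics_empty_roi")
  }
  lv <- array(0L, dim(dose))
  if (is.infinite(bin_width)) {
    lv[mask] <- 1L
  } else {
    lv[mask] <- as.integer(floor((dose[mask] - bin_origin) / bin_width)) + 1L
  }
  if (any(lv[mask] < 1L)) {
    abort("doses below `bin_origin` inside the ROI.",
          class = "dosiomics_invalid_argument")
  }
  structure(
    list(levels = lv, ng = max(lv), bin_width = bin_width,
         bin_origin = bin_origin),
    class = "grey_level_volume"
  )
}

#' @export
print.grey_level_volume <- function(x, ...) {
  cat("<grey_level_volume> Ng = ", x$ng, ", bin width ", x$bin_width,
      " Gy, ", sum(x$levels > 0), " ROI voxels\n", sep = "")
  invisible(x)
}

# The 13 unique 3D directions at Chebyshev distance 1 (up to sign).
.dirs13 <- local({
  d <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  keep <- d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
    (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
  m <- d[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
})

texture_directions <- function() .dirs13
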