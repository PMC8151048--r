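#' Construct a 3D dose grid
#'
#' A `dose_grid` is a 3D array of absorbed dose values (Gy) with voxel
#' spacing and origin (mm). It is the "image" that dosimetric radiomics and
#' DVH computation operate on.
#'
#' @param values 3D numeric array of non-negative, finite doses in Gy.
#' @param spacing Numeric length-3, strictly positive voxel spacing in mm.
#' @param origin Numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @return A `dose_grid` object (a 3D array with `spacing` and `origin`
#'   attributes).
#' @examples
#' g <- dose_grid(array(45, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(g)
#' @export
dose_grid <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.", class = "dosiomics_format_error")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive lengths (mm).",
          class = "dosiomics_invalid_argument")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite coordinates (mm).",
          class = "dosiomics_invalid_argument")
  }
  if (any(!is.finite(values))) {
    abort("dose values must all be finite (no NA/NaN/Inf).",
          class = "dosiomics_format_error")
  }
  if (any(values < 0)) {
    abort("dose values must be non-negative.",
          class = "dosiomics_format_error")
  }
  structure(values, spacing = spacing, origin = origin,
            class = c("dose_grid", "array"))
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(dim(x), collapse = " x "),
      " voxels, spacing ", paste(attr(x, "spacing"), collapse = "/"),
      " mm, dose range [", signif(min(x), 4), ", ", signif(max(x), 4),
      "] Gy\n", sep = "")
  invisible(x)
}

#' Construct a binary organ-at-risk mask
#'
#' An `organ_mask` indicates the region of interest (an organ at risk such
#' as rectum, bladder or vagina) on the same voxel lattice as a
#' [dose_grid()].
#'
#' @param indicator 3D array coercible to logical; `TRUE`/1 inside the organ.
#' @param spacing,origin Grid geometry, as in [dose_grid()].
#' @param organ_label One of `"rectum"`, `"bladder"`, `"vagina"`.
#' @return An `organ_mask` object (logical 3D array with geometry attributes).
#' @export
organ_mask <- function(indicator, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                       organ_label = c("rectum", "bladder", "vagina")) {
  organ_label <- match.arg(organ_label)
  indicator <- as.array(indicator)
  if (length(dim(indicator)) != 3L) {
    abort("`indicator` must be a 3D array.", class = "dosiomics_format_error")
  }
  if (any(is.na(indicator)) || !all(indicator %in% c(0, 1, TRUE, FALSE))) {
    abort("mask values must be binary (0/1).", class = "dosiomics_format_error")
  }
  ind <- array(as.logical(indicator), dim(indicator))
  if (!any(ind)) {
    abort("mask must contain at least one voxel.",
          class = "dosiomics_empty_roi")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive lengths (mm).",
          class = "dosiomics_invalid_argument")
  }
  structure(ind, spacing = spacing, origin = origin,
            organ_label = organ_label,
            class = c("organ_mask", "array"))
}

#' @export
print.organ_mask <- function(x, ...) {
  cat("<organ_mask> ", attr(x, "organ_label"), ", ",
      sum(x), " of ", length(x), " voxels (",
      signif(mask_volume_cc(x), 4), " cc)\n", sep = "")
  invisible(x)
}

#' Organ volume of a mask in cc
#'
#' @param mask An [organ_mask()].
#' @return Volume in cc (voxel count times voxel volume).
#' @export
mask_volume_cc <- function(mask) {
  sum(mask) * prod(attr(mask, "spacing")) / 1000
}

#' Number of 26-connected components of a mask
#'
#' @param mask An [organ_mask()] or binary 3D array.
#' @return Integer component count under 26-connectivity.
#' @export
mask_components <- function(mask) {
  m <- array(as.integer(mask), dim(mask))
  attr(cpp_label26(m), "n_components")
}

#' Check that a dose grid and mask share the same lattice
#'
#' No resampling is ever performed: misaligned inputs are rejected rather
#' than silently interpolated, because interpolation materially changes
#' texture values.
#'
#' @param dose A [dose_grid()].
#' @param mask An [organ_mask()].
#' @param tol_mm Component-wise tolerance (mm) on spacing and origin.
#' @return `TRUE` if shapes are identical and spacing/origin agree within
#'   `tol_mm`; otherwise `FALSE` with a `reason` attribute.
#' @export
validate_alignment <- function(dose, mask, tol_mm = 0.01) {
  if (!identical(dim(dose), dim(mask))) {
    return(structure(FALSE, reason = "shape mismatch"))
  }
  if (any(abs(attr(dose, "spacing") - attr(mask, "spacing")) > tol_mm)) {
    return(structure(FALSE, reason = "spacing mismatch"))
  }
  if (any(abs(attr(dose, "origin") - attr(mask, "origin")) > tol_mm)) {
    return(structure(FALSE, reason = "origin mismatch"))
  }
  TRUE
}

check_aligned <- function(dose, mask, tol_mm = 0.01) {
  ok <- validate_alignment(dose, mask, tol_mm)
  if (!isTRUE(ok)) {
    abort(paste0("dose grid and mask are not aligned: ", attr(ok, "reason")),
          class = "dosiomics_invalid_argument")
  }
  invisible(TRUE)
}
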