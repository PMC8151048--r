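#' Extract the 91-feature dosimetric-radiomic vector
#'
#' Discretizes the dose map inside the organ mask at a fixed bin width and
#' computes the full feature panel: 18 intensity statistics + 11
#' intensity-histogram features + 25 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM
#' = 91 IBSI-style features, all in 3D with merged direction aggregation.
#'
#' @param dose A [dose_grid()].
#' @param mask An [organ_mask()] on the same lattice.
#' @param bin_width Discretization bin width in Gy (default 1).
#' @param bin_origin Lower edge of the first dose bin (default 0 Gy).
#' @return A named numeric vector of exactly 91 finite values, with
#'   attributes `organ_label` and `bin_width`.
#' @examples
#' d <- dose_grid(array(runif(8^3, 40, 50), c(8, 8, 8)))
#' m <- organ_mask(array(TRUE, c(8, 8, 8)))
#' length(extract_feature_vector(d, m))  # 91
#' @export
extract_feature_vector <- function(dose, mask, bin_width = 1, bin_origin = 0) {
  glv <- discretize_fbw(dose, mask, bin_width, bin_origin)
  out <- c(
    intensity_features(dose, mask, glv),
    glcm_features(glv),
    glrlm_features(glv),
    glszm_features(glv),
    ngtdm_features(glv)
  )
  attributes(out) <- list(names = names(out))
  stopifnot(length(out) == 91L, all(is.finite(out)))
  attr(out, "organ_label") <- attr(mask, "organ_label")
  attr(out, "bin_width") <- bin_width
  out
}

#' The dosimetric-radiomics feature registry
#'
#' One row per feature: name, family, the IBSI feature it implements and the
#' fallback rule applied on degenerate (single-grey-level or single-voxel)
#' ROIs. The same table ships as a plain-text file under
#' `inst/extdata/feature_registry.csv`.
#'
#' @return A tibble with 91 rows and columns `name`, `family`, `ibsi_ref`,
#'   `fallback`.
#' @export
feature_registry <- function() {
  path <- system.file("extdata", "feature_registry.csv",
                      package = "dosiomics", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
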