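#' Write a dose grid or organ mask to NIfTI
#'
#' Dose grids are stored as float64 so values round-trip bit-identically;
#' masks as uint8. Spacing goes to `pixdim` and the origin to the
#' qform/sform translation.
#'
#' @param x A [dose_grid()] or [organ_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(x, path) {
  a <- array(as.numeric(x), dim(x))
  attr(a, "pixdim") <- attr(x, "spacing")
  img <- RNifti::asNifti(a, datatype = "double")
  m <- diag(4)
  diag(m)[1:3] <- attr(x, "spacing")
  m[1:3, 4] <- attr(x, "origin")
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
write_organ_mask <- function(x, path) {
  a <- array(as.integer(x), dim(x))
  attr(a, "pixdim") <- attr(x, "spacing")
  img <- RNifti::asNifti(a, datatype = "uint8")
  m <- diag(4)
  diag(m)[1:3] <- attr(x, "spacing")
  m[1:3, 4] <- attr(x, "origin")
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    abort(sprintf("expected a 3D volume, got %dD.", length(d)),
          class = "dosiomics_format_error")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- RNifti::xform(img)[1:3, 4]
  list(values = array(as.numeric(img), d), spacing = spacing, origin = origin)
}

#' Read a dose grid or organ mask from NIfTI
#'
#' Volumes must be 3D; NaN or negative voxels in a dose grid, or non-binary
#' voxels in a mask, raise a format error naming the offending property.
#'
#' @param path NIfTI file path.
#' @param organ_label Organ name to attach to the mask (NIfTI does not carry
#'   one).
#' @return A [dose_grid()] / [organ_mask()].
#' @export
read_dose_grid <- function(path) {
  v <- read_nifti_volume(path)
  if (any(is.na(v$values))) {
    abort("dose volume contains NaN voxels.", class = "dosiomics_format_error")
  }
  if (any(v$values < 0)) {
    abort("dose volume contains negative doses.",
          class = "dosiomics_format_error")
  }
  dose_grid(v$values, v$spacing, v$origin)
}

#' @rdname read_dose_grid
#' @export
read_organ_mask <- function(path, organ_label = c("rectum", "bladder",
                                                  "vagina")) {
  v <- read_nifti_volume(path)
  if (any(is.na(v$values)) || !all(v$values %in% c(0, 1))) {
    abort("mask volume is not binary.", class = "dosiomics_format_error")
  }
  organ_mask(v$values, v$spacing, v$origin, match.arg(organ_label))
}

#' Read and write DVH curves as two-column delimited text
#'
#' Format: comment lines carrying the volume bookkeeping, then a header row
#' and two comma-separated columns `dose_gy`, `volume_fraction`.
#'
#' @param dvh A `dvh_curve`.
#' @param path File path.
#' @return `write_dvh` returns `path` invisibly; `read_dvh` a `dvh_curve`.
#' @export
write_dvh <- function(dvh, path) {
  hdr <- c(
    sprintf("# total_volume_cc=%.12g", dvh$total_volume),
    sprintf("# voxel_volume_cc=%.12g", dvh$voxel_volume),
    sprintf("# organ_label=%s", dvh$organ_label)
  )
  writeLines(c(hdr, "dose_gy,volume_fraction",
               sprintf("%.12g,%.12g", dvh$dose_edges, dvh$volume_fraction)),
             path)
  invisible(path)
}

#' @rdname write_dvh
#' @export
read_dvh <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, "="), "", grep(key, hdr,
                                                             value = TRUE))
  tab <- readr::read_csv(I(lines[!grepl("^#", lines)]),
                         show_col_types = FALSE)
  lab <- get("organ_label")
  dvh_curve(tab$dose_gy, tab$volume_fraction,
            total_volume = as.numeric(get("total_volume_cc")),
            voxel_volume = as.numeric(get("voxel_volume_cc")),
            organ_label = if (length(lab) && lab != "NA") lab
                          else NA_character_)
}

#' Read and write a cohort table as CSV
#'
#' One row per patient: id, split, clinical covariates, endpoint flags and
#' any `DVH_`/`RA_` feature columns.
#'
#' @param table A tibble (e.g. `gen_cohort(...)$table`).
#' @param path CSV file path.
#' @return `write_cohort_table` returns `path` invisibly;
#'   `read_cohort_table` a tibble.
#' @export
write_cohort_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
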