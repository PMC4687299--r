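# Input/output for the external artifacts the pipeline touches: 4D BOLD
# NIfTI images, 3D maps and masks, realignment motion text files, and
# cohort covariate tables.

#' Construct a 4D BOLD image object
#'
#' The in-memory substrate of every pipeline stage: a 4D array (x, y, z, t)
#' of BOLD intensities in native scanner units, the 4x4 voxel-to-world
#' affine (mm), and the repetition time in seconds.
#'
#' @param data 4D numeric array
#' @param affine 4x4 voxel-to-world matrix; must be invertible
#' @param tr repetition time in seconds (> 0)
#' @return object of class `bold_image`
#' @export
bold_image <- function(data, affine = diag(4), tr = 2) {
  if (length(dim(data)) != 4L) stop_acf("bold_image: expected 4D data array")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop_acf("bold_image: field 'tr' must be a positive number")
  if (dim(data)[4] < 9L)
    stop_acf("bold_image: need at least 9 volumes (lags 0-8 of the ACF)")
  if (length(affine) != 16L)
    stop_acf("bold_image: field 'affine' must be a 4x4 matrix")
  affine <- matrix(as.numeric(affine), 4, 4)
  if (abs(det(affine)) < 1e-12)
    stop_acf("bold_image: field 'affine' must be an invertible 4x4 matrix")
  structure(list(data = data, affine = affine, tr = tr,
                 n_volumes = dim(data)[4]),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<bold_image> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              dm[1], dm[2], dm[3], dm[4], x$tr))
  invisible(x)
}

#' Construct a 3D volume map
#'
#' A scalar field on a voxel grid (e.g. a b map or a t map) together with
#' the analysis mask. Values must be finite exactly where the mask is true;
#' out-of-mask voxels are stored as `NaN` (not zero, because 0 is a legal
#' value of most mapped quantities).
#'
#' @param values 3D numeric array
#' @param affine 4x4 voxel-to-world matrix
#' @param mask logical 3D array; defaults to the finite voxels of `values`
#' @return object of class `volume_map`
#' @export
volume_map <- function(values, affine = diag(4), mask = NULL) {
  if (length(dim(values)) != 3L) stop_acf("volume_map: expected 3D values array")
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as_mask(mask)
  if (!all(dim(mask) == dim(values)))
    stop_acf("volume_map: mask and values must have the same shape")
  if (any(mask & !is.finite(values)))
    stop_acf("volume_map: non-finite values inside the mask")
  values[!mask] <- NaN
  structure(list(values = values, affine = matrix(as.numeric(affine), 4, 4),
                 mask = mask),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("<volume_map> %s grid, %d in-mask voxels\n",
              paste(dim(x$values), collapse = " x "), sum(x$mask)))
  invisible(x)
}

# Decode the time unit of pixdim[4] from the NIfTI xyzt_units field.
.nifti_time_scale <- function(xyzt_units) {
  tcode <- bitwAnd(as.integer(xyzt_units %||% 0), 56L)
  switch(as.character(tcode), "8" = 1, "16" = 1e-3, "24" = 1e-6, 1)
}

#' Read a 4D BOLD NIfTI file
#'
#' The repetition time is taken from the header time step (converted to
#' seconds according to the header time unit) unless `tr` is supplied, in
#' which case the override wins and a header mismatch is reported as a
#' warning.
#'
#' @param path NIfTI-1/2 file (.nii or .nii.gz)
#' @param tr optional repetition-time override in seconds
#' @return a [bold_image()]
#' @export
read_bold <- function(path, tr = NULL) {
  if (!file.exists(path)) stop_acf("read_bold: file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop_acf("read_bold: expected 4D image, got ", length(dim(img)), "D: ", path)
  hdr <- RNifti::niftiHeader(img)
  header_tr <- hdr$pixdim[5] * .nifti_time_scale(hdr$xyzt_units)
  if (is.null(tr)) {
    if (!is.finite(header_tr) || header_tr <= 0)
      stop_acf("read_bold: header field 'pixdim[4]' (time step) is not positive; ",
               "supply tr explicitly")
    tr <- header_tr
  } else if (is.finite(header_tr) && header_tr > 0 &&
             abs(header_tr - tr) > 1e-6) {
    warning(sprintf("read_bold: tr override %g s differs from header %g s; using override",
                    tr, header_tr), call. = FALSE)
  }
  bold_image(array(as.numeric(img), dim = dim(img)),
             affine = unclass(RNifti::xform(img)), tr = tr)
}

#' Write a 4D BOLD image to NIfTI
#'
#' @param bold a [bold_image()]
#' @param path output path (.nii or .nii.gz)
#' @param datatype storage type passed to [RNifti::writeNifti()]
#' @return `path`, invisibly
#' @export
write_bold <- function(bold, path, datatype = "double") {
  img <- RNifti::asNifti(bold$data)
  vox <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(vox, bold$tr)
  RNifti::sform(img) <- structure(bold$affine, code = 2L)
  RNifti::qform(img) <- structure(bold$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a volume map to NIfTI
#'
#' Out-of-mask voxels are written as `NaN`; [read_map()] reconstructs the
#' mask as the finite-valued voxels.
#'
#' @param map a [volume_map()]
#' @param path output path
#' @param datatype storage type (default single precision)
#' @return `path`, invisibly
#' @export
write_map <- function(map, path, datatype = "float") {
  if (!inherits(map, "volume_map")) stop_acf("write_map: not a volume_map")
  if (any(map$mask & !is.finite(map$values)))
    stop_acf("write_map: non-finite values inside the mask")
  vals <- map$values
  vals[!map$mask] <- NaN
  img <- RNifti::asNifti(vals)
  vox <- sqrt(colSums(map$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vox
  RNifti::sform(img) <- structure(map$affine, code = 2L)
  RNifti::qform(img) <- structure(map$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a volume map from NIfTI
#'
#' @param path NIfTI file holding a 3D map
#' @return a [volume_map()] whose mask is the set of finite voxels
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop_acf("read_map: file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) dim(img) <- dm[1:3]
  if (length(dim(img)) != 3L)
    stop_acf("read_map: expected 3D image, got ", length(dm), "D: ", path)
  vals <- array(as.numeric(img), dim = dim(img))
  volume_map(vals, affine = unclass(RNifti::xform(img)),
             mask = is.finite(vals))
}

#' Read a binary mask from NIfTI
#'
#' Non-zero finite voxels are in-mask.
#' @param path NIfTI file
#' @return logical 3D array with an `affine` attribute
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) dim(img) <- dm[1:3]
  vals <- array(as.numeric(img), dim = dim(img))
  m <- is.finite(vals) & vals != 0
  attr(m, "affine") <- unclass(RNifti::xform(img))
  m
}

#' Write a binary mask to NIfTI
#' @param mask logical 3D array
#' @param affine 4x4 voxel-to-world matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, affine, path) {
  img <- RNifti::asNifti(array(as.numeric(mask), dim = dim(mask)))
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vox
  RNifti::sform(img) <- structure(unname(as.matrix(affine)), code = 2L)
  RNifti::qform(img) <- structure(unname(as.matrix(affine)), code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a 6-column realignment motion-parameter file
#'
#' Whitespace-delimited text, one row per volume: columns 1-3 translations
#' in mm, columns 4-6 rotations in radians (the realignment-output
#' convention). Header lines or non-numeric cells are an error (no silent
#' skipping), reported with their line number.
#'
#' @param path text file
#' @return T x 6 numeric matrix of class `motion_params`
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop_acf("read_motion: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_acf("read_motion: empty file: ", path)
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 6L)
      stop_acf("read_motion: row ", i, " has ", length(parts),
               " columns, expected 6: ", path)
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      stop_acf("read_motion: non-numeric value in row ", i, ": ", path)
    vals
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(tab, class = c("motion_params", class(tab)))
}

#' Write motion parameters as whitespace-delimited text
#' @param motion T x 6 numeric matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_motion <- function(motion, path) {
  write.table(format(unclass(motion), digits = 10, scientific = FALSE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort covariate table
#'
#' CSV with at least `subject_id` and `group` columns; `group` must be
#' `patient` or `control`. Clinical covariates (`duration`, `lm_dr`) may be
#' missing for controls; unknown extra columns are preserved untouched.
#'
#' @param path CSV file
#' @return data.frame of class `cohort_table`
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_acf("read_cohort: file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop_acf("read_cohort: missing required column(s): ",
             paste(miss, collapse = ", "))
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id))
    stop_acf("read_cohort: duplicated subject_id: ",
             tab$subject_id[duplicated(tab$subject_id)][1])
  bad <- setdiff(unique(tab$group), c("patient", "control"))
  if (length(bad) || any(!nzchar(tab$group)) || anyNA(tab$group))
    stop_acf("read_cohort: group labels must be 'patient' or 'control'",
             if (length(bad)) paste0("; found: ", paste(bad, collapse = ", ")))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Write a cohort covariate table
#' @param cohort data.frame with `subject_id` and `group` columns
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_cohort_table <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
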