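## Domain types and NIfTI / JSON input-output.
##
## Conventions: 0-based physical geometry is never exposed; arrays are
## indexed (z, y, x) with 1-based R indices, spacing is mm per voxel along
## (z, y, x), physical lengths are computed in mm and reported in cm.

#' Construct a CT-like intensity volume
#'
#' @param data numeric 3-D array, axes ordered (z, y, x).
#' @param spacing numeric length-3, mm per voxel along (z, y, x).
#' @return an object of class `hep_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stopf("volume data must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive numbers (mm)")
  structure(list(data = data, spacing = spacing), class = "hep_volume")
}

#' Construct a binary mask aligned with a volume
#'
#' @param data 3-D array over {0,1} (logical accepted).
#' @param spacing mm per voxel along (z, y, x).
#' @return an object of class `hep_mask`.
#' @export
mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stopf("mask data must be a 3-D array")
  v <- unique(as.vector(data))
  if (!all(v %in% c(0, 1, TRUE, FALSE)))
    stopf("mask values must lie in {0,1}")
  d <- array(as.integer(data != 0), dim(data))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stopf("spacing must be 3 positive numbers (mm)")
  structure(list(data = d, spacing = spacing), class = "hep_mask")
}

#' Construct a segment label map (0 = background, 1..8 = Couinaud-style codes)
#'
#' @param data integer 3-D array with values in 0..8.
#' @param spacing mm per voxel along (z, y, x).
#' @return an object of class `hep_labelmap`.
#' @export
labelmap <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stopf("labelmap data must be a 3-D array")
  v <- unique(as.vector(data))
  if (!all(v %in% 0:8)) stopf("labelmap values must lie in {0..8}")
  structure(list(data = array(as.integer(data), dim(data)),
                 spacing = as.numeric(spacing)),
            class = "hep_labelmap")
}

#' Project one segment of a label map to a binary mask
#'
#' @param lm a `hep_labelmap`.
#' @param k segment code in 1..8.
#' @export
segment_mask <- function(lm, k) {
  stopifnot(inherits(lm, "hep_labelmap"), k %in% 1:8)
  mask(lm$data == k, lm$spacing)
}

#' @export
print.hep_volume <- function(x, ...) {
  cat(sprintf("<Volume %s, spacing %s mm, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.hep_mask <- function(x, ...) {
  cat(sprintf("<Mask %s, %d positive voxels>\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
print.hep_labelmap <- function(x, ...) {
  tb <- table(factor(x$data[x$data > 0], levels = 1:8))
  cat(sprintf("<LabelMap %s, segment voxels: %s>\n",
              paste(dim(x$data), collapse = "x"),
              paste(sprintf("%d:%d", 1:8, as.integer(tb)), collapse = " ")))
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return a `hep_volume` with spacing taken from the header voxel
#'   dimensions. The on-disk (x, y, z) axis order of NIfTI is transposed to
#'   the package's (z, y, x) convention.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) { img <- array(img, d[1:3]); d <- d[1:3] }
  if (length(d) != 3) stopf("not a 3-D image: %s (%d dims)", path, length(d))
  pix <- RNifti::pixdim(img)[1:3]            # (x, y, z) mm
  dat <- aperm(array(as.numeric(img), d), c(3, 2, 1))
  volume(dat, spacing = rev(pix))
}

#' Read a NIfTI mask (values coerced to {0,1})
#' @param path a `.nii` or `.nii.gz` file.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  mask(v$data != 0, v$spacing)
}

#' Read a NIfTI segment label map
#' @param path a `.nii` or `.nii.gz` file.
#' @export
read_labelmap <- function(path) {
  v <- read_volume(path)
  labelmap(array(as.integer(round(v$data)), dim(v$data)), v$spacing)
}

write_nifti_raw <- function(data_zyx, spacing_zyx, path, datatype) {
  arr <- aperm(data_zyx, c(3, 2, 1))         # back to on-disk (x, y, z)
  attr(arr, "pixdim") <- rev(spacing_zyx)
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(NULL)
}

#' Write a volume to NIfTI-1
#' @param v a `hep_volume`.
#' @param path destination `.nii` or `.nii.gz`.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "hep_volume"))
  write_nifti_raw(v$data, v$spacing, path, "float")
}

#' Write a binary mask to NIfTI-1 (stored as unsigned 8-bit)
#' @param m a `hep_mask`.
#' @param path destination `.nii` or `.nii.gz`.
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "hep_mask"))
  write_nifti_raw(m$data, m$spacing, path, "uint8")
}

#' Write a segment label map to NIfTI-1 (unsigned 8-bit codes 0..8)
#' @param lm a `hep_labelmap`.
#' @param path destination `.nii` or `.nii.gz`.
#' @export
write_labelmap <- function(lm, path) {
  stopifnot(inherits(lm, "hep_labelmap"))
  write_nifti_raw(lm$data, lm$spacing, path, "uint8")
}

#' Construct a per-tumor annotation record
#'
#' The final report unit: physical size, Couinaud segment locations, the
#' 11 characteristic bits, and the identifiers of the models that produced
#' each stage.
#'
#' @param tumor_id integer instance id.
#' @param size_cm reported size in cm (clamped at 0).
#' @param locations subset of 1..8.
#' @param characteristics binary vector of length 11 (NA allowed when the
#'   recognition stage is disabled).
#' @param provenance named list mapping stage name to model identifier.
#' @export
annotation <- function(tumor_id, size_cm, locations, characteristics,
                       provenance = list()) {
  locations <- sort(unique(as.integer(locations)))
  if (length(locations) && !all(locations %in% 1:8))
    stopf("locations must be a subset of 1..8")
  if (length(characteristics) != 11)
    stopf("characteristics must have length 11")
  if (!all(is.na(characteristics) | characteristics %in% c(0, 1)))
    stopf("characteristics must be binary (or NA)")
  structure(list(tumor_id = as.integer(tumor_id),
                 size_cm = as.numeric(size_cm),
                 locations = locations,
                 characteristics = as.integer(characteristics),
                 provenance = provenance),
            class = "hep_annotation")
}

#' @export
print.hep_annotation <- function(x, ...) {
  cat(sprintf("tumor %d: size %.2f cm, segments {%s}, characteristics %s\n",
              x$tumor_id, x$size_cm, paste(x$locations, collapse = ","),
              paste(ifelse(is.na(x$characteristics), "?", x$characteristics),
                    collapse = "")))
  invisible(x)
}

#' Write an annotation report as JSON
#'
#' @param annotations list of [annotation()] records.
#' @param path destination file.
#' @export
write_report <- function(annotations, path) {
  recs <- lapply(annotations, function(a) {
    if (!inherits(a, "hep_annotation")) stopf("not an annotation record")
    list(tumor_id = a$tumor_id,
         size_cm = a$size_cm,
         locations = as.integer(sort(a$locations)),
         characteristics = a$characteristics,
         provenance = a$provenance)
  })
  jsonlite::write_json(list(tumors = recs), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(NULL)
}

#' Read an annotation report written by [write_report()]
#' @param path JSON report file.
#' @return list of `hep_annotation` records.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(doc$tumors, function(r) {
    ch <- unlist(r$characteristics)
    ch[is.null(ch)] <- NA
    annotation(r$tumor_id, r$size_cm, unlist(r$locations) %||% integer(0),
               ch, r$provenance %||% list())
  })
}
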