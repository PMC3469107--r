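#' Read a CT volume from a DICOM series directory or a NIfTI file
#'
#' DICOM series are assembled slice by slice: stored values are converted to
#' Hounsfield Units via the rescale slope/intercept (files without those tags
#' are rejected rather than silently assumed to be HU), slices are sorted by
#' their physical position along the slice normal (never by filename), and the
#' slice spacing is taken from the position increments. NIfTI files are read
#' with RNifti and rearranged to the package's (slice, row, col) axis order.
#'
#' @param path a DICOM series directory or a `.nii`/`.nii.gz` file.
#' @param format_hint one of `"auto"`, `"dicom_dir"`, `"nifti"`.
#' @return A [ct_volume].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format_hint = c("auto", "dicom_dir", "nifti")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("path does not exist: ", path)
  fmt <- format_hint
  if (fmt == "auto") {
    fmt <- if (dir.exists(path)) "dicom_dir" else "nifti"
  }
  switch(fmt,
    dicom_dir = .dcm_read_series(path),
    nifti = .read_nifti_volume(path)
  )
}

.read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  pd <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  # NIfTI axes (x=col, y=row, z=slice) -> package order (slice, row, col)
  vox <- aperm(arr, c(3L, 2L, 1L))
  spacing <- abs(pd[c(3L, 2L, 1L)])
  origin <- as.numeric(xf[1:3, 4])[c(3L, 2L, 1L)]
  ct_volume(vox, spacing = spacing, origin = origin)
}

#' Write a CT volume to NIfTI-1
#'
#' Geometry (grid, spacing, origin) survives a [read_volume()] round trip
#' losslessly; integer-valued HU grids round-trip bit exactly.
#'
#' @param vol a [ct_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param format only `"nifti"` is supported.
#' @export
write_volume <- function(vol, path, format = "nifti") {
  format <- match.arg(format, "nifti")
  if (!is_ct_volume(vol)) stop("'vol' must be a ct_volume")
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path))
  }
  .write_nifti_array(unclass(vol$voxels), vol$spacing, vol$origin, path,
                     datatype = "double")
  invisible(path)
}

.write_nifti_array <- function(arr, spacing, origin, path, datatype) {
  data <- aperm(arr, c(3L, 2L, 1L))
  sp_xyz <- spacing[c(3L, 2L, 1L)]
  img <- RNifti::asNifti(structure(data, pixdim = sp_xyz),
                         datatype = datatype)
  or_xyz <- origin[c(3L, 2L, 1L)]
  xf <- rbind(cbind(diag(sp_xyz), or_xyz), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 1L)
  RNifti::writeNifti(img, path, datatype = datatype)
}

#' Read and write label maps as integer NIfTI
#'
#' Labels round-trip losslessly and are never renumbered. Reading a file with
#' non-integer voxel values as a label map is an error.
#'
#' @param lm a [label_map].
#' @param path a `.nii`/`.nii.gz` path.
#' @return `read_labelmap` returns a [label_map].
#' @export
write_labelmap <- function(lm, path) {
  if (!inherits(lm, "label_map")) stop("'lm' must be a label_map")
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path))
  }
  grid <- lm$grid
  if (length(dim(grid)) == 2L) grid <- array(grid, c(1L, dim(grid)))
  .write_nifti_array(grid, c(1, 1, 1), c(0, 0, 0), path, datatype = "int32")
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (any(arr != round(arr))) {
    stop("file contains non-integer values; not a label map: ", path)
  }
  label_map(aperm(arr, c(3L, 2L, 1L)))
}
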