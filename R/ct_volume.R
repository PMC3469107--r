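#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar grid in Hounsfield Units (HU) together with
#' its physical geometry. The axis convention used throughout the package is
#' axis 1 = slice (through-plane, z), axes 2-3 = in-plane (row, column), so a
#' volume is indexed `voxels[slice, row, col]`. Spacing is carried separately
#' in millimetres, in the same (slice, row, col) order.
#'
#' Voxel values are clipped to the plausible HU range \[-1100, 3100\]; values
#' outside (scanner padding, overflow) are clipped with a warning, never an
#' error.
#'
#' @param voxels numeric 3D array, HU. A matrix is promoted to a single-slice
#'   volume.
#' @param spacing numeric length-3, mm, for (slice, row, col); all > 0.
#' @param origin numeric length-3, mm; position of voxel (1,1,1).
#' @return An object of class `ct_volume` with elements `voxels`, `spacing`,
#'   `origin`.
#' @examples
#' v <- ct_volume(array(-1000, c(3, 32, 32)), spacing = c(2.5, 0.7, 0.7))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, c(1L, nrow(voxels), ncol(voxels)))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("'voxels' must be a 3D array (slice, row, col)")
  }
  storage.mode(voxels) <- "double"
  d <- dim(voxels)
  if (d[1] < 1L || d[2] < 16L || d[3] < 16L) {
    stop("volume must have >= 1 slice and >= 16x16 in-plane extent, got ",
         paste(d, collapse = "x"))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 positive finite values (mm)")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("'origin' must have length 3")
  n_out <- sum(voxels < HU_MIN | voxels > HU_MAX, na.rm = TRUE)
  if (n_out > 0L) {
    warning(n_out, " voxel(s) outside plausible HU range [", HU_MIN, ", ",
            HU_MAX, "] clipped")
    voxels[voxels < HU_MIN] <- HU_MIN
    voxels[voxels > HU_MAX] <- HU_MAX
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

HU_MIN <- -1100
HU_MAX <- 3100

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("ct_volume: ", d[1], " slices x ", d[2], "x", d[3], " in-plane\n",
      sep = "")
  cat(sprintf("  spacing (slice,row,col): %.4g x %.4g x %.4g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range: [%.0f, %.0f]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

is_ct_volume <- function(x) inherits(x, "ct_volume")

#' Binary mask aligned to a volume or slice
#'
#' Thin wrapper asserting a logical 2D/3D grid with values in \{0, 1\} only.
#' Masks are ordinary logical arrays; this constructor validates and coerces.
#'
#' @param grid logical (or 0/1 numeric) matrix or 3D array.
#' @return logical array of the same shape, class `binary_mask`.
#' @export
binary_mask <- function(grid) {
  if (is.logical(grid)) {
    g <- grid
  } else {
    if (!all(grid %in% c(0, 1, NA))) stop("mask values must be 0 or 1")
    g <- grid == 1
  }
  if (anyNA(g)) stop("mask must not contain NA")
  nd <- length(dim(g))
  if (is.null(dim(g)) || !(nd %in% c(2L, 3L))) {
    stop("mask must be a 2D or 3D grid")
  }
  class(g) <- c("binary_mask", class(g))
  g
}

as_mask_array <- function(a) {
  # strip class for arithmetic
  unclass(a)
}

#' Label map container
#'
#' Integer grid where 0 is background and each positive value labels one
#' connected component (or semantic class). Validates that every nonzero
#' value is listed in `labels`.
#'
#' @param grid integer 2D or 3D grid.
#' @param labels integer vector of positive identifiers; defaults to the
#'   distinct nonzero values present.
#' @return list of class `label_map` with elements `grid`, `labels`.
#' @export
label_map <- function(grid, labels = NULL) {
  if (is.null(dim(grid)) || !(length(dim(grid)) %in% c(2L, 3L))) {
    stop("label grid must be 2D or 3D")
  }
  if (any(grid != round(grid))) stop("label map must be integer-valued")
  storage.mode(grid) <- "integer"
  present <- sort(unique(grid[grid != 0L]))
  if (is.null(labels)) labels <- present
  labels <- as.integer(labels)
  if (any(labels <= 0L)) stop("labels must be positive integers")
  if (!all(present %in% labels)) {
    stop("grid contains values not in 'labels': ",
         paste(setdiff(present, labels), collapse = ", "))
  }
  structure(list(grid = grid, labels = labels), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("label_map: ", paste(dim(x$grid), collapse = "x"),
      " grid, ", length(x$labels), " label(s)\n", sep = "")
  invisible(x)
}

# Semantic class codes used by the segmentation stage.
LABEL_AIR <- 1L
LABEL_LUNG <- 2L
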