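#' Structuring elements
#'
#' A structuring element (SE) is a small binary shape with an anchor cell; it
#' probes a mask in the morphological operations. `struct_el` builds one from
#' a logical matrix, `se_disk2` returns the 2x2 disk used throughout the
#' segmentation stage (geometrically a full 2x2 square — the only discrete
#' realization of a disk at that size — anchored at its (1,1) cell), and
#' `reflect_se` negates the cell set about the anchor.
#'
#' @param grid logical matrix with at least one `TRUE` cell.
#' @param anchor integer (row, col) of the anchor, inside the grid.
#' @return An object of class `struct_el`.
#' @export
struct_el <- function(grid, anchor = c(1L, 1L)) {
  if (!is.matrix(grid)) stop("SE grid must be a matrix")
  grid <- grid != 0
  if (!any(grid)) stop("structuring element must have at least one true cell")
  anchor <- as.integer(anchor)
  if (anchor[1] < 1L || anchor[1] > nrow(grid) ||
      anchor[2] < 1L || anchor[2] > ncol(grid)) {
    stop("anchor must lie inside the SE grid")
  }
  structure(list(grid = grid, anchor = anchor), class = "struct_el")
}

#' @rdname struct_el
#' @export
se_disk2 <- function() struct_el(matrix(TRUE, 2, 2), anchor = c(1L, 1L))

#' @rdname struct_el
#' @param b a `struct_el`.
#' @export
reflect_se <- function(b) {
  stopifnot(inherits(b, "struct_el"))
  off <- se_offsets(b)
  se_from_offsets(-off)
}

#' @export
print.struct_el <- function(x, ...) {
  cat("struct_el ", nrow(x$grid), "x", ncol(x$grid), ", anchor (",
      x$anchor[1], ",", x$anchor[2], ")\n", sep = "")
  print(x$grid * 1L)
  invisible(x)
}

# (row, col) offsets of true cells relative to the anchor
se_offsets <- function(b) {
  w <- which(b$grid, arr.ind = TRUE)
  cbind(w[, 1] - b$anchor[1], w[, 2] - b$anchor[2])
}

# rebuild a SE from a set of offsets; anchor placed at offset (0,0)
se_from_offsets <- function(off) {
  off <- unique(off)
  rmin <- min(off[, 1], 0L); cmin <- min(off[, 2], 0L)
  g <- matrix(FALSE, max(off[, 1], 0L) - rmin + 1L,
              max(off[, 2], 0L) - cmin + 1L)
  g[cbind(off[, 1] - rmin + 1L, off[, 2] - cmin + 1L)] <- TRUE
  struct_el(g, anchor = c(1L - rmin, 1L - cmin))
}

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (dr > nr - 1L || dr < 1L - nr || dc > nc - 1L || dc < 1L - nc) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

check_mask2d <- function(a) {
  if (!is.matrix(a)) stop("mask must be a 2D logical matrix")
  a != 0
}

#' Binary dilation and erosion
#'
#' Set-theoretic binary morphology on 2D masks. Dilation of mask `A` by SE `B`
#' is the set of all sums `a + b` over cells `a` of `A` and offsets `b` of `B`
#' (relative to the anchor), cropped to the grid; erosion keeps the positions
#' `c` for which `c + b` lies in `A` for every offset `b`, with cells outside
#' the grid treated as background. When the anchor cell of `B` is true,
#' dilation is extensive (result contains `A`) and erosion anti-extensive.
#' The two are dual: `!erode(a, b) == dilate(!a, reflect_se(b))`.
#'
#' @param a logical 2D mask (matrix).
#' @param b a [struct_el].
#' @return Logical matrix of the same shape as `a`.
#' @export
dilate <- function(a, b) {
  a <- check_mask2d(a)
  stopifnot(inherits(b, "struct_el"))
  off <- se_offsets(b)
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mask(a, off[i, 1], off[i, 2])
  }
  out
}

#' @rdname dilate
#' @export
erode <- function(a, b) {
  a <- check_mask2d(a)
  stopifnot(inherits(b, "struct_el"))
  off <- se_offsets(b)
  out <- matrix(TRUE, nrow(a), ncol(a))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mask(a, -off[i, 1], -off[i, 2])
  }
  out
}

#' Structuring-element decomposition
#'
#' `dilate_se` forms the Minkowski sum of two structuring elements.
#' `erode_decomposed` applies the erosion chain rule: eroding by the composite
#' SE equals two successive erosions by its factors,
#' `erode(a, dilate_se(b, c)) == erode(erode(a, b), c)`, which lets a large
#' erosion be computed as a chain of smaller ones.
#'
#' @param a logical 2D mask.
#' @param b,c [struct_el]s.
#' @return `dilate_se` returns a `struct_el`; `erode_decomposed` a logical
#'   matrix.
#' @export
dilate_se <- function(b, c) {
  stopifnot(inherits(b, "struct_el"), inherits(c, "struct_el"))
  ob <- se_offsets(b); oc <- se_offsets(c)
  sums <- cbind(rep(ob[, 1], each = nrow(oc)) + rep(oc[, 1], nrow(ob)),
                rep(ob[, 2], each = nrow(oc)) + rep(oc[, 2], nrow(ob)))
  se_from_offsets(sums)
}

#' @rdname dilate_se
#' @export
erode_decomposed <- function(a, b, c) {
  erode(erode(a, b), c)
}

#' Morphological reconstruction from a marker
#'
#' Returns the union of the connected components of `mask` that contain at
#' least one cell of `marker` — whole components only. Works on 2D masks and
#' on 3D slice stacks. Marker cells outside the mask are dropped with a
#' warning. Reconstruction is implemented by component labeling; it is
#' equivalent to iterated conditional dilation of the marker inside the mask
#' until stability, and is idempotent.
#'
#' @param marker,mask logical arrays of identical shape (2D or 3D).
#' @param connectivity for 2D: 4 (edge-sharing) or 8 (default); for 3D: 6 or
#'   26 (default).
#' @return Logical array of the same shape.
#' @export
reconstruct <- function(marker, mask, connectivity = NULL) {
  if (!identical(dim(marker), dim(mask))) {
    stop("marker and mask must have identical shape")
  }
  marker <- marker != 0
  mask <- mask != 0
  if (any(marker & !mask)) {
    warning("marker cells outside the mask dropped")
    marker <- marker & mask
  }
  lab <- .label_binary(mask, connectivity)
  keep <- unique(lab[marker])
  keep <- keep[keep != 0L]
  out <- array(lab %in% keep, dim(mask))
  out
}

# label a logical 2D/3D array; 2D connectivity 4/8 maps onto 3D 6/26 with a
# single-slice embedding
.label_binary <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  if (length(d) == 2L) {
    if (is.null(connectivity)) connectivity <- 8L
    conn3 <- if (connectivity == 4L) 6L else if (connectivity == 8L) 26L else
      stop("2D connectivity must be 4 or 8")
    g <- array(mask, c(1L, d))
    lab <- .cc_label3d(g, conn3)
    array(lab, d)
  } else if (length(d) == 3L) {
    if (is.null(connectivity)) connectivity <- 26L
    if (!connectivity %in% c(6L, 26L)) stop("3D connectivity must be 6 or 26")
    .cc_label3d(array(mask, d), as.integer(connectivity))
  } else {
    stop("mask must be 2D or 3D")
  }
}

#' Fill enclosed holes in a 2D mask
#'
#' Background components not connected to the grid border are set true;
#' border-connected background (including holes that leak to the border
#' through a channel) is preserved. Implemented as complement, reconstruction
#' from a border marker, complement.
#'
#' @param a logical 2D mask.
#' @param connectivity background connectivity for the reconstruction, 4 or 8
#'   (default 8).
#' @return Logical matrix with holes filled. Idempotent.
#' @export
fill_holes <- function(a, connectivity = 8L) {
  a <- check_mask2d(a)
  comp <- !a
  border <- matrix(FALSE, nrow(a), ncol(a))
  border[1, ] <- TRUE; border[nrow(a), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(a)] <- TRUE
  marker <- comp & border
  if (!any(marker)) return(a | comp)  # no border background: all holes
  rec <- reconstruct(marker, comp, connectivity = connectivity)
  # rec is the border-connected background; everything else is body or hole
  matrix(!rec, nrow(a), ncol(a))
}
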