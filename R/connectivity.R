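#' Configuration for the 3D connectivity stage
#'
#' @param connectivity_3d 6 (face) or 26 (face+edge+corner, default —
#'   anisotropic slice spacing makes diagonal continuity common).
#' @param min_component_voxels components smaller than this are discarded as
#'   noise speckle (default 8; kept small so genuine trace air survives).
#' @param airway_seed `"auto"` seeds the tracheal lumen from the most cranial
#'   air-containing slice; `"none"` disables the seed.
#' @return Object of class `connectivity_config`.
#' @export
connectivity_config <- function(connectivity_3d = 26L,
                                min_component_voxels = 8L,
                                airway_seed = c("auto", "none")) {
  connectivity_3d <- as.integer(connectivity_3d)
  if (!connectivity_3d %in% c(6L, 26L)) stop("connectivity_3d must be 6 or 26")
  min_component_voxels <- as.integer(min_component_voxels)
  if (min_component_voxels < 1L) stop("min_component_voxels must be >= 1")
  airway_seed <- match.arg(airway_seed)
  structure(list(connectivity_3d = connectivity_3d,
                 min_component_voxels = min_component_voxels,
                 airway_seed = airway_seed),
            class = "connectivity_config")
}

#' Label 3D connected air components
#'
#' Extracts the AIR class from a 2D/3D label map and labels its connected
#' components in 3D (the stack of per-slice masks is treated as one 3D grid).
#' Per-component statistics — voxel count, centroid in (slice, row, col)
#' index coordinates, slice range — are returned alongside the component
#' label map. Exclusion fields are filled later by [exclude_external_air()].
#'
#' @param labels a [label_map] containing the AIR class (value 1).
#' @param cfg a [connectivity_config].
#' @return List with `components` (data.frame, one row per component) and
#'   `comp_map` (a [label_map] of component identifiers). No air voxels give
#'   an empty components table, not an error.
#' @export
label_air_components <- function(labels, cfg = connectivity_config()) {
  if (!inherits(labels, "label_map")) stop("'labels' must be a label_map")
  g <- labels$grid
  if (length(dim(g)) == 2L) g <- array(g, c(1L, dim(g)))
  air <- array(g == LABEL_AIR, dim(g))
  lab <- .cc_label3d(air, cfg$connectivity_3d)
  nlab <- max(lab)
  if (nlab == 0L) {
    comps <- data.frame(
      label = integer(0), voxel_count = integer(0),
      centroid_slice = numeric(0), centroid_row = numeric(0),
      centroid_col = numeric(0), slice_min = integer(0),
      slice_max = integer(0), touches_exterior = logical(0),
      touches_body_boundary = logical(0), excluded = logical(0),
      exclusion_reason = character(0), stringsAsFactors = FALSE
    )
    return(list(components = comps,
                comp_map = label_map(array(0L, dim(g)))))
  }
  idx <- which(lab != 0L)
  lv <- lab[idx]
  d <- dim(g)
  s <- ((idx - 1L) %% d[1]) + 1L
  r <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  cc <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  comps <- data.frame(
    label = seq_len(nlab),
    voxel_count = as.integer(tabulate(lv, nbins = nlab)),
    centroid_slice = as.numeric(tapply(s, lv, mean)),
    centroid_row = as.numeric(tapply(r, lv, mean)),
    centroid_col = as.numeric(tapply(cc, lv, mean)),
    slice_min = as.integer(tapply(s, lv, min)),
    slice_max = as.integer(tapply(s, lv, max)),
    touches_exterior = FALSE,
    touches_body_boundary = FALSE,
    excluded = FALSE,
    exclusion_reason = "none",
    stringsAsFactors = FALSE
  )
  list(components = comps, comp_map = label_map(lab))
}

# shift a 3D logical array by (ds, dr, dc), padding with FALSE
shift3 <- function(a, ds, dr, dc) {
  d <- dim(a)
  out <- array(FALSE, d)
  si <- max(1L, 1L + ds):min(d[1], d[1] + ds)
  ri <- max(1L, 1L + dr):min(d[2], d[2] + dr)
  ci <- max(1L, 1L + dc):min(d[3], d[3] + dc)
  if (ds >= d[1] || ds <= -d[1] || dr >= d[2] || dr <= -d[2] ||
      dc >= d[3] || dc <= -d[3]) return(out)
  out[si, ri, ci] <- a[si - ds, ri - dr, ci - dc, drop = FALSE]
  out
}

#' Exclude air continuous with spaces outside the pleural cavity
#'
#' A pneumothorax must have finite boundaries within the pleural cavity, so an
#' air component is excluded in full when it shows continuity with air spaces
#' outside the chest cavity, operationalized as:
#' \itemize{
#'   \item any voxel 26-adjacent to a non-body voxel, or lying on the
#'     volume's top/bottom slice face (trachea, esophagus or bowel entering
#'     the scanned range, or exterior air) — `exterior_connected`;
#'   \item connection to the airway seed: the component whose in-plane
#'     centroid, in the most cranial slice containing air, lies nearest the
#'     body-mask centroid of that slice (the tracheal lumen) — `airway_seed`;
#'   \item fewer than `min_component_voxels` voxels — `below_min_size`.
#' }
#' Exclusion is per whole component and never adds voxels; all surviving AIR
#' voxels constitute the pneumothorax mask.
#'
#' @param comps output of [label_air_components()].
#' @param labels the semantic [label_map] (AIR/LUNG) the components came from.
#' @param body logical 3D array, the stacked body masks.
#' @param cfg a [connectivity_config].
#' @return List with `labels` (pruned semantic [label_map]: excluded AIR
#'   voxels zeroed), `components` (data.frame with exclusion fields filled),
#'   and `ptx_mask` (logical 3D array of the surviving pneumothorax voxels).
#' @export
exclude_external_air <- function(comps, labels, body,
                                 cfg = connectivity_config()) {
  components <- comps$components
  lab <- comps$comp_map$grid
  g <- labels$grid
  if (length(dim(g)) == 2L) g <- array(g, c(1L, dim(g)))
  if (!identical(dim(body), dim(lab))) {
    stop("body mask shape must match the label map")
  }
  d <- dim(lab)
  if (nrow(components) == 0L) {
    return(list(labels = label_map(g, labels = c(LABEL_AIR, LABEL_LUNG)),
                components = components,
                ptx_mask = array(FALSE, d)))
  }

  # 26-neighbourhood of the non-body region
  nonbody <- body == 0
  near_nonbody <- nonbody
  for (ds in -1:1) for (dr in -1:1) for (dc in -1:1) {
    if (ds == 0 && dr == 0 && dc == 0) next
    near_nonbody <- near_nonbody | shift3(nonbody, ds, dr, dc)
  }
  touch_ids <- unique(lab[lab != 0L & near_nonbody])
  face_ids <- unique(c(lab[1, , ], lab[d[1], , ]))
  face_ids <- face_ids[face_ids != 0L]
  exterior <- components$label %in% c(touch_ids, face_ids)

  components$touches_body_boundary <- components$label %in% touch_ids
  components$touches_exterior <- exterior

  airway <- rep(FALSE, nrow(components))
  if (cfg$airway_seed == "auto") {
    top <- min(components$slice_min)
    in_top <- which(components$slice_min <= top & components$slice_max >= top)
    bslice <- body[top, , ]
    if (any(bslice) && length(in_top)) {
      bc <- c(mean(row(bslice)[bslice]), mean(col(bslice)[bslice]))
      lt <- lab[top, , ]
      dist <- vapply(in_top, function(i) {
        sel <- lt == components$label[i]
        sqrt((mean(row(lt)[sel]) - bc[1])^2 + (mean(col(lt)[sel]) - bc[2])^2)
      }, 0)
      airway[in_top[which.min(dist)]] <- TRUE
    }
  }
  small <- components$voxel_count < cfg$min_component_voxels

  components$excluded <- exterior | airway | small
  components$exclusion_reason <- ifelse(
    exterior, "exterior_connected",
    ifelse(airway, "airway_seed",
           ifelse(small, "below_min_size", "none"))
  )

  drop_ids <- components$label[components$excluded]
  pruned <- g
  pruned[lab %in% drop_ids] <- 0L
  ptx <- array(pruned == LABEL_AIR, d)
  list(labels = label_map(pruned, labels = c(LABEL_AIR, LABEL_LUNG)),
       components = components,
       ptx_mask = ptx)
}
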