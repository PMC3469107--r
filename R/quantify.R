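#' Physical volume of one voxel
#'
#' @param spacing numeric length-3 (slice, row, col) spacing in mm, all > 0.
#' @return Voxel volume in mm^3 (product of the three spacings).
#' @examples
#' voxel_volume(c(2.5, 0.7, 0.7))  # 1.225 mm^3
#' @export
voxel_volume <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)")
  }
  prod(spacing)
}

#' Volumetric pneumothorax measurement
#'
#' Converts a pruned AIR/LUNG label map into physical volumes and the relative
#' pneumothorax size `v_ptx = V_air / (V_air + V_lung)`. `V_air` counts the
#' surviving (pneumothorax) AIR voxels; `V_lung` counts parenchyma-labeled
#' voxels only — vessels excluded by thresholding stay excluded, so the ratio
#' is slightly biased versus manual pleural-region contours. If no air or lung
#' voxels remain, `v_ptx` is 0 with a warning.
#'
#' @param labels a [label_map] with AIR (1) and LUNG (2) classes, already
#'   pruned by [exclude_external_air()].
#' @param spacing voxel spacing, mm (slice, row, col).
#' @param thresholds the [threshold_set] actually used (provenance).
#' @param n_kept,n_excluded component counts from the connectivity stage.
#' @return Object of class `volume_report` with `v_air`, `v_lung` (mm^3),
#'   `v_ptx` (fraction in \[0, 1\]), `thresholds_used`, `n_components_kept`,
#'   `n_components_excluded`.
#' @export
measure <- function(labels, spacing, thresholds = NULL,
                    n_kept = NA_integer_, n_excluded = NA_integer_) {
  if (!inherits(labels, "label_map")) stop("'labels' must be a label_map")
  if (missing(spacing) || is.null(spacing)) stop("spacing is required")
  vv <- voxel_volume(spacing)
  n_air <- sum(labels$grid == LABEL_AIR)
  n_lung <- sum(labels$grid == LABEL_LUNG)
  v_air <- n_air * vv
  v_lung <- n_lung * vv
  if (v_air + v_lung > 0) {
    v_ptx <- v_air / (v_air + v_lung)
  } else {
    warning("no air or lung voxels: v_ptx reported as 0")
    v_ptx <- 0
  }
  structure(list(v_air = v_air, v_lung = v_lung, v_ptx = v_ptx,
                 thresholds_used = thresholds,
                 n_components_kept = as.integer(n_kept),
                 n_components_excluded = as.integer(n_excluded)),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat("volume_report\n")
  cat(sprintf("  V_air : %12.2f mm^3\n", x$v_air))
  cat(sprintf("  V_lung: %12.2f mm^3\n", x$v_lung))
  cat(sprintf("  V_ptx : %.2f%%\n", 100 * x$v_ptx))
  if (!is.na(x$n_components_kept)) {
    cat(sprintf("  components kept/excluded: %d/%d\n",
                x$n_components_kept, x$n_components_excluded))
  }
  if (!is.null(x$thresholds_used)) print(x$thresholds_used)
  invisible(x)
}

#' Serialize a volume report to JSON
#'
#' Fixed key names; percentage reported to 2 decimals.
#'
#' @param x a `volume_report`.
#' @param path optional file to write; if `NULL` the JSON string is returned.
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "volume_report"))
  obj <- list(
    v_air_mm3 = x$v_air,
    v_lung_mm3 = x$v_lung,
    v_ptx = x$v_ptx,
    v_ptx_pct = round(100 * x$v_ptx, 2),
    n_components_kept = x$n_components_kept,
    n_components_excluded = x$n_components_excluded,
    thresholds = if (is.null(x$thresholds_used)) NULL else
      list(th_m = x$thresholds_used$th_m, th_a = x$thresholds_used$th_a,
           th_l = x$thresholds_used$th_l, source = x$thresholds_used$source)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else {
    js
  }
}
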