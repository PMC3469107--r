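#' Run the full pneumothorax quantification pipeline
#'
#' Executes the stages in order: per-slice Gaussian smoothing, body-mask
#' extraction at `th_m` with hole filling, adaptive threshold estimation from
#' the masked whole-volume histogram (optional), two-class air/lung labeling,
#' 3D connected-component labeling of air, exclusion of air continuous with
#' spaces outside the pleural cavity, and volumetric measurement. The pipeline
#' is a pure function of (input volume, configuration); identical inputs give
#' identical reports.
#'
#' @param input a [ct_volume] or a path readable by [read_volume()].
#' @param out_dir optional output directory (created if absent); if given, the
#'   JSON report, the final pneumothorax mask (NIfTI), and a run log naming
#'   the thresholds actually used are written there.
#' @param thresholds a [threshold_set] of defaults/overrides.
#' @param adaptive estimate `th_a`/`th_l` from the volume's histogram
#'   (default `TRUE`); on fallback or `FALSE` the fixed values are used.
#' @param smoothing a [smoothing_params].
#' @param connectivity a [connectivity_config].
#' @param case_id identifier used in messages and the log.
#' @param verbose print stage progress to stderr.
#' @return List with `report` (a `volume_report`), `thresholds`, `components`
#'   (the air-component table), `labels` (pruned [label_map]), `ptx_mask`,
#'   and `body` (the stacked body mask).
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         thresholds = threshold_set(),
                         adaptive = TRUE,
                         smoothing = smoothing_params(),
                         connectivity = connectivity_config(),
                         case_id = "case", verbose = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", case_id, "] stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  say <- function(...) if (verbose) message("[", case_id, "] ", ...)

  vol <- stage("read", {
    if (is_ct_volume(input)) input else read_volume(input)
  })
  d <- dim(vol$voxels)

  say("smoothing ", d[1], " slices")
  sm <- stage("smooth", {
    out <- vol$voxels
    for (z in seq_len(d[1])) {
      out[z, , ] <- gaussian_smooth(vol$voxels[z, , ], smoothing)
    }
    ct_volume(out, spacing = vol$spacing, origin = vol$origin)
  })

  say("extracting body mask")
  body <- stage("body_mask", {
    b <- array(FALSE, d)
    for (z in seq_len(d[1])) {
      b[z, , ] <- suppressWarnings(body_mask(sm$voxels[z, , ], thresholds))
    }
    b
  })

  th <- stage("thresholds", {
    if (adaptive && any(body)) {
      estimate_thresholds(sm, body, defaults = thresholds)
    } else {
      thresholds
    }
  })
  say(sprintf("thresholds (%s): th_a = %.1f, th_l = %.1f HU",
              th$source, th$th_a, th$th_l))

  labels <- stage("classify", classify_air_lung(sm, body, th))
  comps <- stage("label_components", label_air_components(labels, connectivity))
  say(nrow(comps$components), " air component(s)")
  pruned <- stage("exclude",
                  exclude_external_air(comps, labels, body, connectivity))
  n_excl <- sum(pruned$components$excluded)
  say(n_excl, " component(s) excluded")

  report <- stage("measure", {
    measure(pruned$labels, vol$spacing, thresholds = th,
            n_kept = nrow(pruned$components) - n_excl, n_excluded = n_excl)
  })

  if (!is.null(out_dir)) {
    stage("write", {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      report_json(report, file.path(out_dir, "report.json"))
      .write_nifti_array(array(as.integer(pruned$ptx_mask), d), vol$spacing,
                         vol$origin, file.path(out_dir, "ptx_mask.nii.gz"),
                         datatype = "int32")
      log <- c(
        paste0("case: ", case_id),
        paste0("shape: ", paste(d, collapse = "x")),
        paste0("spacing_mm: ", paste(vol$spacing, collapse = "x")),
        sprintf("thresholds: th_m=%g th_a=%g th_l=%g (%s)",
                th$th_m, th$th_a, th$th_l, th$source),
        sprintf("smoothing: sigma=%g size=%dx%d", smoothing$sigma,
                smoothing$size[1], smoothing$size[2]),
        sprintf("connectivity: %d min_voxels=%d airway_seed=%s",
                connectivity$connectivity_3d,
                connectivity$min_component_voxels, connectivity$airway_seed),
        sprintf("components_kept: %d excluded: %d",
                report$n_components_kept, report$n_components_excluded),
        sprintf("v_ptx_pct: %.2f", 100 * report$v_ptx)
      )
      writeLines(log, file.path(out_dir, "run_log.txt"))
    })
  }

  list(report = report, thresholds = th, components = pruned$components,
       labels = pruned$labels, ptx_mask = pruned$ptx_mask, body = body)
}
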