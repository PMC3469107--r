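# Ground-truth class codes for phantom label maps. PTX and LUNG share the
# AIR/LUNG codes of the segmentation stage so truth and prediction align.
PHANTOM_PTX <- 1L
PHANTOM_LUNG <- 2L
PHANTOM_AIRWAY <- 3L
PHANTOM_BOWEL <- 4L
PHANTOM_BODY <- 5L

#' Specification of a synthetic thorax phantom
#'
#' The phantom emulates a chest CT cross-section: a soft-tissue body ellipse
#' surrounded by exterior air, two elliptic-cylinder lungs of parenchyma, a
#' vertebral bone disk, an optional tracheal air tube that always reaches the
#' top slice face, an optional sub-diaphragmatic bowel-gas pocket reaching the
#' bottom slice face, and an optional pleural air crescent carved from the
#' outer shell of one lung so that the ground-truth relative pneumothorax
#' volume matches `ptx_fraction` to well under half a percentage point.
#' Voxel values are class means plus additive Gaussian noise.
#'
#' @param shape grid (slices, rows, cols); default 40 x 128 x 128.
#' @param spacing mm (slice, row, col); default 2.5 x 0.7 x 0.7, typical of
#'   chest CT reconstructed at 2.5 mm increments.
#' @param ptx_fraction target relative pneumothorax volume in \[0, 0.6\]
#'   (values beyond the largest carvable crescent are rejected).
#' @param ptx_side `"right"` or `"left"`.
#' @param include_trachea,include_bowel_gas logical, both default `TRUE`.
#' @param noise_sd additive Gaussian noise, HU (default 20).
#' @param hu_means named list of class means, HU.
#' @param seed integer RNG seed for the noise field.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40L, 128L, 128L),
                         spacing = c(2.5, 0.7, 0.7),
                         ptx_fraction = 0,
                         ptx_side = c("right", "left"),
                         include_trachea = TRUE,
                         include_bowel_gas = TRUE,
                         noise_sd = 20,
                         hu_means = list(exterior = -1000, body = 40,
                                         parenchyma = -850, air = -1000,
                                         bone = 700),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(8L, 32L, 32L))) {
    stop("phantom shape must be at least 8 x 32 x 32")
  }
  if (!is.finite(ptx_fraction) || ptx_fraction < 0 || ptx_fraction > 0.6) {
    stop("ptx_fraction must lie in [0, 0.6]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 ptx_fraction = ptx_fraction,
                 ptx_side = match.arg(ptx_side),
                 include_trachea = isTRUE(include_trachea),
                 include_bowel_gas = isTRUE(include_bowel_gas),
                 noise_sd = noise_sd, hu_means = hu_means,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Select n_cells in-plane cells of mask2, preferring high scores, as one
# 8-connected footprint: take the top-scoring cells, then swap any detached
# staircase strays for the best-scoring cells adjacent to the main region.
.carve_cells <- function(score, mask2, n_cells) {
  idx <- which(mask2)
  sel <- idx[order(-score[idx], idx)][seq_len(n_cells)]
  box3 <- struct_el(matrix(TRUE, 3, 3), anchor = c(2L, 2L))
  for (pass in 1:20) {
    fp <- matrix(FALSE, nrow(score), ncol(score))
    fp[sel] <- TRUE
    lab <- .label_binary(fp, 8L)
    if (max(lab) <= 1L) break
    sizes <- tabulate(lab[lab > 0L])
    main <- which.max(sizes)
    strays <- sel[lab[sel] != main]
    sel <- setdiff(sel, strays)
    for (i in seq_along(strays)) {
      fp <- matrix(FALSE, nrow(score), ncol(score))
      fp[sel] <- TRUE
      cand <- which(dilate(fp, box3) & mask2 & !fp)
      if (!length(cand)) break
      sel <- c(sel, cand[order(-score[cand], cand)][1])
    }
  }
  sel
}

# in-plane squared elliptical radius for every (row, col) of a slice
.ellipse_rho2 <- function(nr, nc, cr, cc, ar, ac) {
  r <- (seq_len(nr) - cr) / ar
  c <- (seq_len(nc) - cc) / ac
  outer(r^2, c^2, `+`)
}

#' Generate a synthetic thorax phantom
#'
#' Deterministic for a fixed seed: the same spec renders bit-identical
#' volumes. The achieved pneumothorax fraction is computed from the noiseless
#' geometry (carved air voxels over carved air plus remaining parenchyma).
#'
#' @param spec a [phantom_spec].
#' @return List with `volume` (a [ct_volume]), `truth` (a [label_map] with
#'   classes PTX = 1, LUNG = 2, AIRWAY = 3, BOWEL = 4, BODY = 5),
#'   `achieved_ptx_fraction`, and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  nz <- spec$shape[1]; nr <- spec$shape[2]; nc <- spec$shape[3]

  body2 <- .ellipse_rho2(nr, nc, 0.5 * nr, 0.5 * nc,
                         0.39 * nr, 0.453 * nc) <= 1
  lung_cr <- 0.52 * nr
  lung_ar <- 0.203 * nr
  lung_ac <- 0.141 * nc
  rho_l <- .ellipse_rho2(nr, nc, lung_cr, 0.3125 * nc, lung_ar, lung_ac)
  rho_r <- .ellipse_rho2(nr, nc, lung_cr, 0.6875 * nc, lung_ar, lung_ac)
  lung2_l <- rho_l <= 1
  lung2_r <- rho_r <= 1
  trachea2 <- .ellipse_rho2(nr, nc, 0.4375 * nr, 0.5 * nc,
                            0.0234 * nc, 0.0234 * nc) <= 1
  bowel2 <- .ellipse_rho2(nr, nc, 0.55 * nr, 0.39 * nc,
                          0.0625 * nc, 0.0625 * nc) <= 1
  bone2 <- .ellipse_rho2(nr, nc, 0.82 * nr, 0.5 * nc,
                         0.047 * nc, 0.047 * nc) <= 1

  z_lung <- max(2L, round(0.15 * nz)):round(0.85 * nz)
  z_trachea <- 1L:round(0.25 * nz)
  z_bowel <- round(0.9 * nz):nz

  truth <- array(0L, c(nz, nr, nc))
  for (z in seq_len(nz)) truth[z, , ][body2] <- PHANTOM_BODY
  for (z in z_lung) {
    truth[z, , ][lung2_l] <- PHANTOM_LUNG
    truth[z, , ][lung2_r] <- PHANTOM_LUNG
  }
  if (spec$include_trachea) {
    for (z in z_trachea) truth[z, , ][trachea2] <- PHANTOM_AIRWAY
  }
  if (spec$include_bowel_gas) {
    for (z in z_bowel) truth[z, , ][bowel2] <- PHANTOM_BOWEL
  }

  # carve the pleural crescent between the lung surface and the chest wall:
  # voxels of the chosen lung are ranked by the score rho^2 + lateral offset,
  # whose level sets are crescents hugging the lateral lung boundary (and
  # wrapping around the lung as they grow, the morphology of a large
  # pneumothorax); the k top-ranked voxels are carved, where k / (total lung
  # voxels) equals the requested fraction -- v_ptx = k / N is exact by
  # construction because carved voxels leave the parenchyma count as they
  # enter the air count
  achieved <- 0
  if (spec$ptx_fraction > 0) {
    lateral <- if (spec$ptx_side == "right") {
      (seq_len(nc) - 0.6875 * nc) / lung_ac
    } else {
      -(seq_len(nc) - 0.3125 * nc) / lung_ac
    }
    rho_side2 <- if (spec$ptx_side == "right") rho_r else rho_l
    score <- rho_side2 + matrix(lateral, nr, nc, byrow = TRUE)
    side2 <- rho_side2 <= 1
    nzl <- length(z_lung)
    n_total <- sum(truth == PHANTOM_LUNG)
    k <- round(spec$ptx_fraction * n_total)
    if (k > sum(side2) * nzl) {
      stop(sprintf(
        "infeasible ptx_fraction %.3f: maximum carvable fraction is %.3f",
        spec$ptx_fraction, sum(side2) * nzl / n_total))
    }
    if (k > 0L) {
      m <- k %/% nzl
      rem <- k %% nzl
      cells <- .carve_cells(score, side2, m + (rem > 0L))
      full <- if (rem > 0L) {
        partial <- cells[which.min(score[cells])]
        setdiff(cells, partial)
      } else {
        cells
      }
      fp <- matrix(FALSE, nr, nc)
      fp[full] <- TRUE
      for (z in z_lung) truth[z, , ][fp] <- PHANTOM_PTX
      if (rem > 0L) {
        for (z in z_lung[seq_len(rem)]) truth[z, , ][partial] <- PHANTOM_PTX
      }
    }
    achieved <- k / n_total
  }

  hu <- array(spec$hu_means$exterior, c(nz, nr, nc))
  hu[truth == PHANTOM_BODY] <- spec$hu_means$body
  hu[truth == PHANTOM_LUNG] <- spec$hu_means$parenchyma
  hu[truth == PHANTOM_PTX] <- spec$hu_means$air
  hu[truth == PHANTOM_AIRWAY] <- spec$hu_means$air
  hu[truth == PHANTOM_BOWEL] <- spec$hu_means$air
  for (z in seq_len(nz)) {
    sl <- hu[z, , ]
    sl[bone2 & body2] <- spec$hu_means$bone
    hu[z, , ] <- sl
  }
  # bone sits inside the body; keep its truth class as BODY

  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd), dim(hu))
    # clamp rare noise excursions to the scanner-plausible HU range
    hu[hu < -1100] <- -1100
    hu[hu > 3100] <- 3100
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }

  list(volume = ct_volume(hu, spacing = spec$spacing),
       truth = label_map(truth),
       achieved_ptx_fraction = achieved,
       spec = spec)
}

#' Published-cohort-like pneumothorax fractions
#'
#' The eight manually measured relative pneumothorax sizes of the benchmark
#' cohort, as fractions — spanning normal (0) through large (~0.35). Used as
#' the default preset for [generate_cohort()].
#'
#' @return numeric vector of length 8.
#' @export
ptx_fraction_preset <- function() {
  table1_preset()$ref_pct / 100
}

#' Generate a cohort of phantoms
#'
#' One phantom per requested fraction; case `i` uses seed `seed + i - 1`, so
#' geometry depends only on the fraction while noise fields differ per case.
#'
#' @param n number of cases.
#' @param fractions target pneumothorax fractions, length `n`.
#' @param seed base RNG seed.
#' @param ... further arguments passed to [phantom_spec()].
#' @return List of `n` phantom cases (see [generate_phantom()]).
#' @export
generate_cohort <- function(n = 8L, fractions = ptx_fraction_preset(),
                            seed = 1L, ...) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (length(fractions) != n) {
    stop("length(fractions) must equal n (", n, "), got ", length(fractions))
  }
  lapply(seq_len(n), function(i) {
    generate_phantom(phantom_spec(ptx_fraction = fractions[i],
                                  seed = seed + i - 1L, ...))
  })
}
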