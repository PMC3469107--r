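#' Threshold set for air/lung segmentation
#'
#' Three HU cutoffs drive the 2D stage: `th_m` extracts the body mask (voxels
#' at or above it are body candidates), and `th_a` / `th_l` split voxels
#' inside the body into air (below `th_a`), lung parenchyma (in
#' `[th_a, th_l)`) and everything else. Air is darkest, so `th_a < th_l` is
#' required; `th_m` governs a separate masking step and is not ordered against
#' them. Defaults are the fixed cutoffs -500 / -870 / -200 HU; the adaptive
#' estimator ([estimate_thresholds()]) replaces `th_a` and `th_l` per volume.
#'
#' @param th_m body-mask cutoff, HU.
#' @param th_a air cutoff, HU.
#' @param th_l lung-parenchyma cutoff, HU.
#' @param source `"fixed_default"` or `"histogram_estimated"`.
#' @return Object of class `threshold_set`.
#' @export
threshold_set <- function(th_m = -500, th_a = -870, th_l = -200,
                          source = c("fixed_default", "histogram_estimated")) {
  source <- match.arg(source)
  if (!is.finite(th_m) || !is.finite(th_a) || !is.finite(th_l)) {
    stop("thresholds must be finite")
  }
  if (!(th_a < th_l)) {
    stop("incoherent thresholds: require th_a < th_l (air is darkest), got ",
         th_a, " >= ", th_l)
  }
  structure(list(th_m = th_m, th_a = th_a, th_l = th_l, source = source),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set (%s): th_m = %g, th_a = %g, th_l = %g HU\n",
              x$source, x$th_m, x$th_a, x$th_l))
  invisible(x)
}

#' Gaussian smoothing parameters
#'
#' @param sigma standard deviation in pixels, > 0. Default 0.5.
#' @param size kernel extent (rows, cols); a scalar is recycled. Default 5x5.
#' @return Object of class `smoothing_params`.
#' @export
smoothing_params <- function(sigma = 0.5, size = c(5L, 5L)) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  size <- as.integer(rep(size, length.out = 2L))
  if (any(size < 1L)) stop("kernel size must be >= 1")
  structure(list(sigma = sigma, size = size), class = "smoothing_params")
}

# the discretized, renormalized Gaussian kernel
gaussian_kernel <- function(p) {
  hr <- (p$size[1] - 1) / 2
  hc <- (p$size[2] - 1) / 2
  x <- seq_len(p$size[1]) - 1 - hr
  y <- seq_len(p$size[2]) - 1 - hc
  k <- outer(x, y, function(u, v) exp(-(u^2 + v^2) / (2 * p$sigma^2)))
  k / sum(k)
}

#' Smooth a CT slice with a small Gaussian kernel
#'
#' Convolution with the discretized, renormalized Gaussian
#' `g(x, y) = exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)`, sampled on
#' the kernel grid and rescaled to unit sum, using a reflective (symmetric)
#' boundary. A constant slice passes through unchanged.
#'
#' @param slice numeric matrix, HU.
#' @param p a [smoothing_params].
#' @return Numeric matrix of the same shape.
#' @export
gaussian_smooth <- function(slice, p = smoothing_params()) {
  if (!inherits(p, "smoothing_params")) stop("'p' must be smoothing_params")
  if (!is.matrix(slice)) stop("'slice' must be a matrix")
  k <- gaussian_kernel(p)
  hr <- (p$size[1] - 1L) %/% 2L
  hc <- (p$size[2] - 1L) %/% 2L
  nr <- nrow(slice); nc <- ncol(slice)
  ridx <- c(rev(seq_len(hr)), seq_len(nr), nr - seq_len(p$size[1] - 1L - hr) + 1L)
  cidx <- c(rev(seq_len(hc)), seq_len(nc), nc - seq_len(p$size[2] - 1L - hc) + 1L)
  pad <- slice[ridx, cidx, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(p$size[1])) {
    for (j in seq_len(p$size[2])) {
      out <- out + k[i, j] * pad[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
    }
  }
  out
}

#' Extract the body mask from a smoothed slice
#'
#' Thresholds at `th_m` (voxel >= `th_m` is body candidate), then fills
#' enclosed holes so that lung parenchyma and air pockets inside the thorax
#' stay within the mask while exterior (border-connected) air is excluded.
#' An all-air slice yields an empty mask with a warning, not an error.
#'
#' @param slice numeric matrix, HU, already smoothed.
#' @param t a [threshold_set].
#' @return Logical matrix.
#' @export
body_mask <- function(slice, t = threshold_set()) {
  if (!inherits(t, "threshold_set")) stop("'t' must be a threshold_set")
  m <- slice >= t$th_m
  if (!any(m)) {
    warning("empty body mask: no voxel at or above th_m = ", t$th_m, " HU")
    return(m)
  }
  fill_holes(m)
}

# 10-HU-wide histogram over the range relevant to air/lung/soft tissue
HIST_RANGE <- c(-1100, 300)
HIST_BIN <- 10

#' Adaptive threshold estimation from the masked HU histogram
#'
#' Builds the histogram of in-mask voxels (10-HU bins over \[-1100, 300\]),
#' locates the intensity modes (local maxima with at least 1% of total mass,
#' at least 50 HU apart), and — when both a lung-parenchyma mode (in
#' \[-950, -400)) and a soft-tissue mode (at or above -300 HU) are present —
#' derives the two cutoffs:
#' \itemize{
#'   \item `th_a` sits at the lower edge of the parenchyma mode (interpolated
#'     mode position minus 2.5 times its width, estimated from the FWHM with
#'     Sheppard's correction for the bin width), clamped to lie above any
#'     detected air mode. Hugging the parenchyma mode, rather than cutting at
#'     the air/parenchyma valley, assigns partial-volume voxels on air
#'     interfaces to the air class, which preserves thin pleural air
#'     collections; an air mode is not required, because a small pneumothorax
#'     contributes too little mass to raise one.
#'   \item `th_l` sits at the histogram valley between the parenchyma and
#'     soft-tissue modes (a flat valley run is cut at its middle bin); the
#'     inter-mode region there is nearly empty, so any cut in the gap labels
#'     the same voxels.
#' }
#' If the histogram is not bimodal-or-better in this sense, the estimator
#' falls back to the fixed defaults and tags `source = "fixed_default"`.
#'
#' The estimator sees only the histogram, so it is invariant to voxel
#' shuffling; thresholds are estimated once per volume, not per slice.
#'
#' @param volume a [ct_volume].
#' @param mask logical array, same shape as the volume (body mask stack).
#' @param defaults a [threshold_set] supplying `th_m` and the fallbacks.
#' @return A [threshold_set] with `source` recording the outcome.
#' @export
estimate_thresholds <- function(volume, mask, defaults = threshold_set()) {
  if (!is_ct_volume(volume)) stop("'volume' must be a ct_volume")
  if (!identical(dim(mask), dim(volume$voxels))) {
    stop("mask shape must match the volume")
  }
  if (!any(mask)) stop("empty mask: cannot estimate thresholds")
  v <- volume$voxels[mask != 0]
  v <- v[v >= HIST_RANGE[1] & v < HIST_RANGE[2]]
  breaks <- seq(HIST_RANGE[1], HIST_RANGE[2], by = HIST_BIN)
  counts <- tabulate(findInterval(v, breaks), nbins = length(breaks) - 1L)
  centers <- breaks[-length(breaks)] + HIST_BIN / 2
  peaks <- .find_modes(counts)
  par_cand <- peaks[centers[peaks] >= -950 & centers[peaks] < -400]
  tis_cand <- peaks[centers[peaks] >= -300]
  if (!length(par_cand) || !length(tis_cand)) {
    return(threshold_set(defaults$th_m, defaults$th_a, defaults$th_l,
                         source = "fixed_default"))
  }
  m_p <- par_cand[which.max(counts[par_cand])]  # lung parenchyma mode
  m_t <- tis_cand[which.max(counts[tis_cand])]  # soft-tissue mode
  pm <- .mode_fit(counts, centers, m_p)
  th_a <- pm$mu - 2.5 * pm$sigma
  air_cand <- peaks[centers[peaks] < centers[m_p] - 50]
  lo <- if (length(air_cand)) {
    centers[air_cand[which.max(counts[air_cand])]] + HIST_BIN
  } else {
    HIST_RANGE[1]
  }
  th_a <- min(max(th_a, lo), centers[m_p] - HIST_BIN)
  th_l <- .valley_cut(counts, centers, m_p, m_t)
  threshold_set(defaults$th_m, th_a, th_l, source = "histogram_estimated")
}

# interpolated position and width of a histogram mode: log-parabolic vertex
# through the peak bin and its neighbours, sigma from the full width at half
# maximum (floored at the resolution a single bin can support)
.mode_fit <- function(counts, centers, i) {
  n <- length(counts)
  mu <- centers[i]
  if (i > 1L && i < n && counts[i - 1L] > 0 && counts[i + 1L] > 0) {
    ly <- log(counts[(i - 1L):(i + 1L)])
    denom <- ly[1] - 2 * ly[2] + ly[3]
    if (denom < 0) mu <- centers[i] + HIST_BIN * 0.5 * (ly[1] - ly[3]) / denom
  }
  half <- counts[i] / 2
  # walk out to the half-maximum crossings, interpolating linearly
  lo <- i
  while (lo > 1L && counts[lo - 1L] > half) lo <- lo - 1L
  x_lo <- if (lo == 1L) centers[1] else {
    centers[lo] - HIST_BIN * (counts[lo] - half) / (counts[lo] - counts[lo - 1L])
  }
  hi <- i
  while (hi < n && counts[hi + 1L] > half) hi <- hi + 1L
  x_hi <- if (hi == n) centers[n] else {
    centers[hi] + HIST_BIN * (counts[hi] - half) / (counts[hi] - counts[hi + 1L])
  }
  # Sheppard's correction removes the variance the binning itself adds
  sig2 <- ((x_hi - x_lo) / 2.355)^2 - HIST_BIN^2 / 12
  sigma <- max(sqrt(max(sig2, 0)), HIST_BIN / 2.355)
  list(mu = mu, sigma = sigma)
}

# local maxima with prominence >= 1% of total mass and >= 50 HU separation
.find_modes <- function(counts) {
  n <- length(counts)
  total <- sum(counts)
  if (total == 0L) return(integer(0))
  lo <- c(0L, counts[-n])
  hi <- c(counts[-1], 0L)
  cand <- which(counts >= lo & counts >= hi & counts >= 0.01 * total)
  if (!length(cand)) return(integer(0))
  # collapse plateau runs to their middle bin
  runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
  cand <- vapply(runs, function(r) r[ceiling(length(r) / 2)], 0L)
  # enforce minimum separation: greedily keep tallest peaks first
  ord <- cand[order(-counts[cand], cand)]
  kept <- integer(0)
  min_sep <- ceiling(50 / HIST_BIN)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

# histogram valley between two peak bins; ties resolved at the run middle
.valley_cut <- function(counts, centers, i, j) {
  stopifnot(i < j)
  between <- (i + 1L):(j - 1L)
  if (!length(between)) return(mean(centers[c(i, j)]))
  cmin <- min(counts[between])
  run <- between[counts[between] == cmin]
  centers[run[ceiling(length(run) / 2)]]
}

#' Two-class air/lung labeling inside the body mask
#'
#' Within the body mask only: voxels below `th_a` are labeled AIR (1), voxels
#' in `[th_a, th_l)` are labeled LUNG (2), all others 0. A voxel exactly at
#' `th_a` is LUNG (boundaries assign upward); outside the body mask the label
#' is always 0. Raising `th_a` can only move voxels from AIR to LUNG.
#'
#' @param volume a [ct_volume] (smoothed).
#' @param body logical array, same shape, the stacked body masks.
#' @param t a [threshold_set] with coherent `th_a < th_l`.
#' @return A [label_map] with classes AIR = 1, LUNG = 2.
#' @export
classify_air_lung <- function(volume, body, t) {
  if (!is_ct_volume(volume)) stop("'volume' must be a ct_volume")
  if (!inherits(t, "threshold_set")) stop("'t' must be a threshold_set")
  if (!identical(dim(body), dim(volume$voxels))) {
    stop("body mask shape must match the volume")
  }
  v <- volume$voxels
  g <- array(0L, dim(v))
  inb <- body != 0
  g[inb & v < t$th_a] <- LABEL_AIR
  g[inb & v >= t$th_a & v < t$th_l] <- LABEL_LUNG
  label_map(g, labels = c(LABEL_AIR, LABEL_LUNG))
}
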