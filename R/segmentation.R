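#' Segmentation parameters
#'
#' Controls for [segment_aggregate()]. Defaults were chosen to segment
#' DAPI images of single aggregates robustly: 200 Chan-Vese iterations
#' with one smoothing pass per iteration, an initial disk covering 25% of
#' the frame area, a 2-pixel opening radius, and a minimum accepted area
#' of 100 pixels.
#'
#' @param iterations maximum Chan-Vese iterations (>= 1).
#' @param smoothing number of boundary-smoothing passes per iteration
#'   (0 disables smoothing).
#' @param init_frac area fraction of the frame covered by the initial
#'   centred disk.
#' @param opening_radius radius (px) of the final morphological opening.
#' @param min_area minimum mask area (px) below which segmentation fails.
#' @return a `seg_params` list.
#' @export
seg_params <- function(iterations = 200, smoothing = 1, init_frac = 0.25,
                       opening_radius = 2, min_area = 100) {
  stopifnot(iterations >= 1, smoothing >= 0, init_frac > 0, init_frac < 1,
            opening_radius >= 0, min_area >= 0)
  structure(list(iterations = as.integer(iterations),
                 smoothing = as.integer(smoothing),
                 init_frac = init_frac,
                 opening_radius = opening_radius,
                 min_area = min_area),
            class = "seg_params")
}

# 3x3 neighbourhood sum of a binary matrix (replicated edges), via
# column/row running sums; the binary median is then sum >= 5.
box3_sum <- function(u) {
  n <- nrow(u); m <- ncol(u)
  up <- u[c(1, 1:(n - 1)), , drop = FALSE]
  dn <- u[c(2:n, n), , drop = FALSE]
  v <- up + u + dn
  v[, c(1, 1:(m - 1)), drop = FALSE] + v + v[, c(2:m, m), drop = FALSE]
}

binary_median3 <- function(u) (box3_sum(u) >= 5) * 1

# Chan-Vese two-phase active contour, morphological scheme: boundary
# pixels switch phase by the sign of (I-c1)^2 - (I-c2)^2, followed by a
# 3x3 binary median acting as the curvature-smoothing operator.
chan_vese <- function(img, u, iterations, smoothing) {
  for (it in seq_len(iterations)) {
    inside <- u > 0.5
    if (!any(inside) || all(inside)) break
    c1 <- mean(img[inside]); c2 <- mean(img[!inside])
    s3 <- box3_sum(u)
    band <- s3 > 0 & s3 < 9  # pixels with both phases in their 3x3 patch
    f <- (img - c1)^2 - (img - c2)^2
    un <- u
    un[band & f < 0] <- 1
    un[band & f > 0] <- 0
    if (smoothing > 0)
      for (s in seq_len(smoothing)) un <- binary_median3(un)
    if (it %% 5 == 0 && identical(un, u)) { u <- un; break }
    u <- un
  }
  u
}

#' Segment an aggregate from the DAPI channel
#'
#' Automatic segmentation: a Chan-Vese active contour evolved from a
#' centred disk separates the bright (nucleus-dense) aggregate from the
#' background, after which the largest connected component is kept, holes
#' are filled, and a morphological opening removes boundary spurs. The
#' foreground phase is chosen so that mean DAPI intensity inside the mask
#' exceeds that outside.
#'
#' @param dapi 2D numeric matrix (the DAPI channel), finite and
#'   nonnegative, at least 32 x 32.
#' @param params a [seg_params()].
#' @return a `lam_mask` with provenance `"auto"`.
#' @examples
#' agg <- simulate_aggregate(synth_config(image_size = 160, aggregate_radius = 50,
#'   n_cells = c(CFP = 15, GFP_RFP = 15, RFP = 8, CFP_RFP = 15)))
#' m <- segment_aggregate(agg$stack$DAPI)
#' mask_area(m) / mask_area(agg$mask)
#' @export
segment_aggregate <- function(dapi, params = seg_params()) {
  if (inherits(dapi, "lam_stack")) dapi <- dapi$DAPI
  if (!is.matrix(dapi) || any(!is.finite(dapi)))
    stop("DAPI channel missing or not a finite numeric matrix")
  if (nrow(dapi) < 32 || ncol(dapi) < 32)
    stop("DAPI image too small (need >= 32 x 32)")
  n <- nrow(dapi); m <- ncol(dapi)
  r0 <- sqrt(params$init_frac * n * m / pi)
  rows <- matrix(seq_len(n), n, m) - (n + 1) / 2
  cols <- matrix(seq_len(m), n, m, byrow = TRUE) - (m + 1) / 2
  u0 <- (rows^2 + cols^2 <= r0^2) * 1
  u <- chan_vese(dapi, u0, params$iterations, params$smoothing)
  if (!any(u > 0) || !any(u == 0))
    stop("no aggregate found (contour collapsed to one phase)")
  # phase selection: the aggregate is the DAPI-bright phase
  contrast <- mean(dapi[u > 0]) - mean(dapi[u == 0])
  if (abs(contrast) <= 1e-9 * (1 + max(dapi)))
    stop("no aggregate found (no intensity contrast)")
  if (contrast < 0) u <- 1 - u
  u <- segment_morphology(u, params)
  if (sum(u) < max(params$min_area, 1))
    stop("no aggregate found (segmented area below min_area)")
  as_mask(u, "auto")
}

# morphological clean-up chain: largest component -> fill holes ->
# opening -> re-select largest and refill (opening may fragment)
segment_morphology <- function(u, params = seg_params()) {
  u <- keep_largest_filled((u != 0) * 1)
  if (params$opening_radius > 0 && any(u != 0)) {
    brush <- EBImage::makeBrush(2 * params$opening_radius + 1, "disc")
    u <- EBImage::imageData(EBImage::opening(u, brush))
    u <- keep_largest_filled(u)
  }
  u
}

#' Default noise grid for segmentation robustness checks
#'
#' The fixture set over which automatic segmentation is expected to stay
#' accurate: every combination of Gaussian read noise sd 0, 2 and 5
#' intensity units with Poisson shot noise off (scale 0) or on (scale 1
#' photon per intensity unit), at otherwise default generator settings.
#'
#' @return a tibble with columns `noise_gaussian_sd`, `noise_poisson_scale`.
#' @export
default_noise_grid <- function() {
  tidyr::expand_grid(noise_gaussian_sd = c(0, 2, 5),
                     noise_poisson_scale = c(0, 1))
}

#' Load a user-drawn (manual) mask from file
#'
#' Accepts any two-valued PNG/TIFF image: it is thresholded at half its
#' maximum, the largest connected component is kept and holes are filled.
#' Manual masks are how easily recognised artefacts (e.g. dead cells stuck
#' to the aggregate outside) are excluded.
#'
#' @param path PNG or TIFF file.
#' @param expected_dims optional `c(rows, cols)` the mask must match.
#' @return a `lam_mask` with provenance `"manual"`.
#' @export
load_mask <- function(path, expected_dims = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- read_gray(path)
  vals <- unique(as.vector(img))
  if (length(vals) > 2)
    stop("image at ", path, " has ", length(vals),
         " distinct values; it does not look like a binary mask")
  if (!is.null(expected_dims) && !all(dim(img) == expected_dims))
    stop("mask dimensions ", paste(dim(img), collapse = "x"),
         " do not match expected ", paste(expected_dims, collapse = "x"))
  m <- (img > max(img) / 2) * 1
  if (sum(m) == 0) stop("mask at ", path, " is empty")
  m <- keep_largest_filled(m)
  as_mask(m, "manual")
}
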