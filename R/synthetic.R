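#' Configuration for the synthetic aggregate-image generator
#'
#' The generator emulates single confocal sections of re-aggregated
#' retinal organoids carrying three fate reporters: a CFP-labelled
#' population concentrated in the aggregate centre, a GFP-labelled
#' population forming a ring around it, an RFP-labelled population spread
#' throughout, and DAPI staining every cell. Cell classes mirror the
#' reporter combinations: `CFP` (CFP only), `GFP_RFP` (GFP + RFP),
#' `RFP` (RFP only) and `CFP_RFP` (CFP + RFP).
#'
#' @param image_size side of the square image, pixels.
#' @param aggregate_radius mean aggregate radius, pixels.
#' @param shape_perturbation relative amplitude of the low-order radial
#'   boundary deformation (sum of |amplitudes| of cosine modes k = 2..5);
#'   0 gives a perfect disk.
#' @param n_cells named integer vector of cell counts per class, names
#'   `CFP`, `GFP_RFP`, `RFP`, `CFP_RFP`.
#' @param organization lambda in `[0, 1]`: probability that a cell is
#'   placed inside its class's radial zone (1 = fully laminated, 0 =
#'   position independent of class).
#' @param r_inner,r_outer class-zone boundaries as fractions of the local
#'   centre-to-boundary distance, `0 < r_inner < r_outer < 1`. CFP classes
#'   occupy normalised radius `< r_inner`, the GFP class the annulus
#'   `[r_inner, r_outer)`, RFP-only cells any position.
#' @param rpe_core if `TRUE`, a central non-fluorescent disk (pigmented
#'   RPE-like core: DAPI-positive but dark in all reporter channels).
#' @param rpe_core_frac core radius as a fraction of `aggregate_radius`.
#' @param debris_rate expected number of extra-aggregate debris blobs
#'   (dead cells) rendered into the DAPI channel just outside the boundary.
#' @param cell_radius nominal cell radius, pixels; rendered blobs have
#'   Gaussian sd `cell_radius / 2`.
#' @param amplitude peak fluorescence amplitude of one cell (arbitrary
#'   intensity units, before per-cell brightness jitter).
#' @param dapi_amplitude peak DAPI amplitude of one cell.
#' @param dapi_fill DAPI intensity added uniformly inside the aggregate,
#'   emulating the densely packed nuclei of unlabelled cells (the
#'   aggregate is DAPI-positive throughout, not only at reporter-positive
#'   cells).
#' @param background_level constant intensity offset in every channel.
#' @param noise_gaussian_sd sd of additive Gaussian read noise (0 = off).
#' @param noise_poisson_scale photons per intensity unit for Poisson shot
#'   noise (0 = off); larger values mean less relative shot noise.
#' @param seed integer seed fixing all randomness.
#' @return a `synth_config` list.
#' @examples
#' cfg <- synth_config(image_size = 192, aggregate_radius = 60,
#'                     n_cells = c(CFP = 20, GFP_RFP = 20, RFP = 10, CFP_RFP = 20))
#' agg <- simulate_aggregate(cfg)
#' names(agg$stack)
#' @export
synth_config <- function(image_size = 512,
                         aggregate_radius = 120,
                         shape_perturbation = 0.06,
                         n_cells = c(CFP = 60, GFP_RFP = 60, RFP = 40, CFP_RFP = 60),
                         organization = 1,
                         r_inner = 0.55,
                         r_outer = 0.85,
                         rpe_core = FALSE,
                         rpe_core_frac = 0.12,
                         debris_rate = 0,
                         cell_radius = 6,
                         amplitude = 100,
                         dapi_amplitude = 80,
                         dapi_fill = 40,
                         background_level = 5,
                         noise_gaussian_sd = 2,
                         noise_poisson_scale = 1,
                         seed = 1L) {
  stopifnot(organization >= 0, organization <= 1,
            r_inner > 0, r_inner < r_outer, r_outer < 1,
            all(n_cells >= 0), debris_rate >= 0,
            cell_radius > 0, shape_perturbation >= 0,
            noise_gaussian_sd >= 0, noise_poisson_scale >= 0)
  classes <- c("CFP", "GFP_RFP", "RFP", "CFP_RFP")
  if (is.null(names(n_cells))) names(n_cells) <- classes
  if (!setequal(names(n_cells), classes))
    stop("n_cells must be named with classes: ", paste(classes, collapse = ", "))
  cfg <- list(image_size = as.integer(image_size),
              aggregate_radius = aggregate_radius,
              shape_perturbation = shape_perturbation,
              n_cells = n_cells[classes],
              organization = organization,
              r_inner = r_inner, r_outer = r_outer,
              rpe_core = isTRUE(rpe_core), rpe_core_frac = rpe_core_frac,
              debris_rate = debris_rate,
              cell_radius = cell_radius,
              amplitude = amplitude, dapi_amplitude = dapi_amplitude,
              dapi_fill = dapi_fill,
              background_level = background_level,
              noise_gaussian_sd = noise_gaussian_sd,
              noise_poisson_scale = noise_poisson_scale,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# channel positivity of each cell class
class_channels <- list(
  CFP     = c("CFP"),
  GFP_RFP = c("GFP", "RFP"),
  RFP     = c("RFP"),
  CFP_RFP = c("CFP", "RFP")
)

#' Generate the ground-truth aggregate mask
#'
#' The boundary is a radially perturbed circle
#' `r(theta) = R * (1 + sum_k a_k cos(k theta + phi_k))`, modes k = 2..5,
#' with amplitudes drawn from the seeded generator and normalised so that
#' `sum |a_k| = shape_perturbation`. The region is star-shaped about the
#' centre, hence connected and hole-free by construction.
#'
#' @param cfg a [synth_config()].
#' @return a `lam_mask` with provenance `"truth"`.
#' @export
make_aggregate_mask <- function(cfg) {
  R <- cfg$aggregate_radius
  sp <- cfg$shape_perturbation
  n <- cfg$image_size
  if (n <= 2 * R * (1 + sp))
    stop("aggregate does not fit the frame: need image_size > 2 * aggregate_radius * (1 + shape_perturbation)")
  set.seed(derive_seed(cfg$seed, 1L))
  k <- 2:5
  if (sp > 0) {
    u <- runif(length(k), -1, 1)
    a <- sp * u / sum(abs(u))
  } else {
    a <- rep(0, length(k))
  }
  phi <- runif(length(k), 0, 2 * pi)
  ctr <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n) - ctr
  col <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  rho <- sqrt(row^2 + col^2)
  theta <- atan2(row, col)
  rb <- R * (1 + Reduce(`+`, lapply(seq_along(k),
                                    function(i) a[i] * cos(k[i] * theta + phi[i]))))
  m <- (rho <= rb) * 1
  out <- as_mask(m, "truth")
  attr(out, "boundary") <- list(R = R, k = k, a = a, phi = phi, centre = c(ctr, ctr))
  out
}

#' Place labelled cells inside an aggregate mask
#'
#' Each cell is placed, with probability `organization` (lambda), uniformly
#' at random within its class's radial zone, and otherwise uniformly
#' anywhere in the mask. Radial position is the normalised radius
#' `1 - d / d_max`, where `d` is the Euclidean distance to the aggregate
#' outline (see [distance_map()]): 0 at the centre, 1 at the boundary.
#'
#' @param mask a `lam_mask` (typically from [make_aggregate_mask()]).
#' @param cfg a [synth_config()].
#' @return a tibble with one row per cell: `x` (column), `y` (row),
#'   `class`, `norm_radius`, and per-channel amplitudes `amp_cfp`,
#'   `amp_gfp`, `amp_rfp`, `amp_dapi`.
#' @export
place_cells <- function(mask, cfg) {
  mask <- coerce_mask(mask)
  if (mask_area(mask) == 0) stop("mask is empty")
  dm <- distance_map(mask)
  d_max <- attr(dm, "d_max")
  inside <- which(mask != 0)
  nr <- 1 - dm[inside] / d_max
  zones <- list(
    CFP     = inside[nr < cfg$r_inner],
    GFP_RFP = inside[nr >= cfg$r_inner & nr < cfg$r_outer],
    RFP     = inside,
    CFP_RFP = inside[nr < cfg$r_inner]
  )
  set.seed(derive_seed(cfg$seed, 2L))
  rows <- lapply(names(cfg$n_cells), function(cl) {
    nk <- cfg$n_cells[[cl]]
    if (nk == 0) return(NULL)
    if (length(zones[[cl]]) == 0)
      stop("radial zone for class ", cl, " contains no pixels")
    organized <- runif(nk) < cfg$organization
    pool_org <- zones[[cl]]
    pix <- integer(nk)
    pix[organized] <- pool_org[sample.int(length(pool_org), sum(organized), replace = TRUE)]
    pix[!organized] <- inside[sample.int(length(inside), sum(!organized), replace = TRUE)]
    brightness <- runif(nk, 0.7, 1.3)
    rc <- arrayInd(pix, dim(mask))
    chans <- class_channels[[cl]]
    tibble::tibble(
      x = rc[, 2], y = rc[, 1], class = cl,
      norm_radius = 1 - dm[pix] / d_max,
      amp_cfp  = ifelse("CFP" %in% chans, cfg$amplitude, 0) * brightness,
      amp_gfp  = ifelse("GFP" %in% chans, cfg$amplitude, 0) * brightness,
      amp_rfp  = ifelse("RFP" %in% chans, cfg$amplitude, 0) * brightness,
      amp_dapi = cfg$dapi_amplitude * brightness
    )
  })
  dplyr::bind_rows(rows)
}

# add an isotropic Gaussian blob (peak `amp`, sd `sd`) to `img` at (row0, col0)
add_blob <- function(img, row0, col0, amp, sd) {
  n <- nrow(img); m <- ncol(img)
  w <- ceiling(3.5 * sd)
  r1 <- max(1, round(row0) - w); r2 <- min(n, round(row0) + w)
  c1 <- max(1, round(col0) - w); c2 <- min(m, round(col0) + w)
  if (r1 > r2 || c1 > c2) return(img)
  rr <- r1:r2; cc <- c1:c2
  g <- exp(-(outer((rr - row0)^2, (cc - col0)^2, `+`)) / (2 * sd^2))
  img[rr, cc] <- img[rr, cc] + amp * g
  img
}

#' Render a multichannel image from placed cells
#'
#' Each cell contributes an isotropic Gaussian blob (sd = `cell_radius/2`)
#' to every channel in which its class is fluorescent, and to DAPI always.
#' If `rpe_core` is set, the reporter channels (not DAPI) are zeroed inside
#' the central core disk before noise. Debris blobs, if configured, are
#' added to the DAPI channel outside the aggregate. Poisson shot noise is
#' applied first, then additive Gaussian read noise; output is clipped at
#' zero.
#'
#' @param cells cell table from [place_cells()].
#' @param mask the aggregate mask the cells were placed in.
#' @param cfg a [synth_config()].
#' @return an [image_stack()] with channels CFP, GFP, RFP, DAPI.
#' @export
render_image <- function(cells, mask, cfg) {
  mask <- coerce_mask(mask)
  n <- cfg$image_size
  stopifnot(nrow(mask) == n, ncol(mask) == n)
  if (nrow(cells) > 0 && any(mask[cbind(cells$y, cells$x)] == 0))
    stop("cells inconsistent with mask: some centres fall outside")
  sdb <- cfg$cell_radius / 2
  ch <- list(CFP = "amp_cfp", GFP = "amp_gfp", RFP = "amp_rfp", DAPI = "amp_dapi")
  imgs <- lapply(ch, function(ampcol) {
    img <- matrix(cfg$background_level, n, n)
    if (nrow(cells) > 0) {
      amps <- cells[[ampcol]]
      for (i in which(amps > 0))
        img <- add_blob(img, cells$y[i], cells$x[i], amps[i], sdb)
    }
    img
  })
  if (cfg$dapi_fill > 0)
    imgs$DAPI <- imgs$DAPI + cfg$dapi_fill * (mask != 0)
  set.seed(derive_seed(cfg$seed, 3L))
  if (cfg$rpe_core) {
    ctr <- mask_centroid(mask)
    row <- matrix(seq_len(n), n, n) - ctr[1]
    col <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr[2]
    core <- (row^2 + col^2) <= (cfg$rpe_core_frac * cfg$aggregate_radius)^2
    for (nm in c("CFP", "GFP", "RFP")) imgs[[nm]][core] <- 0
  }
  if (cfg$debris_rate > 0) {
    ndeb <- rpois(1, cfg$debris_rate)
    if (ndeb > 0) {
      ctr <- mask_centroid(mask)
      dm <- distance_map(mask)
      for (i in seq_len(ndeb)) {
        th <- runif(1, 0, 2 * pi)
        # local boundary radius along th, from the discrete mask
        rad <- local_boundary_radius(mask, ctr, th)
        r <- rad * runif(1, 1.1, 1.35)
        row0 <- ctr[1] + r * sin(th); col0 <- ctr[2] + r * cos(th)
        row0 <- min(max(row0, 1), n); col0 <- min(max(col0, 1), n)
        imgs$DAPI <- add_blob(imgs$DAPI, row0, col0,
                              cfg$dapi_amplitude * runif(1, 0.5, 1), sdb)
      }
    }
  }
  imgs <- lapply(imgs, function(img) {
    if (cfg$noise_poisson_scale > 0)
      img <- rpois(length(img), pmax(img, 0) * cfg$noise_poisson_scale) /
        cfg$noise_poisson_scale
    if (cfg$noise_gaussian_sd > 0)
      img <- img + rnorm(length(img), 0, cfg$noise_gaussian_sd)
    matrix(pmax(img, 0), n, n)
  })
  image_stack(!!!imgs)
}

# farthest in-mask pixel along a ray from the centroid (coarse scan)
local_boundary_radius <- function(mask, ctr, theta) {
  n <- nrow(mask)
  rmax <- sqrt(2) * n / 2
  rs <- seq(1, rmax, by = 1)
  rows <- round(ctr[1] + rs * sin(theta)); cols <- round(ctr[2] + rs * cos(theta))
  ok <- rows >= 1 & rows <= n & cols >= 1 & cols <= ncol(mask)
  inside <- mask[cbind(rows[ok], cols[ok])] != 0
  if (!any(inside)) return(0)
  rs[ok][max(which(inside))]
}

#' Simulate one synthetic aggregate
#'
#' Runs [make_aggregate_mask()], [place_cells()] and [render_image()] on
#' one configuration.
#'
#' @param cfg a [synth_config()].
#' @return a list with elements `stack` (the rendered [image_stack()]),
#'   `mask` (ground-truth `lam_mask`), `cells` (cell table) and `config`.
#' @export
simulate_aggregate <- function(cfg) {
  mask <- make_aggregate_mask(cfg)
  cells <- place_cells(mask, cfg)
  stack <- render_image(cells, mask, cfg)
  list(stack = stack, mask = mask, cells = cells, config = cfg)
}

#' Generate a cohort of synthetic aggregates
#'
#' Each cohort member is simulated from a per-item seed derived
#' deterministically from `cfg$seed` (one congruential step per item
#' index), so cohorts are reproducible and members independent.
#'
#' @param cfg a [synth_config()].
#' @param n number of aggregates (default 15, a typical per-condition
#'   cohort size in this assay).
#' @return a list of `n` simulation results (see [simulate_aggregate()]).
#' @export
generate_cohort <- function(cfg, n = 15) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, 100L + i)
    simulate_aggregate(cfg_i)
  })
}
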