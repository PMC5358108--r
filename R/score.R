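#' Normalise a radial profile onto the 0-100 radial-unit axis
#'
#' Band coordinates are rescaled so the outermost band midpoint maps to
#' 100 radial units (ru), the sampled curve is extended to x = 0 and
#' x = 100 by constant continuation, and each channel is divided by its
#' trapezoidal integral so the profile integrates to 1. The result is a
#' fluorescence density (units 1/ru) comparable across aggregates of
#' different sizes.
#'
#' @param profile a `lam_profile` from [radial_profile()] (>= 2 bands).
#' @param channels channels to keep; default: all intensity channels in
#'   the profile.
#' @return a `lam_nprofile` tibble in long form: `channel`, `x` (ru),
#'   `density` (1/ru).
#' @export
normalize_profile <- function(profile, channels = NULL) {
  channels <- channels %||% profile_channels(profile)
  r <- profile$radial_px
  if (length(r) < 2)
    stop("cannot rescale a single-band profile")
  x <- 100 * r / max(r)
  out <- lapply(channels, function(ch) {
    y <- profile[[ch]]
    if (all(y == 0))
      stop("channel ", ch, " is all zero; cannot normalise")
    xs <- x; ys <- y
    if (xs[1] > 0) { xs <- c(0, xs); ys <- c(ys[1], ys) }
    if (xs[length(xs)] < 100) { xs <- c(xs, 100); ys <- c(ys, ys[length(ys)]) }
    tot <- trapz_xy(xs, ys)
    tibble::tibble(channel = ch, x = xs, density = ys / tot)
  })
  out <- dplyr::bind_rows(out)
  structure(out, class = c("lam_nprofile", class(out)),
            mode = attr(profile, "mode"), w = attr(profile, "w"))
}

#' Cumulative fluorescence distribution (ECDF curve)
#'
#' The cumulative trapezoidal integral of the normalised fluorescence
#' density from the centre (x = 0) outward; `F(100) = 1`. A spatially
#' uniform channel gives the diagonal `F(x) = x / 100`, the reference for
#' a perfectly even distribution of fluorescence from centre to
#' periphery.
#'
#' @param nprofile a `lam_nprofile` from [normalize_profile()], or any
#'   tibble with `channel`, `x`, `density` columns.
#' @return a `lam_ecdf` tibble: `channel`, `x` (ru), `F` (nondecreasing,
#'   `F(0) = 0`, `F(100) = 1`).
#' @export
profile_ecdf <- function(nprofile) {
  out <- nprofile |>
    dplyr::group_by(.data$channel) |>
    dplyr::arrange(.data$x, .by_group = TRUE) |>
    dplyr::mutate(F = as.vector(pracma::cumtrapz(.data$x, .data$density)),
                  F = .data$F / .data$F[dplyr::n()]) |>
    dplyr::ungroup() |>
    dplyr::select("channel", "x", "F")
  structure(out, class = c("lam_ecdf", class(tibble::tibble())))
}

#' Area beneath each ECDF curve
#'
#' Trapezoidal integral of `F` over the 0-100 ru axis, per channel. A
#' uniform channel yields 50 (the diagonal); the deviation from 50 is
#' positive for centrally enriched signal.
#'
#' @param ecdf a `lam_ecdf`.
#' @return a tibble: `channel`, `area` (ru), `deviation` (`area - 50`).
#' @export
area_beneath <- function(ecdf) {
  ecdf |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(area = trapz_xy(.data$x, .data$F), .groups = "drop") |>
    dplyr::mutate(deviation = .data$area - 50)
}

#' Signed area between two ECDF curves
#'
#' The lamination statistic: the trapezoidal area beneath curve `a` minus
#' that beneath curve `b`. With `a` the centrally located CFP population
#' and `b` the peripheral GFP population, well-laminated aggregates score
#' positive (range -100..100 ru). Curves on different grids are resampled
#' onto the union grid by linear interpolation.
#'
#' @param a,b either a single `lam_ecdf` holding both channels (`b`
#'   omitted), or two ECDF objects / data frames with `x` and `F`
#'   columns.
#' @param channel_a,channel_b channel names to compare (defaults CFP and
#'   GFP).
#' @return the signed area (scalar, ru).
#' @export
area_between <- function(a, b = NULL, channel_a = "CFP", channel_b = "GFP") {
  pick <- function(obj, ch) {
    if ("channel" %in% names(obj)) obj <- obj[obj$channel == ch, ]
    if (nrow(obj) == 0) stop("channel ", ch, " not found in ECDF")
    obj[order(obj$x), c("x", "F")]
  }
  ca <- pick(a, channel_a)
  cb <- pick(if (is.null(b)) a else b, channel_b)
  grid <- sort(union(ca$x, cb$x))
  fa <- approx(ca$x, ca$F, xout = grid, rule = 2)$y
  fb <- approx(cb$x, cb$F, xout = grid, rule = 2)$y
  trapz_xy(grid, fa) - trapz_xy(grid, fb)
}

#' Lamination score of one aggregate
#'
#' End-to-end per-aggregate statistic: radial profile, unit-integral
#' normalisation, ECDF curves, then the signed area between the CFP and
#' GFP cumulative curves (CFP minus GFP). Positive scores mean the CFP
#' population sits more centrally than the GFP population.
#'
#' @param stack an [image_stack()] with at least CFP and GFP channels.
#' @param mask a `lam_mask` for the aggregate.
#' @param w band width in pixels.
#' @param mode `"periphery"` (default) or `"centroid"`.
#' @param channel_a,channel_b the channels whose areas are differenced.
#' @return a one-row tibble with one `area_<channel>` column per
#'   profiled channel, `score` (= `area_a - area_b`, ru) and
#'   `mask_provenance`.
#' @examples
#' agg <- simulate_aggregate(synth_config(image_size = 192, aggregate_radius = 60,
#'   n_cells = c(CFP = 20, GFP_RFP = 20, RFP = 10, CFP_RFP = 20)))
#' lamination_score(agg$stack, agg$mask)
#' @export
lamination_score <- function(stack, mask, w = 5, mode = "periphery",
                             channel_a = "CFP", channel_b = "GFP") {
  chans <- intersect(c("CFP", "GFP", "RFP"), names(stack))
  if (!all(c(channel_a, channel_b) %in% names(stack)))
    stop("stack must contain channels ", channel_a, " and ", channel_b)
  chans <- union(chans, c(channel_a, channel_b))
  prof <- radial_profile(stack, mask, w = w, mode = mode)
  ec <- profile_ecdf(normalize_profile(prof, channels = chans))
  areas <- area_beneath(ec)
  wide <- stats::setNames(areas$area, paste0("area_", areas$channel))
  out <- tibble::as_tibble(as.list(wide))
  out$score <- wide[[paste0("area_", channel_a)]] - wide[[paste0("area_", channel_b)]]
  out$mask_provenance <- mask_provenance(coerce_mask(mask))
  out
}
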