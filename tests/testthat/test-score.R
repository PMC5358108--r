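make_profile <- function(radial, values, channel = "CFP") {
  out <- tibble::tibble(mode = "periphery",
                        band_index = seq_along(radial) - 1,
                        radial_px = radial, n_pixels = 1L)
  out[[channel]] <- values
  structure(out, class = c("lam_profile", class(out)),
            w = 5, mode = "periphery", channels = channel)
}

test_that("normalisation gives unit integral, handles constants and hand example", {
  # constant profile at any level -> density 0.01 per ru
  np <- normalize_profile(make_profile(c(10, 20, 30, 40), rep(7, 4)))
  expect_true(all(abs(np$density - 0.01) < 1e-12))
  expect_equal(pracma::trapz(np$x, np$density), 1, tolerance = 1e-9)

  # two bands at the axis ends: (0, 3), (100, 1) -> integral 200
  np2 <- normalize_profile(make_profile(c(0, 100), c(3, 1)))
  expect_equal(np2$density[np2$x == 0], 0.015)
  expect_equal(np2$density[np2$x == 100], 0.005)

  # scale invariance
  np3 <- normalize_profile(make_profile(c(0, 100), 7 * c(3, 1)))
  expect_equal(np3$density, np2$density)
})

test_that("normalisation rejects degenerate profiles", {
  expect_error(normalize_profile(make_profile(c(5, 10), c(0, 0))), "CFP")
  expect_error(normalize_profile(make_profile(50, 1)), "single-band")
})

test_that("endpoint extension is constant continuation covering [0, 100]", {
  np <- normalize_profile(make_profile(c(20, 40, 80), c(2, 4, 6)))
  expect_equal(range(np$x), c(0, 100))
  # rescaled band coordinates: 100 * r / r_max
  expect_true(all(c(25, 50, 100) %in% np$x))
  d <- np$density
  expect_equal(d[np$x == 0], d[np$x == 25])    # constant continuation inward
  expect_equal(d[np$x == 100], d[np$x == 100]) # outermost band maps to 100
})

test_that("ECDF of a uniform density is the diagonal and always monotone", {
  np <- normalize_profile(make_profile(seq(0, 100, by = 10), rep(2, 11)))
  ec <- profile_ecdf(np)
  expect_equal(ec$F, ec$x / 100, tolerance = 1e-9)
  ab <- area_beneath(ec)
  expect_equal(ab$area, 50, tolerance = 1e-9)
  expect_equal(ab$deviation, 0, tolerance = 1e-9)

  set.seed(1)
  for (i in 1:5) {
    rnd <- normalize_profile(make_profile(sort(runif(8, 0, 100)), runif(8) + 0.1))
    f <- profile_ecdf(rnd)$F
    expect_true(all(diff(f) >= -1e-12))
    expect_equal(f[length(f)], 1)
    expect_equal(f[1], 0)
  }
})

test_that("analytic linear density reproduces closed forms to 1e-6", {
  x <- seq(0, 100, length.out = 10001)
  np <- tibble::tibble(channel = "CFP", x = x, density = 0.015 - 0.0001 * x)
  ec <- profile_ecdf(np)
  # F(x) = 0.015 x - 5e-5 x^2 ; F(50) = 0.625
  expect_equal(ec$F[ec$x == 50], 0.625, tolerance = 1e-6)
  # area beneath F on [0,100] = 58.3333...
  expect_equal(area_beneath(ec)$area, 175 / 3, tolerance = 1e-6)
  # against a uniform reference the score is area - 50
  un <- tibble::tibble(channel = "GFP", x = x, density = rep(0.01, length(x)))
  both <- profile_ecdf(dplyr::bind_rows(np, un))
  expect_equal(area_between(both), 175 / 3 - 50, tolerance = 1e-6)
})

test_that("area between curves is signed, antisymmetric and zero on self", {
  x <- seq(0, 100, length.out = 501)
  set.seed(2)
  mk <- function(ch) {
    d <- runif(length(x)) + 0.2
    tibble::tibble(channel = ch, x = x, density = d / pracma::trapz(x, d))
  }
  ec <- profile_ecdf(dplyr::bind_rows(mk("CFP"), mk("GFP")))
  expect_equal(area_between(ec, channel_a = "CFP", channel_b = "CFP"), 0)
  ab <- area_between(ec, channel_a = "CFP", channel_b = "GFP")
  ba <- area_between(ec, channel_a = "GFP", channel_b = "CFP")
  expect_equal(ab, -ba)
})

test_that("extreme central vs peripheral mass scores 100", {
  a <- data.frame(x = c(0, 1e-6, 100), F = c(0, 1, 1))
  b <- data.frame(x = c(0, 100 - 1e-6, 100), F = c(0, 0, 1))
  expect_equal(area_between(a, b), 100, tolerance = 1e-4)
})

test_that("curves on different grids are resampled onto the union grid", {
  a <- data.frame(x = c(0, 50, 100), F = c(0, 0.5, 1))
  b <- data.frame(x = c(0, 25, 75, 100), F = c(0, 0.25, 0.75, 1))
  expect_equal(area_between(a, b), 0, tolerance = 1e-12)  # both diagonals
})

test_that("a uniform synthetic channel deviates < 0.5 ru from the diagonal at w = 2", {
  mask <- make_aggregate_mask(synth_config(shape_perturbation = 0))  # radius 120
  st <- image_stack(CFP = matrix(3, 512, 512), GFP = matrix(5, 512, 512))
  ec <- profile_ecdf(normalize_profile(radial_profile(st, mask, w = 2)))
  expect_true(all(abs(area_beneath(ec)$deviation) <= 0.5))
})

test_that("scores at w = 5 and w = 2 agree within 2 ru on a noiseless aggregate", {
  cfg <- small_config(noise_gaussian_sd = 0, noise_poisson_scale = 0, seed = 21)
  agg <- simulate_aggregate(cfg)
  s5 <- lamination_score(agg$stack, agg$mask, w = 5)$score
  s2 <- lamination_score(agg$stack, agg$mask, w = 2)$score
  expect_lt(abs(s5 - s2), 2)
})

test_that("lamination_score reports per-channel areas and provenance", {
  agg <- simulate_aggregate(small_config(seed = 22))
  sc <- lamination_score(agg$stack, agg$mask)
  expect_named(sc, c("area_CFP", "area_GFP", "area_RFP", "score", "mask_provenance"))
  expect_equal(sc$score, sc$area_CFP - sc$area_GFP)
  expect_identical(sc$mask_provenance, "truth")
  expect_gt(sc$score, 0)  # organised aggregate: CFP central
})
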