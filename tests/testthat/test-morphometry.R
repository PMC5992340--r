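gauss_profile <- function(n, mu, sigma, amp = 1, base = 0) {
  structure(list(values = base + amp * exp(-((1:n) - mu)^2 / (2 * sigma^2)),
                 pixel_size = 7,
                 extracellular_direction = "increasing_index"),
            class = "band_profile")
}

test_that("band profiles average the central columns", {
  col <- sin(seq(0, pi, length.out = 20))
  img <- matrix(col, 20, 15)
  bp <- band_profile(img, 7, pixel_size = 7)
  expect_equal(bp$values, col)
  # Gaussian ridge along x keeps its sigma in the profile
  rid <- matrix(rep(exp(-((1:32) - 16)^2 / (2 * 9)), 32), 32, 32)
  bp2 <- band_profile(rid, 7, 7)
  fitted_sigma <- sqrt(sum(bp2$values * ((1:32) - 16)^2) / sum(bp2$values))
  expect_equal(fitted_sigma, 3, tolerance = 0.1)
  expect_error(band_profile(matrix(0, 10, 6), 7), "exceeds")
  expect_error(band_profile(matrix(0, 10, 10), 4), "odd")
})

test_that("the mean-level width rule matches closed forms", {
  # rectangular peak: width = extent regardless of the threshold level
  v <- c(rep(0, 8), rep(1, 10), rep(0, 8))
  bp <- structure(list(values = v, pixel_size = 7,
                       extracellular_direction = "increasing_index"),
                  class = "band_profile")
  th <- measure_thickness(bp)
  expect_true(th$ok)
  expect_equal(th$width_px, 10)
  expect_equal(th$thickness_nm, 7)
  expect_equal(th$threshold, 0.5)
  # whole-sample mode agrees on the rectangle
  expect_equal(measure_thickness(bp, interpolate = FALSE)$width_px, 10)

  # Gaussian peak: width = FWHM = 2.3548 sigma
  for (sigma in c(2.5, 3, 4)) {
    g <- measure_thickness(gauss_profile(64, 28, sigma))
    expect_equal(g$width_px, 2 * sqrt(2 * log(2)) * sigma,
                 tolerance = 0.005 * 2.3548 * sigma)
  }

  # merged membrane+coat double peak vs a numeric root-finding oracle
  f <- function(x) exp(-(x - 25)^2 / 8) + 0.9 * exp(-(x - 30)^2 / 8)
  v2 <- f(1:64)
  bp2 <- structure(list(values = v2, pixel_size = 7,
                        extracellular_direction = "increasing_index"),
                   class = "band_profile")
  th2 <- measure_thickness(bp2)
  pk_x <- optimize(f, c(24, 31), maximum = TRUE)
  thr <- pk_x$objective / 2
  left <- uniroot(function(x) f(x) - thr, c(15, pk_x$maximum))$root
  right <- uniroot(function(x) f(x) - thr, c(pk_x$maximum, 40))$root
  expect_equal(th2$width_px, right - left, tolerance = 0.05)
  expect_gt(th2$width_px, measure_thickness(gauss_profile(64, 28, 2))$width_px)

  # scale and offset equivariance hold exactly
  base <- gauss_profile(64, 28, 3)
  w0 <- measure_thickness(base)$width_px
  sc <- base; sc$values <- 4.2 * sc$values
  of <- base; of$values <- of$values + 0.37
  expect_identical(measure_thickness(sc)$width_px, w0)
  expect_equal(measure_thickness(of)$width_px, w0, tolerance = 1e-12)
})

test_that("degenerate profiles are flagged, not mis-measured", {
  mono <- structure(list(values = 1:20 / 20, pixel_size = 7,
                         extracellular_direction = "increasing_index"),
                    class = "band_profile")
  expect_false(measure_thickness(mono)$ok)
  expect_match(measure_thickness(mono)$flags, "peak_at_profile_end")

  # a saddle right next to the peak is a genuine dip
  saddle <- structure(list(values = c(0, 0.2, 1, 0.8, 0.85, 0.9, 0.95),
                           pixel_size = 7,
                           extracellular_direction = "increasing_index"),
                      class = "band_profile")
  s <- measure_thickness(saddle)
  expect_true(s$ok)
  expect_equal(s$dip_value, 0.8)

  # no sample pair on the extracellular side -> no dip, flagged
  short <- structure(list(values = c(0, 0.4, 1, 0.6),
                          pixel_size = 7,
                          extracellular_direction = "increasing_index"),
                     class = "band_profile")
  r <- measure_thickness(short)
  expect_false(r$ok)
  expect_match(r$flags, "no_extracellular_dip")

  plat <- structure(list(values = c(0, 0.5, 1, 1, 1, 0.5, 0.2, 0),
                         pixel_size = 7,
                         extracellular_direction = "increasing_index"),
                    class = "band_profile")
  p <- measure_thickness(plat)
  expect_true(p$ok)
  expect_true("plateaued_max_center_convention" %in% p$flags)
})

test_that("relative thickness is the plain ratio with valid pairing", {
  a <- measure_thickness(gauss_profile(64, 28, 6.4 / 2.3548 / 0.7))
  b <- measure_thickness(gauss_profile(64, 28, 4.0 / 2.3548 / 0.7))
  rt <- relative_thickness(a, b, "curved")
  expect_equal(rt$ratio, 1.6, tolerance = 0.02)
  same <- relative_thickness(a, a, "shallow")
  expect_identical(same$ratio, 1)
  bad <- measure_thickness(structure(list(values = 1:10 / 10, pixel_size = 7,
                                          extracellular_direction = "increasing_index"),
                                     class = "band_profile"))
  expect_error(relative_thickness(a, bad, "curved"), "valid")
})

test_that("the Welch test matches its closed form and the reference implementation", {
  w <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t_statistic, -1.224745, tolerance = 1e-6)
  expect_equal(w$df, 4.0, tolerance = 1e-9)
  expect_equal(w$p_two_tailed, 0.2878641, tolerance = 1e-6)

  strong <- welch_test(c(0, 0, 0.1), c(10, 10, 10.1))
  expect_lt(strong$p_two_tailed, 0.001)

  ident <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t_statistic, 0)
  expect_equal(ident$p_two_tailed, 1)

  for (s in 1:100) {
    g <- eisoclem:::with_seed(s, list(a = rnorm(sample(3:12, 1), 0, runif(1, 0.5, 2)),
                                      b = rnorm(sample(3:12, 1), runif(1, -1, 1))))
    mine <- welch_test(g$a, g$b)
    ref <- t.test(g$a, g$b, var.equal = FALSE)
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-9)
  }
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("circle fits are exact on exact points and robust to noise", {
  th <- c(0.3, 1.4, 2.6)
  pts <- cbind(40 + 25 * cos(th), 40 + 25 * sin(th))
  fit <- fit_coat_circle(pts, 7)
  expect_equal(fit$radius_px, 25, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-9)
  expect_equal(fit$diameter_nm, 2 * 25 * 0.7, tolerance = 1e-6)

  # 20 points on a 90 degree arc of a 45 nm circle, 0.5 nm localization noise
  R_px <- 45 / 2 / 0.7
  ang <- seq(0, pi / 2, length.out = 20)
  noise <- eisoclem:::with_seed(17, matrix(rnorm(40, 0, 0.5 / 0.7), 20, 2))
  pts2 <- cbind(50 + R_px * cos(ang), 50 + R_px * sin(ang)) + noise
  fit2 <- fit_coat_circle(pts2, 7)
  expect_equal(fit2$diameter_nm, 45, tolerance = 0.05 * 45)

  expect_error(fit_coat_circle(cbind(1:5, 2 * (1:5)), 7), "collinear")
})

test_that("cohort reports recover the built-in category means", {
  fake_rec <- function(ratio, category)
    structure(list(ratio = ratio, category = category),
              class = "relative_thickness")
  mk <- function(seed) eisoclem:::with_seed(seed, {
    c(lapply(1 + rnorm(3, 0, 0.1), fake_rec, category = "shallow"),
      lapply(1.6 + rnorm(3, 0, 0.1), fake_rec, category = "curved"))
  })
  rep <- cohort_report(mk(5))
  expect_equal(rep$summary$mean[rep$summary$category == "shallow"], 1,
               tolerance = 0.15)
  expect_equal(rep$summary$mean[rep$summary$category == "curved"], 1.6,
               tolerance = 0.15)
  expect_lt(rep$welch$p_two_tailed, 0.05)

  # identical categories: significant in at most ~5% of seeds
  hits <- sum(vapply(1:100, function(s) {
    recs <- eisoclem:::with_seed(s, c(
      lapply(1.3 + rnorm(4, 0, 0.1), fake_rec, category = "shallow"),
      lapply(1.3 + rnorm(4, 0, 0.1), fake_rec, category = "curved")))
    cohort_report(recs)$welch$p_two_tailed < 0.05
  }, logical(1)))
  expect_lte(hits, 10)

  expect_error(cohort_report(lapply(c(1, 1.1), fake_rec,
                                    category = "curved")),
               "category 'shallow'")
})
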