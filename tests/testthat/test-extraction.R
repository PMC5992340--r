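test_that("spline traces reproduce straight lines and circles", {
  # collinear clicks -> straight trace
  P <- cbind(10, 20, seq(10, 60, by = 10))
  ck <- click_set(P, voxel_size = 10)
  tr <- resample_trace(fit_trace(ck), spacing_nm = 10)
  expect_equal(tr$arc_length, 50 * 1, tolerance = 1e-6)  # 50 vox * 1 nm
  expect_true(all(abs(tr$samples$tz - 1) < 1e-9))
  expect_true(all(abs(tr$samples$tx) < 1e-9))

  # clicks on a circle of radius 50 nm stay within 0.5 nm of it
  R_nm <- 50; vs <- 7
  th <- seq(0, pi, length.out = 14)
  P2 <- cbind(24, (80 + R_nm * cos(th) * 10 / vs),
              (80 + R_nm * sin(th) * 10 / vs))
  tr2 <- resample_trace(fit_trace(click_set(P2, voxel_size = vs)), 5)
  r_err <- abs(sqrt((tr2$samples$y - 80)^2 + (tr2$samples$z - 80)^2) *
                 vs / 10 - R_nm)
  expect_lt(max(r_err), 0.5)

  # smoothing 0 interpolates every click exactly
  P3 <- eisoclem:::with_seed(5, cbind(runif(6, 10, 30), runif(6, 10, 30),
                                      seq(5, 55, 10)))
  ck3 <- click_set(P3, voxel_size = 7)
  tr3 <- fit_trace(ck3, smoothing = 0)
  seg <- sqrt(rowSums((P3[-1, ] - P3[-6, ])^2))
  tt <- c(0, cumsum(seg))
  expect_equal(eisoclem:::trace_point(tr3, tt), unname(P3),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(click_set(rbind(c(1, 1, 1), c(1, 1, 1))), "coincident")
})

test_that("resampling spaces samples evenly and respects the side convention", {
  P <- cbind(10, 50, seq(0, 120, by = 20))  # 120 voxels at 10 A = 120 nm
  ck <- click_set(P, voxel_size = 10)
  tr <- resample_trace(fit_trace(ck), 15)
  expect_equal(nrow(tr$samples), 9)          # floor(120/15) + 1
  expect_equal(diff(tr$samples$arc_nm), rep(15, 8))

  tr2 <- resample_trace(fit_trace(ck), 120)
  expect_equal(nrow(tr2$samples), 2)
  expect_warning(resample_trace(fit_trace(ck), 500), "endpoints")

  # straight trace along x with extracellular +z: angle prior 0
  Px <- cbind(seq(0, 60, 10), 30, 40)
  trx <- resample_trace(fit_trace(click_set(Px, voxel_size = 10)), 20)
  expect_true(all(abs(trx$samples$in_plane_angle) < 1e-9))
  expect_true(all(abs(trx$samples$nz - 1) < 1e-9))

  # tangent and normal are orthonormal everywhere
  tn <- with(tr$samples, tx * nx + ty * ny + tz * nz)
  expect_lt(max(abs(tn)), 1e-9)
})

test_that("box placement follows the closed-form spacing rule", {
  expect_equal(box_centers_along_arc(120, 40, 0.4), c(20, 44, 68, 92))
  expect_equal(box_centers_along_arc(30, 40, 0.4), 15)        # L < B
  expect_equal(box_centers_along_arc(120, 40, 0), c(20, 60, 100))
  # against the brute-force placement oracle
  for (s in 1:20) {
    p <- eisoclem:::with_seed(s, c(L = runif(1, 20, 400), B = runif(1, 8, 60),
                                   o = runif(1, 0, 0.9)))
    expect_equal(box_centers_along_arc(p["L"], p["B"], p["o"]),
                 brute_force_centers(p["L"], p["B"], p["o"]),
                 ignore_attr = TRUE)
  }
  # union of box intervals is contiguous for any overlap
  for (o in c(0, 0.3, 0.6, 0.9)) {
    ctr <- box_centers_along_arc(200, 32, o)
    starts <- ctr - 16; ends <- ctr + 16
    expect_true(all(starts[-1] <= ends[-length(ends)] + 1e-9))
  }
  # halving the spacing nests sample positions
  P <- cbind(10, 50, seq(0, 120, by = 20))
  tr <- fit_trace(click_set(P, voxel_size = 10))
  a1 <- resample_trace(tr, 15)$samples$arc_nm
  a2 <- resample_trace(tr, 7.5)$samples$arc_nm
  expect_true(all(a1 %in% a2))
})

test_that("extracted boxes sit on the trace with correct bookkeeping", {
  tomo <- tomogram(array(0, c(60, 60, 140)), 10)
  P <- cbind(30, 30, seq(5, 125, by = 24))  # straight along z, 120 vox
  tr <- fit_trace(click_set(P, voxel_size = 10))
  st <- extract_boxes(tomo, tr, box_size = 40, overlap_fraction = 0.4)
  expect_equal(length(st$boxes), 4)
  expect_equal(st$centers_arc_vox, c(20, 44, 68, 92))
  expect_equal(st$centers[, 3], 5 + c(20, 44, 68, 92), tolerance = 1e-6)
  expect_error(extract_boxes(tomo, tr, box_size = 70), "larger than")
})

test_that("2D collapse projects constant, point and tube phantoms correctly", {
  # constant box -> constant image of the same value
  tomo <- tomogram(array(3.5, c(40, 40, 40)), 7)
  P <- cbind(seq(8, 32, 8), 19.5, 19.5)
  tr <- fit_trace(click_set(P, voxel_size = 7))
  st <- extract_boxes(tomo, tr, 16, 0)
  cs <- collapse_to_2d(st)
  expect_equal(max(abs(cs$images[[1]] - 3.5)), 0, tolerance = 1e-9)

  # single bright voxel at the box centre -> brightest pixel at image centre
  arr <- array(0, c(41, 41, 41)); arr[21, 21, 21] <- 1
  tomo2 <- tomogram(arr, 7)
  P2 <- cbind(c(14, 26), 20, 20)   # short trace: one box centred at x = 20
  st2 <- extract_boxes(tomo2, fit_trace(click_set(P2, voxel_size = 7)), 17, 0)
  expect_equal(length(st2$boxes), 1)
  expect_equal(st2$centers[1, ], c(20, 20, 20), tolerance = 1e-9,
               ignore_attr = TRUE)
  cs2 <- collapse_to_2d(st2, tomogram = tomo2)
  pk <- which(cs2$images[[1]] == max(cs2$images[[1]]), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(9, 9))

  # Gaussian tube along the tangent -> ring with max-density radius = tube radius
  n <- 48; ctr <- (n - 1) / 2; R <- 8
  yz <- expand.grid(y = 0:(n - 1), z = 0:(n - 1))
  rad <- sqrt((yz$y - ctr)^2 + (yz$z - ctr)^2)
  sl <- matrix(exp(-(rad - R)^2 / (2 * 1.5^2)), n, n)
  tube <- aperm(array(sl, c(n, n, n)), c(3, 1, 2))
  tomo3 <- tomogram(tube, 7)
  P3 <- cbind(seq(6, 42, 6), ctr, ctr)
  st3 <- extract_boxes(tomo3, fit_trace(click_set(P3, voxel_size = 7)), 32, 0)
  cs3 <- collapse_to_2d(st3, tomogram = tomo3)
  img <- cs3$images[[1]]
  ic <- (nrow(img) - 1) / 2
  pts <- which(img > 0.5 * max(img), arr.ind = TRUE)
  rr <- sqrt((pts[, 1] - 1 - ic)^2 + (pts[, 2] - 1 - ic)^2)
  expect_equal(mean(range(rr)), R, tolerance = 1)
})

test_that("collapsed furrow cross-sections are horizontal after the angle prior", {
  spec <- membrane_phantom_spec(noise_sigma = 0, coat_enabled = TRUE)
  ph <- make_membrane_phantom(spec)
  tr <- fit_trace(trace_from_truth(ph$truth, at = "ridge"))
  st <- extract_boxes(ph$tomogram, tr, 32, 0.4)
  cs <- collapse_to_2d(st, tomogram = ph$tomogram)
  for (i in seq_along(cs$images)) {
    img <- rotate_image(cs$images[[i]], cs$angle_prior[i])
    expect_lt(abs(membrane_slope_deg(img)), 5)
  }
})

test_that("binning rescales voxels and conserves density", {
  arr <- eisoclem:::with_seed(2, array(rnorm(24 * 24 * 24), c(24, 24, 24)))
  tomo <- tomogram(arr, 3.5)
  b2 <- bin_volume(tomo, 2)
  expect_equal(b2$voxel_size, 7)
  expect_equal(dim(b2$data), c(12, 12, 12))
  expect_equal(sum(b2$data) * 8, sum(arr), tolerance = 1e-6)
  expect_identical(bin_volume(tomo, 1), tomo)
  expect_warning(bin_volume(tomogram(array(0, c(25, 24, 24)), 3.5), 2),
                 "cropped")
  # binning commutes with the block structure: first block mean
  expect_equal(b2$data[1, 1, 1], mean(arr[1:2, 1:2, 1:2]))
})
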