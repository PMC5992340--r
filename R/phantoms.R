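# Synthetic phantoms: fiducial scenes, spot images, focal stacks, and membrane
# tomogram phantoms with known ground truth. Every generator is a pure function
# of its arguments including the seed.

#' Construct a ground-truth planar transform
#'
#' Maps fluorescence-microscope (FM) coordinates into electron-microscope (EM)
#' coordinates: em = linear_part %*% fm + translation.
#'
#' @param linear_part invertible 2x2 matrix.
#' @param translation length-2 numeric (EM pixels).
#' @param model_tag "similarity" or "affine".
#' @return object of class `ground_truth_transform`.
#' @export
ground_truth_transform <- function(linear_part, translation = c(0, 0),
                                   model_tag = c("affine", "similarity")) {
  model_tag <- match.arg(model_tag)
  linear_part <- matrix(as.numeric(linear_part), 2, 2)
  if (abs(det(linear_part)) <= 1e-12)
    stop("linear_part must be invertible (|det| > 1e-12)")
  if (model_tag == "similarity") {
    # s * R with R orthogonal (rotation, possibly with reflection)
    s <- sqrt(abs(det(linear_part)))
    O <- linear_part / s
    if (max(abs(crossprod(O) - diag(2))) > 1e-8)
      stop("similarity transform requires linear_part = s * orthogonal")
  }
  structure(list(linear_part = linear_part, translation = as.numeric(translation),
                 model_tag = model_tag), class = "ground_truth_transform")
}

#' Apply a planar transform to points
#' @param tf a `ground_truth_transform` or `fitted_transform`.
#' @param pts n x 2 matrix (or length-2 vector) of points.
#' @return n x 2 matrix of transformed points.
#' @export
apply_transform <- function(tf, pts) {
  pts <- rbind(pts)
  t(tf$linear_part %*% t(pts) + tf$translation)
}

#' Invert a planar transform
#' @param tf a transform with `linear_part` and `translation`.
#' @return transform of the same class.
#' @export
invert_transform <- function(tf) {
  Ai <- solve(tf$linear_part)
  out <- tf
  out$linear_part <- Ai
  out$translation <- as.numeric(-Ai %*% tf$translation)
  out
}

#' Simulate a paired FM/EM fiducial scene
#'
#' Multi-modal fiducial beads (e.g. TetraSpeck markers visible in both
#' fluorescence and EM) are placed uniformly in the EM field with a minimum
#' separation of 4 px; their FM coordinates are the inverse-transformed EM
#' positions plus isotropic Gaussian localization noise. A target spot (the
#' "GFP signal") with known true EM location is included for prediction tests.
#'
#' @param n_beads number of fiducials (>= 3).
#' @param truth a [ground_truth_transform()] (FM -> EM).
#' @param noise_sigma_fm localization noise SD in FM pixels.
#' @param field_size EM field (width, height) in pixels.
#' @param seed integer seed.
#' @return object of class `fiducial_scene` with `em_points`, `fm_points`
#'   (n x 2 matrices), `truth`, `target_em`, `target_fm`, `noise_sigma_fm`,
#'   `seed`.
#' @export
make_fiducial_scene <- function(n_beads, truth, noise_sigma_fm = 0,
                                field_size = c(512, 512), seed = 1) {
  if (n_beads < 3)
    stop("invalid scene: need at least 3 beads, transform underdetermined")
  stopifnot(inherits(truth, "ground_truth_transform"), noise_sigma_fm >= 0)
  with_seed(seed, {
    em <- matrix(NA_real_, 0, 2)
    while (nrow(em) < n_beads) {
      cand <- c(stats::runif(1, 0, field_size[1] - 1),
                stats::runif(1, 0, field_size[2] - 1))
      if (nrow(em) == 0 ||
          min(sqrt(rowSums(sweep(em, 2, cand)^2))) >= 4)
        em <- rbind(em, cand)
    }
    rownames(em) <- NULL
    inv <- invert_transform(truth)
    fm <- apply_transform(inv, em)
    if (noise_sigma_fm > 0)
      fm <- fm + matrix(stats::rnorm(2 * n_beads, 0, noise_sigma_fm), n_beads, 2)
    target_em <- c(stats::runif(1, 0.25, 0.75) * field_size[1],
                   stats::runif(1, 0.25, 0.75) * field_size[2])
    structure(list(em_points = em, fm_points = fm, truth = truth,
                   noise_sigma_fm = noise_sigma_fm,
                   target_em = target_em,
                   target_fm = as.numeric(apply_transform(inv, target_em)),
                   seed = seed),
              class = "fiducial_scene")
  })
}

#' Render spots as isotropic Gaussians on a constant background
#'
#' @param centers n x 2 matrix of (x, y) centres in pixels (0-based).
#' @param psf_sigma Gaussian sigma in pixels (> 0).
#' @param amplitude peak amplitude per spot.
#' @param noise_sigma additive Gaussian noise SD.
#' @param size image (width, height) in pixels.
#' @param seed integer seed (used only when noise_sigma > 0).
#' @param background constant background level.
#' @return numeric matrix (height x width).
#' @export
render_spot_image <- function(centers, psf_sigma, amplitude = 1,
                              noise_sigma = 0, size = c(64, 64), seed = 1,
                              background = 0) {
  stopifnot(psf_sigma > 0)
  centers <- rbind(centers)
  if (any(centers[, 1] < 0 | centers[, 1] > size[1] - 1 |
          centers[, 2] < 0 | centers[, 2] > size[2] - 1))
    stop("spot centre outside image")
  w <- size[1]; h <- size[2]
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  img <- matrix(background, h, w)
  for (i in seq_len(nrow(centers))) {
    gx <- exp(-(xs - centers[i, 1])^2 / (2 * psf_sigma^2))
    gy <- exp(-(ys - centers[i, 2])^2 / (2 * psf_sigma^2))
    img <- img + amplitude * (gy %o% gx)
  }
  if (noise_sigma > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(h * w, 0, noise_sigma), h, w))
  img
}

#' Simulate a fluorescence focal stack
#'
#' Each emitter is rendered in every plane with a defocus-dependent PSF:
#' sigma(z) = sigma0 * sqrt(1 + ((z - z_focus)/z_range)^2) and amplitude
#' scaled by (sigma0/sigma(z))^2 so integrated intensity is conserved; the
#' in-plane peak is therefore highest, and the through-focus response
#' unimodal and symmetric, at the plane nearest z_focus.
#'
#' @param emitters data frame with columns x, y (pixels), z_focus (um),
#'   channel (character), brightness.
#' @param z_step plane spacing in um (> 0).
#' @param planes number of planes (>= 3).
#' @param psf_sigma0 in-focus PSF sigma in pixels.
#' @param z_range defocus scale in um.
#' @param size image (width, height).
#' @param noise_sigma additive noise SD.
#' @param seed integer seed.
#' @return object of class `focal_stack`: `stack` (array z, y, x), `z_step`,
#'   `emitters`.
#' @export
make_focal_stack <- function(emitters, z_step = 0.3, planes = 21,
                             psf_sigma0 = 1.5, z_range = 0.45,
                             size = c(64, 64), noise_sigma = 0, seed = 1) {
  stopifnot(planes >= 3, z_step > 0)
  zmax <- (planes - 1) * z_step
  if (any(emitters$z_focus < 0 | emitters$z_focus > zmax))
    stop("emitter z_focus outside stack range [0, ", zmax, "] um")
  w <- size[1]; h <- size[2]
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  stk <- array(0, c(planes, h, w))
  for (p in seq_len(planes)) {
    z <- (p - 1) * z_step
    img <- matrix(0, h, w)
    for (i in seq_len(nrow(emitters))) {
      s <- psf_sigma0 * sqrt(1 + ((z - emitters$z_focus[i]) / z_range)^2)
      a <- emitters$brightness[i] * (psf_sigma0 / s)^2
      gx <- exp(-(xs - emitters$x[i])^2 / (2 * s^2))
      gy <- exp(-(ys - emitters$y[i])^2 / (2 * s^2))
      img <- img + a * (gy %o% gx)
    }
    stk[p, , ] <- img
  }
  if (noise_sigma > 0)
    stk <- stk + with_seed(seed, array(stats::rnorm(length(stk), 0, noise_sigma),
                                       dim(stk)))
  structure(list(stack = stk, z_step = z_step, emitters = emitters),
            class = "focal_stack")
}

#' Specification of a membrane tomogram phantom
#'
#' The phantom is an extrusion along x of a 2D cross-section drawn in the
#' (y, z) plane: a flat plasma-membrane sheet at height `sheet_y` (normal
#' along +y, extracellular side at larger y) interrupted by a furrow-like
#' invagination dipping `furrow_depth` nm toward the cytoplasm, with a tip
#' arc of radius `furrow_radius`. Membrane density is a Gaussian shell of
#' sigma `membrane_sigma` around the midline; an optional coat shell sits
#' `coat_offset` nm on the cytoplasmic side of the curved ridge, so the coat
#' diameter is 2 * (furrow_radius + coat_offset). Mass is rendered bright.
#' Defaults place the coat diameter in the 32-58 nm regime observed for
#' BAR-protein lattices.
#'
#' @param volume_shape c(nx, ny, nz) voxels.
#' @param voxel_size voxel size in Angstrom.
#' @param furrow_depth invagination depth in nm (>= 0).
#' @param furrow_radius tip radius in nm (> 0).
#' @param membrane_sigma shell sigma in nm.
#' @param coat_enabled logical; add the coat shell.
#' @param coat_offset midline-to-coat distance in nm.
#' @param coat_amplitude coat density relative to membrane (1 = equal).
#' @param coat_span_fraction fraction of the ridge arc carrying coat.
#' @param noise_sigma additive white Gaussian noise SD (density units;
#'   membrane peak is 1).
#' @param wedge_max_tilt missing-wedge tilt limit in degrees (90 = no wedge).
#' @param sheet_frac sheet height as a fraction of ny.
#' @param seed integer seed.
#' @param category "shallow" or "curved"; defaults to "curved" iff
#'   `coat_enabled` (generator couples coat presence to curvature).
#' @return object of class `membrane_phantom_spec`.
#' @export
membrane_phantom_spec <- function(volume_shape = c(48, 112, 160),
                                  voxel_size = 7,
                                  furrow_depth = 30, furrow_radius = 18,
                                  membrane_sigma = 2,
                                  coat_enabled = TRUE, coat_offset = 4,
                                  coat_amplitude = 0.9,
                                  coat_span_fraction = 0.75,
                                  noise_sigma = 0.5, wedge_max_tilt = 60,
                                  sheet_frac = 0.62, seed = 1,
                                  category = NULL) {
  stopifnot(furrow_depth >= 0, furrow_radius > 0, membrane_sigma > 0,
            coat_offset > 0, noise_sigma >= 0,
            wedge_max_tilt > 0, wedge_max_tilt <= 90)
  spec <- structure(list(
    volume_shape = as.integer(volume_shape), voxel_size = voxel_size,
    furrow_depth = furrow_depth, furrow_radius = furrow_radius,
    membrane_sigma = membrane_sigma, coat_enabled = coat_enabled,
    coat_offset = coat_offset, coat_amplitude = coat_amplitude,
    coat_span_fraction = coat_span_fraction,
    coat_diameter = 2 * (furrow_radius + coat_offset),
    noise_sigma = noise_sigma, wedge_max_tilt = wedge_max_tilt,
    sheet_frac = sheet_frac, density_polarity = "mass_bright",
    seed = seed,
    category = category %||% if (coat_enabled) "curved" else "shallow"
  ), class = "membrane_phantom_spec")
  spec
}

# Midline geometry of the phantom cross-section, in nm, in the (y, z) plane.
# Returns closures for the distance field plus the ordered midline polyline.
phantom_midline <- function(spec) {
  vs_nm <- spec$voxel_size / 10
  ny <- spec$volume_shape[2]; nz <- spec$volume_shape[3]
  y0 <- spec$sheet_frac * (ny - 1) * vs_nm   # sheet height (nm)
  zc <- (nz - 1) / 2 * vs_nm                 # furrow centre (nm)
  d <- spec$furrow_depth; r <- spec$furrow_radius
  deep <- d > 2 * r
  if (d > 0) {
    yC <- y0 - d + r
    if (deep) {
      psi_max <- pi / 2
      hw <- r
    } else {
      psi_max <- acos((r - d) / r)
      hw <- r * sin(psi_max)     # = sqrt(d (2r - d))
    }
  } else {
    yC <- y0; psi_max <- 0; hw <- 0
  }
  list(y0 = y0, zc = zc, yC = yC, r = r, d = d, deep = deep,
       psi_max = psi_max, hw = hw, vs_nm = vs_nm)
}

# Distance from grid points (Y, Z in nm) to an arc of radius rad centred at
# (yC, zc), spanning |psi| <= psi_max where psi is measured from the -y axis.
arc_distance <- function(Y, Z, yC, zc, rad, psi_max) {
  uy <- Y - yC; uz <- Z - zc
  rho <- sqrt(uy^2 + uz^2)
  psi <- atan2(uz, -uy)
  dist <- abs(rho - rad)
  out <- abs(psi) > psi_max
  if (any(out)) {
    e1 <- c(yC - rad * cos(psi_max), zc + rad * sin(psi_max))
    e2 <- c(yC - rad * cos(psi_max), zc - rad * sin(psi_max))
    d1 <- sqrt((Y - e1[1])^2 + (Z - e1[2])^2)
    d2 <- sqrt((Y - e2[1])^2 + (Z - e2[2])^2)
    dist[out] <- pmin(d1, d2)[out]
  }
  dist
}

seg_distance <- function(Y, Z, p1, p2) {
  v <- p2 - p1
  L2 <- sum(v^2)
  t <- ((Y - p1[1]) * v[1] + (Z - p1[2]) * v[2]) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((Y - (p1[1] + t * v[1]))^2 + (Z - (p1[2] + t * v[2]))^2)
}

# 2D cross-section density (ny x nz matrix, nm grid) and midline polyline.
phantom_profile2d <- function(spec) {
  g <- phantom_midline(spec)
  ny <- spec$volume_shape[2]; nz <- spec$volume_shape[3]
  yv <- (0:(ny - 1)) * g$vs_nm
  zv <- (0:(nz - 1)) * g$vs_nm
  Y <- matrix(yv, ny, nz)
  Z <- matrix(zv, ny, nz, byrow = TRUE)

  # flat sheet half-lines: y = y0, z <= zc - hw and z >= zc + hw.
  # In-z distance is zero once the point lies over the half-line, otherwise
  # the distance to its endpoint.
  dzl <- pmax(Z - (g$zc - g$hw), 0)   # to the left half-line
  dzr <- pmax(g$zc + g$hw - Z, 0)     # to the right half-line
  d_flat <- sqrt((Y - g$y0)^2 + pmin(dzl, dzr)^2)
  dist <- d_flat
  if (g$d > 0) {
    d_arc <- arc_distance(Y, Z, g$yC, g$zc, g$r, g$psi_max)
    dist <- pmin(dist, d_arc)
    if (g$deep) {
      dw1 <- seg_distance(Y, Z, c(g$yC, g$zc - g$r), c(g$y0, g$zc - g$r))
      dw2 <- seg_distance(Y, Z, c(g$yC, g$zc + g$r), c(g$y0, g$zc + g$r))
      dist <- pmin(dist, dw1, dw2)
    }
  }
  dens <- exp(-dist^2 / (2 * spec$membrane_sigma^2))
  coat_mask_dist <- NULL
  if (spec$coat_enabled && g$d > 0) {
    rc <- g$r + spec$coat_offset
    psi_c <- spec$coat_span_fraction * g$psi_max
    d_coat <- arc_distance(Y, Z, g$yC, g$zc, rc, psi_c)
    dens <- dens + spec$coat_amplitude *
      exp(-d_coat^2 / (2 * spec$membrane_sigma^2))
    coat_mask_dist <- d_coat
  } else if (g$d > 0) {
    rc <- g$r + spec$coat_offset
    psi_c <- spec$coat_span_fraction * g$psi_max
    coat_mask_dist <- arc_distance(Y, Z, g$yC, g$zc, rc, psi_c)
  }

  # ordered midline polyline (traveling +z so extracellular normal is +y
  # under the "right" side convention, n = tangent x e_x)
  step <- g$vs_nm / 2
  pts <- cbind(g$y0, seq(0, max(g$zc - g$hw - step, 0), by = step))
  if (g$d > 0) {
    if (g$deep) {
      wy <- seq(g$y0, g$yC, by = -step)
      pts <- rbind(pts, cbind(wy, g$zc - g$r))
    }
    psis <- seq(-g$psi_max, g$psi_max, length.out = 200)
    pts <- rbind(pts, cbind(g$yC - g$r * cos(psis), g$zc + g$r * sin(psis)))
    if (g$deep) {
      wy <- seq(g$yC, g$y0, by = step)
      pts <- rbind(pts, cbind(wy, g$zc + g$r))
    }
  }
  zr <- seq(g$zc + g$hw + step, (nz - 1) * g$vs_nm, by = step)
  if (length(zr)) pts <- rbind(pts, cbind(g$y0, zr))
  list(density = dens, midline_nm = pts, geom = g,
       coat_dist_nm = coat_mask_dist)
}

#' Generate a membrane tomogram phantom with ground truth
#'
#' @param spec a [membrane_phantom_spec()].
#' @return list with elements `tomogram` (a [tomogram()]), `truth` (class
#'   `phantom_truth`: `midline_points` in voxels ordered along the trace,
#'   `extracellular_side` = "+y", `true_membrane_thickness` (nm, the
#'   full-width-at-half-maximum of the Gaussian shell),
#'   `true_coat_diameter` (nm or NA), `category`, `furrow_center_vox`),
#'   and `profile2d` (noiseless cross-section, ny x nz, for reference).
#' @export
make_membrane_phantom <- function(spec) {
  stopifnot(inherits(spec, "membrane_phantom_spec"))
  g <- phantom_midline(spec)
  ny_nm <- (spec$volume_shape[2] - 1) * g$vs_nm
  nz_nm <- (spec$volume_shape[3] - 1) * g$vs_nm
  margin <- 3 * spec$membrane_sigma
  if (g$y0 - spec$furrow_depth - spec$coat_offset * spec$coat_enabled -
      margin < 0 || g$y0 + margin > ny_nm)
    stop("furrow geometry exceeds volume in y")
  if (g$hw + margin > nz_nm / 2)
    stop("furrow geometry exceeds volume in z")

  pr <- phantom_profile2d(spec)
  nx <- spec$volume_shape[1]
  ny <- spec$volume_shape[2]; nz <- spec$volume_shape[3]
  vol <- aperm(array(pr$density, c(ny, nz, nx)), c(3, 1, 2))
  if (spec$noise_sigma > 0)
    vol <- vol + with_seed(spec$seed,
                           array(stats::rnorm(length(vol), 0, spec$noise_sigma),
                                 dim(vol)))
  tomo <- tomogram(vol, spec$voxel_size)
  if (spec$wedge_max_tilt < 90)
    tomo <- apply_missing_wedge(tomo, spec$wedge_max_tilt)

  mid_vox <- cbind((nx - 1) / 2, pr$midline_nm[, 1] / g$vs_nm,
                   pr$midline_nm[, 2] / g$vs_nm)
  colnames(mid_vox) <- c("x", "y", "z")
  truth <- structure(list(
    midline_points = mid_vox,
    extracellular_side = "+y",
    true_membrane_thickness = 2 * sqrt(2 * log(2)) * spec$membrane_sigma,
    true_coat_diameter = if (spec$coat_enabled) spec$coat_diameter else NA_real_,
    category = spec$category,
    furrow_center_vox = c((nx - 1) / 2, g$yC / g$vs_nm, g$zc / g$vs_nm),
    sheet_y_vox = g$y0 / g$vs_nm,
    psi_max = g$psi_max,
    spec = spec
  ), class = "phantom_truth")
  list(tomogram = tomo, truth = truth, profile2d = pr$density)
}

#' Apply a missing-wedge filter to a volume
#'
#' Models the limited tilt range of tomographic acquisition (tilt axis = x):
#' Fourier coefficients whose (ky, kz) direction makes an angle greater than
#' `max_tilt` with the in-plane ky axis are zeroed. The mask is symmetric
#' under frequency negation, so the output is real.
#'
#' @param volume a [tomogram()] or 3D array.
#' @param max_tilt maximum tilt angle in degrees, in (0, 90].
#' @return filtered object of the same type.
#' @export
apply_missing_wedge <- function(volume, max_tilt) {
  stopifnot(max_tilt > 0, max_tilt <= 90)
  is_tomo <- inherits(volume, "tomogram")
  arr <- if (is_tomo) volume$data else volume
  if (max_tilt >= 90) return(volume)
  d <- dim(arr)
  F <- stats::fft(arr)
  keep <- wedge_mask(d, max_tilt)
  F <- F * keep
  out <- stats::fft(F, inverse = TRUE) / length(F)
  res <- Re(out)
  if (is_tomo) tomogram(res, volume$voxel_size) else res
}

# Logical keep-mask for the wedge filter, dim = d; TRUE = retained.
wedge_mask <- function(d, max_tilt) {
  fy <- fft_freq(d[2])
  fz <- fft_freq(d[3])
  ang <- atan2(abs(rep(fz, each = d[2])), abs(rep(fy, times = d[3])))
  keep2d <- matrix(ang <= deg2rad(max_tilt) + 1e-12, d[2], d[3])
  aperm(array(keep2d, c(d[2], d[3], d[1])), c(3, 1, 2))
}

fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Collapsed cross-section template from a phantom
#'
#' Convenience wrapper: builds a noiseless, wedge-filtered phantom, traces its
#' ridge (or a flat segment), extracts one box and collapses it, returning a
#' single 2D cross-section image with the membrane horizontal and the
#' extracellular side toward +y. Used to seed classification test stacks.
#'
#' @param spec a [membrane_phantom_spec()] (noise is forced to 0).
#' @param box_size box side in voxels.
#' @param at "ridge" (furrow tip) or "flat" (sheet far from the furrow).
#' @return square matrix with attributes `pixel_size` (A) and `angle_prior`.
#' @export
phantom_cross_section <- function(spec, box_size = 64,
                                  at = c("ridge", "flat")) {
  at <- match.arg(at)
  spec$noise_sigma <- 0
  spec$volume_shape <- pmax(spec$volume_shape,
                            c(box_size + 4, box_size + 4, box_size + 4))
  ph <- make_membrane_phantom(spec)
  tr <- trace_from_truth(ph$truth, at = at, span_nm = 40)
  mt <- fit_trace(tr, smoothing = 0)
  st <- extract_boxes(ph$tomogram, mt, box_size = box_size,
                      overlap_fraction = 0)
  cs <- collapse_to_2d(st, tomogram = ph$tomogram)
  i <- ceiling(length(cs$images) / 2)
  img <- rotate_image(cs$images[[i]], cs$angle_prior[i])
  attr(img, "pixel_size") <- cs$pixel_size
  attr(img, "angle_prior") <- 0
  img
}

#' Build a noisy, rotated stack of cross-section images from a template
#'
#' Emulates the per-sub-tomogram variability seen by the 2D classifier:
#' each image is the template rotated by a random in-plane angle, shifted,
#' and degraded with white Gaussian noise at the requested SNR
#' (SNR = var(signal) / var(noise)).
#'
#' @param template square matrix (e.g. from [phantom_cross_section()]).
#' @param n number of images.
#' @param rot_range rotations drawn uniformly in +/- rot_range degrees.
#' @param shift_max shifts drawn uniformly in +/- shift_max pixels (rounded
#'   to integers).
#' @param snr signal-to-noise variance ratio (Inf = noiseless).
#' @param seed integer seed.
#' @return list with `images` (list of matrices), `angle_prior` (numeric,
#'   all zero: the prior is "membrane horizontal"), `true_rot`, `true_shift`
#'   (n x 2), `pixel_size`.
#' @export
make_cross_section_stack <- function(template, n, rot_range = 15,
                                     shift_max = 0, snr = 0.5, seed = 1) {
  p <- nrow(template)
  sig_sd <- stats::sd(as.vector(template))
  noise_sd <- if (is.finite(snr)) sig_sd / sqrt(snr) else 0
  with_seed(seed, {
    rots <- stats::runif(n, -rot_range, rot_range)
    shifts <- matrix(round(stats::runif(2 * n, -shift_max, shift_max)), n, 2)
    imgs <- vector("list", n)
    for (i in seq_len(n)) {
      im <- rotate_image(template, rots[i], shifts[i, 1], shifts[i, 2])
      if (noise_sd > 0) im <- im + matrix(stats::rnorm(p * p, 0, noise_sd), p, p)
      imgs[[i]] <- im
    }
    list(images = imgs, angle_prior = rep(0, n), true_rot = rots,
         true_shift = shifts,
         pixel_size = attr(template, "pixel_size") %||% 7)
  })
}

#' Clicks along a phantom's true midline
#'
#' Emulates the manual clicking of membrane profiles: resamples the ground
#' truth midline at the nominal click interval, restricted to the furrow arc
#' ("ridge"), a flat plasma-membrane patch to the side ("flat"), or the whole
#' trace ("all").
#'
#' @param truth a `phantom_truth`.
#' @param at "ridge", "flat" or "all".
#' @param spacing_nm click interval in nm.
#' @param span_nm patch length for "flat"/"ridge".
#' @param flat_offset_nm distance of the flat patch centre from the furrow
#'   centre (nm); the paired plasma-membrane patch.
#' @return a [click_set()].
#' @export
trace_from_truth <- function(truth, at = c("all", "ridge", "flat"),
                             spacing_nm = 15, span_nm = 45,
                             flat_offset_nm = 45) {
  at <- match.arg(at)
  spec <- truth$spec
  vs_nm <- spec$voxel_size / 10
  pts <- truth$midline_points
  seg_nm <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2)) * vs_nm
  s <- c(0, cumsum(seg_nm))
  keep <- rep(TRUE, nrow(pts))
  if (at != "all") {
    zc <- truth$furrow_center_vox[3]
    yc <- truth$sheet_y_vox
    if (at == "ridge") {
      # points on the curved part: below the sheet level
      on_arc <- pts[, "y"] < yc - 0.5
      if (!any(on_arc)) on_arc <- abs(pts[, "z"] - zc) * vs_nm < span_nm / 2
      keep <- on_arc
    } else {
      z_nm <- (pts[, "z"] - zc) * vs_nm
      keep <- z_nm > flat_offset_nm - span_nm / 2 &
        z_nm < flat_offset_nm + span_nm / 2 &
        abs(pts[, "y"] - yc) < 0.5
    }
  }
  idx <- which(keep)
  s_sub <- s[idx] - s[idx[1]]
  want <- seq(0, max(s_sub), by = spacing_nm)
  pick <- vapply(want, function(w) idx[which.min(abs(s_sub - w))], integer(1))
  pick <- unique(pick)
  click_set(pts[pick, , drop = FALSE], voxel_size = spec$voxel_size,
            click_spacing_nominal = spacing_nm, side_convention = "right")
}
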