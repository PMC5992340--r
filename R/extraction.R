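# Spline-guided membrane extraction: clicked points -> spline trace ->
# overlapping sub-volumes with in-plane angle priors -> 2D collapse.

#' Construct a set of clicked membrane points
#'
#' @param points n x 3 matrix of ordered (x, y, z) voxel coordinates clicked
#'   along the membrane (n >= 2, consecutive points distinct).
#' @param voxel_size voxel size in Angstrom.
#' @param click_spacing_nominal nominal clicking interval in nm.
#' @param side_convention which side of the direction of travel is
#'   extracellular: "right" sets the normal to tangent x e_axis, "left" to
#'   e_axis x tangent, where e_axis is the tomogram x axis (the extrusion /
#'   tilt axis). When the tangent is parallel to the axis the normal falls
#'   back to the image up-direction.
#' @return object of class `click_set`.
#' @export
click_set <- function(points, voxel_size = 7, click_spacing_nominal = 15,
                      side_convention = c("right", "left")) {
  side_convention <- match.arg(side_convention)
  points <- rbind(points)
  if (nrow(points) < 2) stop("need at least 2 clicked points")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  bad <- which(seg < 1e-9)
  if (length(bad))
    stop("coincident consecutive clicks at indices: ",
         paste(bad, bad + 1, sep = "-", collapse = ", "))
  structure(list(points = unname(points), voxel_size = voxel_size,
                 click_spacing_nominal = click_spacing_nominal,
                 side_convention = side_convention),
            class = "click_set")
}

# Local orthonormal frame at a point of the trace.
#  t = unit tangent; v = in-plane "up" (projection of e_z, or e_y when the
#  tangent is near e_z); u = v x t; n = extracellular normal per side
#  convention; angle = rotation (deg, CCW) carrying the image y axis onto n,
#  i.e. rotate_image(img, angle) maps the membrane normal to +y.
trace_frame <- function(tangent, side_convention = "right") {
  t <- normalize(tangent)
  ez <- c(0, 0, 1); ey <- c(0, 1, 0); ex <- c(1, 0, 0)
  vref <- if (abs(sum(t * ez)) > 0.99) ey else ez
  v <- normalize(vref - sum(vref * t) * t)
  u <- c(v[2] * t[3] - v[3] * t[2],
         v[3] * t[1] - v[1] * t[3],
         v[1] * t[2] - v[2] * t[1])  # v x t
  cr <- c(t[2] * ex[3] - t[3] * ex[2],
          t[3] * ex[1] - t[1] * ex[3],
          t[1] * ex[2] - t[2] * ex[1])  # t x e_x
  if (sqrt(sum(cr^2)) < 1e-6) {
    n <- v
  } else {
    n <- normalize(if (side_convention == "right") cr else -cr)
  }
  angle <- rad2deg(atan2(sum(n * u), sum(n * v)))
  list(tangent = t, u = u, v = v, normal = n, angle = angle)
}

#' Fit a spline trace through clicked membrane points
#'
#' Fits cubic splines (natural, per coordinate, parameterized by cumulative
#' chord length) through the clicks; `smoothing = 0` interpolates them
#' exactly, positive values smooth via [stats::smooth.spline()] before
#' re-interpolation. Arc length is computed by dense polyline quadrature
#' (relative error below 1e-4).
#'
#' @param clicks a [click_set()].
#' @param smoothing non-negative smoothing parameter (spline lambda).
#' @return object of class `membrane_trace`.
#' @export
fit_trace <- function(clicks, smoothing = 0) {
  stopifnot(inherits(clicks, "click_set"), smoothing >= 0)
  P <- clicks$points
  n <- nrow(P)
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-n, , drop = FALSE])^2))
  tt <- c(0, cumsum(seg))
  if (smoothing > 0 && n >= 4) {
    P <- sapply(1:3, function(j)
      stats::predict(stats::smooth.spline(tt, P[, j], lambda = smoothing),
                     tt)$y)
  }
  method <- if (n == 2) "linear" else "natural"
  funs <- lapply(1:3, function(j) {
    if (n == 2) {
      slope <- (P[2, j] - P[1, j]) / (tt[2] - tt[1])
      int <- P[1, j]
      function(t, deriv = 0) if (deriv == 0) int + slope * t
        else rep(slope, length(t))
    } else stats::splinefun(tt, P[, j], method = "natural")
  })
  dense_t <- seq(0, tt[n], length.out = max(4000, 400 * n))
  dx <- cbind(funs[[1]](dense_t), funs[[2]](dense_t), funs[[3]](dense_t))
  dl <- sqrt(rowSums((dx[-1, ] - dx[-nrow(dx), ])^2))
  cum <- c(0, cumsum(dl))
  structure(list(funs = funs, t_max = tt[n], dense_t = dense_t,
                 dense_arc_vox = cum,
                 arc_length = max(cum) * clicks$voxel_size / 10,  # nm
                 voxel_size = clicks$voxel_size,
                 side_convention = clicks$side_convention,
                 clicks = clicks, samples = NULL),
            class = "membrane_trace")
}

trace_point <- function(trace, t, deriv = 0) {
  cbind(trace$funs[[1]](t, deriv), trace$funs[[2]](t, deriv),
        trace$funs[[3]](t, deriv))
}

# Map arc positions (voxel units) to spline parameters.
arc_to_param <- function(trace, arc_vox) {
  stats::approx(trace$dense_arc_vox, trace$dense_t, xout = arc_vox,
                rule = 2)$y
}

#' Resample a trace at equal arc-length spacing
#'
#' Samples sit at arc positions 0, s, 2s, ... along the trace; each carries
#' the local tangent, extracellular normal and in-plane rotation angle.
#'
#' @param trace a [fit_trace()] result.
#' @param spacing_nm sample spacing in nm (default mirrors the 15 nm
#'   clicking interval).
#' @return the trace with `samples`: data frame (arc_nm, x, y, z, tx, ty,
#'   tz, nx, ny, nz, in_plane_angle).
#' @export
resample_trace <- function(trace, spacing_nm = 15) {
  stopifnot(spacing_nm > 0)
  L <- trace$arc_length
  if (spacing_nm > L) {
    warning("spacing exceeds arc length; falling back to the two endpoints")
    arcs_nm <- c(0, L)
  } else {
    arcs_nm <- seq(0, L, by = spacing_nm)
  }
  vs <- trace$voxel_size
  tp <- arc_to_param(trace, arcs_nm * 10 / vs)
  pos <- trace_point(trace, tp)
  der <- trace_point(trace, tp, deriv = 1)
  rows <- lapply(seq_along(tp), function(i) {
    fr <- trace_frame(der[i, ], trace$side_convention)
    data.frame(arc_nm = arcs_nm[i], x = pos[i, 1], y = pos[i, 2],
               z = pos[i, 3], tx = fr$tangent[1], ty = fr$tangent[2],
               tz = fr$tangent[3], nx = fr$normal[1], ny = fr$normal[2],
               nz = fr$normal[3], in_plane_angle = fr$angle)
  })
  trace$samples <- do.call(rbind, rows)
  trace$spacing_nm <- spacing_nm
  trace
}

#' Closed-form box placement along an arc
#'
#' Centres sit at arc positions B/2 + k (1-o) B for arc length L >= B
#' (count = floor((L - B) / ((1-o) B)) + 1); a shorter trace gets a single
#' box at its midpoint.
#'
#' @param L arc length (any unit).
#' @param B box extent (same unit).
#' @param o overlap fraction in [0, 1).
#' @return numeric vector of centre arc positions.
#' @export
box_centers_along_arc <- function(L, B, o) {
  stopifnot(o >= 0, o < 1, B > 0)
  if (L < B) return(L / 2)
  spacing <- (1 - o) * B
  count <- floor((L - B) / spacing) + 1
  B / 2 + (0:(count - 1)) * spacing
}

#' Extract overlapping sub-volumes along a membrane trace
#'
#' Boxes are cubic, axis-aligned, trilinearly interpolated at sub-voxel
#' centres spaced (1 - overlap) * box_size along the arc. Out-of-bounds
#' voxels are zero-padded and the padded fraction recorded per box.
#'
#' @param tomogram a [tomogram()].
#' @param trace a [fit_trace()] result.
#' @param box_size box side in voxels (>= 8).
#' @param overlap_fraction overlap in [0, 1) (default 0.4: 40% overlap).
#' @return object of class `sub_volume_stack`: `boxes` (list of arrays),
#'   `box_size`, `overlap_fraction`, `centers` (n x 3 voxels), `tangents`,
#'   `normals`, `angle_prior` (deg), `pad_fraction`, `voxel_size`, `frames`.
#' @export
extract_boxes <- function(tomogram, trace, box_size = 32,
                          overlap_fraction = 0.4) {
  stopifnot(inherits(tomogram, "tomogram"), box_size >= 8,
            overlap_fraction >= 0, overlap_fraction < 1)
  if (any(box_size > dim(tomogram$data)))
    stop("box larger than tomogram")
  vs <- tomogram$voxel_size
  L_vox <- trace$arc_length * 10 / vs
  centers_arc <- box_centers_along_arc(L_vox, box_size, overlap_fraction)
  tp <- arc_to_param(trace, centers_arc)
  pos <- trace_point(trace, tp)
  der <- trace_point(trace, tp, deriv = 1)
  off <- (0:(box_size - 1)) - (box_size - 1) / 2
  grid <- as.matrix(expand.grid(x = off, y = off, z = off))
  boxes <- vector("list", length(tp))
  frames <- vector("list", length(tp))
  pad <- numeric(length(tp))
  for (i in seq_along(tp)) {
    pts <- sweep(grid, 2, pos[i, ], "+")
    v <- trilinear(tomogram$data, pts, fill = 0)
    pad[i] <- mean(!attr(v, "inside"))
    boxes[[i]] <- array(v, c(box_size, box_size, box_size))
    frames[[i]] <- trace_frame(der[i, ], trace$side_convention)
  }
  structure(list(boxes = boxes, box_size = as.integer(box_size),
                 overlap_fraction = overlap_fraction,
                 centers = pos, centers_arc_vox = centers_arc,
                 tangents = t(vapply(frames, `[[`, numeric(3), "tangent")),
                 normals = t(vapply(frames, `[[`, numeric(3), "normal")),
                 angle_prior = vapply(frames, `[[`, numeric(1), "angle"),
                 pad_fraction = pad, voxel_size = vs, frames = frames),
            class = "sub_volume_stack")
}

#' Collapse sub-volumes into 2D membrane cross-section images
#'
#' Each box is resampled in its local frame (image x = in-plane transverse
#' direction, image y = in-plane up, collapse axis = local membrane tangent)
#' and mean-projected along the tangent over the central fraction of the
#' box depth. Samples falling outside the available data are excluded from
#' the mean. Rotating the resulting image by its `angle_prior` maps the
#' membrane normal onto +y (extracellular side at increasing row index).
#'
#' @param stack a [extract_boxes()] result.
#' @param tomogram optional source [tomogram()]; when supplied, samples are
#'   drawn from the full volume (avoids corner loss in rotated frames),
#'   otherwise from the stored boxes.
#' @param depth_fraction fraction of the box depth to project over
#'   (default 0.6; limits contributions from membrane curving out of the
#'   cross-section plane).
#' @return object of class `collapsed_2d_stack`: `images` (list of square
#'   matrices), `pixel_size` (A), `angle_prior` (deg), `centers`,
#'   `pad_fraction`.
#' @export
collapse_to_2d <- function(stack, tomogram = NULL, depth_fraction = 0.6) {
  stopifnot(inherits(stack, "sub_volume_stack"))
  B <- stack$box_size
  half_depth <- floor(depth_fraction * B / 2)
  a_vals <- (-half_depth):half_depth
  off <- (0:(B - 1)) - (B - 1) / 2
  # image pixel (xi, yi): offset xi*u + yi*v + a*t
  uv <- expand.grid(yi = off, xi = off)   # column-major: rows vary fastest
  imgs <- vector("list", length(stack$boxes))
  pad <- numeric(length(stack$boxes))
  for (i in seq_along(stack$boxes)) {
    fr <- stack$frames[[i]]
    acc <- matrix(0, B * B, 1)
    cnt <- matrix(0, B * B, 1)
    for (a in a_vals) {
      d3 <- cbind(uv$xi * fr$u[1] + uv$yi * fr$v[1] + a * fr$tangent[1],
                  uv$xi * fr$u[2] + uv$yi * fr$v[2] + a * fr$tangent[2],
                  uv$xi * fr$u[3] + uv$yi * fr$v[3] + a * fr$tangent[3])
      if (is.null(tomogram)) {
        pts <- sweep(d3, 2, rep((B - 1) / 2, 3), "+")
        v <- trilinear(stack$boxes[[i]], pts, fill = 0)
      } else {
        pts <- sweep(d3, 2, stack$centers[i, ], "+")
        v <- trilinear(tomogram$data, pts, fill = 0)
      }
      ins <- attr(v, "inside")
      acc <- acc + v * ins
      cnt <- cnt + ins
    }
    img <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
    pad[i] <- mean(cnt == 0)
    imgs[[i]] <- matrix(img, B, B)
  }
  structure(list(images = imgs, pixel_size = stack$voxel_size,
                 angle_prior = stack$angle_prior,
                 centers = stack$centers, pad_fraction = pad,
                 box_size = B),
            class = "collapsed_2d_stack")
}

bin_axis <- function(arr, f, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- d[axis] %/% f
  a <- a[1:(m * f), , , drop = FALSE]
  dim(a) <- c(f, m * prod(d[setdiff(1:3, axis)]))
  a <- colMeans(a)
  dim(a) <- c(m, d[setdiff(1:3, axis)])
  aperm(a, order(perm))
}

#' Bin a volume by block averaging
#'
#' @param tomo a [tomogram()].
#' @param factor integer binning factor (>= 1); dimensions not divisible by
#'   the factor are edge-cropped with a warning.
#' @return binned [tomogram()] with voxel size multiplied by the factor.
#' @export
bin_volume <- function(tomo, factor) {
  stopifnot(inherits(tomo, "tomogram"), factor >= 1,
            factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1) return(tomo)
  d <- dim(tomo$data)
  if (any(d %% factor != 0))
    warning("dimensions not divisible by factor; edge voxels cropped")
  arr <- tomo$data
  for (ax in 1:3) arr <- bin_axis(arr, factor, ax)
  tomogram(arr, tomo$voxel_size * factor)
}

#' Write a collapsed stack plus STAR metadata
#' @param cs a `collapsed_2d_stack`.
#' @param mrc_path multi-image MRC output (images stacked along z).
#' @param star_path STAR metadata output.
#' @export
write_collapsed_stack <- function(cs, mrc_path, star_path) {
  B <- cs$box_size
  arr <- array(0, c(B, B, length(cs$images)))
  for (i in seq_along(cs$images)) arr[, , i] <- t(cs$images[[i]])
  write_mrc(tomogram(arr, cs$pixel_size), mrc_path)
  df <- data.frame(
    rlnImageName = sprintf("%06d@%s", seq_along(cs$images),
                           basename(mrc_path)),
    rlnCoordinateX = cs$centers[, 1], rlnCoordinateY = cs$centers[, 2],
    rlnCoordinateZ = cs$centers[, 3],
    rlnAnglePsiPrior = cs$angle_prior,
    rlnPadFraction = cs$pad_fraction)
  write_star(df, star_path)
  invisible(list(mrc = mrc_path, star = star_path))
}
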