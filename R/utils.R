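#' @keywords internal
"_PACKAGE"

# Coordinate conventions used throughout:
#  * 2D images are matrices indexed [row, col] with pixel (x, y) = (col-1, row-1),
#    i.e. 0-based, pixel-centre origin, (x, y) ordering in all interfaces.
#  * 3D volumes are arrays dim = c(nx, ny, nz) with voxel (x, y, z) =
#    (i-1, j-1, k-1); x is the fastest axis (MRC order).
#  * Angles are degrees, counter-clockwise in the (x, y) plane.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generators are pure
#' functions of their arguments without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' 2x2 rotation matrix
#' @param deg angle in degrees, counter-clockwise.
#' @return 2x2 matrix.
#' @keywords internal
rot2 <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalize zero vector")
  v / n
}

#' Build a bilinear resampling map for a square image
#'
#' The map sends destination pixel u to source position
#' R(-theta) (u - c - shift) + c, where c is the image centre; applying it
#' rotates the image content by `deg` counter-clockwise and translates it by
#' (dx, dy) pixels. Out-of-bounds samples get weight zero.
#'
#' @param p image side in pixels.
#' @param deg rotation in degrees.
#' @param dx,dy translation in pixels.
#' @return list of four index vectors and four weight vectors (length p^2,
#'   column-major over [row = y+1, col = x+1]).
#' @keywords internal
image_mapping <- function(p, deg, dx = 0, dy = 0) {
  c0 <- (p - 1) / 2
  xy <- expand.grid(y = 0:(p - 1), x = 0:(p - 1))  # column-major: y fastest
  R <- rot2(-deg)
  u <- cbind(xy$x - c0 - dx, xy$y - c0 - dy)
  src <- u %*% t(R)
  sx <- src[, 1] + c0
  sy <- src[, 2] + c0
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;  fy <- sy - y0
  idx <- function(x, y, ok) {
    i <- (y + 1) + x * p
    i[!ok] <- 1L
    i
  }
  inb <- function(x, y) x >= 0 & x <= p - 1 & y >= 0 & y <= p - 1
  ok00 <- inb(x0, y0); ok10 <- inb(x0 + 1, y0)
  ok01 <- inb(x0, y0 + 1); ok11 <- inb(x0 + 1, y0 + 1)
  list(
    i00 = idx(x0, y0, ok00),         w00 = (1 - fx) * (1 - fy) * ok00,
    i10 = idx(x0 + 1, y0, ok10),     w10 = fx * (1 - fy) * ok10,
    i01 = idx(x0, y0 + 1, ok01),     w01 = (1 - fx) * fy * ok01,
    i11 = idx(x0 + 1, y0 + 1, ok11), w11 = fx * fy * ok11
  )
}

#' Apply a resampling map to one image or a pixel-by-image matrix
#' @param X numeric matrix: either a p x p image or an (p^2) x n matrix of
#'   vectorized images.
#' @param map output of [image_mapping()].
#' @param p image side (needed when `X` is a stacked matrix).
#' @keywords internal
apply_mapping <- function(X, map, p = NULL) {
  if (is.null(p)) p <- nrow(X)
  single <- (nrow(X) == p && ncol(X) == p)
  V <- if (single) matrix(as.vector(X), ncol = 1) else X
  out <- map$w00 * V[map$i00, , drop = FALSE] +
    map$w10 * V[map$i10, , drop = FALSE] +
    map$w01 * V[map$i01, , drop = FALSE] +
    map$w11 * V[map$i11, , drop = FALSE]
  if (single) matrix(out, p, p) else out
}

#' Rotate (and optionally shift) an image about its centre
#' @param img square numeric matrix.
#' @param deg counter-clockwise rotation in degrees.
#' @param dx,dy translation in pixels.
#' @return matrix of the same size.
#' @export
rotate_image <- function(img, deg, dx = 0, dy = 0) {
  stopifnot(is.matrix(img), nrow(img) == ncol(img))
  apply_mapping(img, image_mapping(nrow(img), deg, dx, dy))
}

#' Trilinear interpolation into a 3D volume
#'
#' @param vol array dim c(nx, ny, nz).
#' @param pts n x 3 matrix of (x, y, z) voxel coordinates (0-based centres).
#' @param fill value for samples outside the volume.
#' @return numeric vector, with attribute "inside" (logical).
#' @keywords internal
trilinear <- function(vol, pts, fill = 0) {
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  x0 <- pmin(pmax(floor(x), 0), d[1] - 2)
  y0 <- pmin(pmax(floor(y), 0), d[2] - 2)
  z0 <- pmin(pmax(floor(z), 0), d[3] - 2)
  fx <- pmin(pmax(x - x0, 0), 1)
  fy <- pmin(pmax(y - y0, 0), 1)
  fz <- pmin(pmax(z - z0, 0), 1)
  at <- function(ax, ay, az) vol[cbind(ax + 1, ay + 1, az + 1)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * at(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * at(x0, y0 + 1, z0) +
    fx * fy * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * at(x0, y0, z0 + 1) +
    fx * (1 - fy) * fz * at(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * at(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * at(x0 + 1, y0 + 1, z0 + 1)
  v[!inside] <- fill
  attr(v, "inside") <- inside
  v
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
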