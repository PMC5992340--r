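# FM -> EM registration: sub-pixel spot localization, transform fitting from
# fiducial pairs, target prediction with leave-one-out accuracy, focal-plane
# attachment scoring.

#' Construct a point-match set of paired fiducial coordinates
#'
#' @param fm n x 2 matrix of FM coordinates (pixels).
#' @param em n x 2 matrix of EM coordinates (pixels).
#' @param labels per-pair identifiers (unique).
#' @return object of class `point_match_set`.
#' @export
point_match_set <- function(fm, em, labels = NULL) {
  fm <- rbind(fm); em <- rbind(em)
  if (nrow(fm) != nrow(em)) stop("fm and em must have equal length")
  if (nrow(fm) < 3) stop("need at least 3 point pairs")
  labels <- labels %||% sprintf("bead_%02d", seq_len(nrow(fm)))
  if (anyDuplicated(labels)) stop("duplicate labels")
  structure(list(fm = fm, em = em, labels = labels),
            class = "point_match_set")
}

subset_matches <- function(m, keep) {
  structure(list(fm = m$fm[keep, , drop = FALSE],
                 em = m$em[keep, , drop = FALSE],
                 labels = m$labels[keep]), class = "point_match_set")
}

collinearity_check <- function(pts, tol = 1e-9) {
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Fit an FM -> EM transform from matched fiducials
#'
#' Least-squares minimizer of sum ||em_i - (A fm_i + t)||^2. The affine model
#' (default) absorbs magnification anisotropy and shear between the two
#' modalities; the similarity model constrains A = s R with R orthogonal
#' (reflection permitted), fitted by the Umeyama/Procrustes closed form.
#'
#' @param matches a [point_match_set()].
#' @param model_tag "affine" or "similarity".
#' @return object of class `fitted_transform`: `linear_part`, `translation`,
#'   `model_tag`, `rms_residual` (EM px), `per_point_residuals`.
#' @export
fit_transform <- function(matches, model_tag = c("affine", "similarity")) {
  model_tag <- match.arg(model_tag)
  fm <- matches$fm; em <- matches$em
  n <- nrow(fm)
  if (model_tag == "affine") {
    if (n < 3) stop("affine fit needs at least 3 pairs")
    if (collinearity_check(fm))
      stop("degenerate geometry: FM points are collinear (",
           paste(matches$labels, collapse = ", "), ")")
    X <- cbind(fm, 1)
    beta <- qr.solve(X, em)            # 3 x 2
    A <- t(beta[1:2, ])
    tr <- as.numeric(beta[3, ])
  } else {
    if (n < 2) stop("similarity fit needs at least 2 pairs")
    mu_f <- colMeans(fm); mu_e <- colMeans(em)
    Fc <- sweep(fm, 2, mu_f); Ec <- sweep(em, 2, mu_e)
    S <- crossprod(Ec, Fc) / n         # cov(em, fm)
    sv <- svd(S)
    R <- sv$u %*% t(sv$v)              # best orthogonal map, reflection allowed
    varf <- sum(Fc^2) / n
    if (varf <= 0) stop("degenerate geometry: coincident FM points")
    s <- sum(sv$d) / varf
    A <- s * R
    tr <- as.numeric(mu_e - A %*% mu_f)
  }
  pred <- t(A %*% t(fm) + tr)
  res <- sqrt(rowSums((em - pred)^2))
  structure(list(linear_part = A, translation = tr, model_tag = model_tag,
                 rms_residual = sqrt(mean(res^2)),
                 per_point_residuals = res),
            class = "fitted_transform")
}

#' @export
print.fitted_transform <- function(x, ...) {
  cat(sprintf("<fitted_transform> %s, rms residual %.4g EM px\n",
              x$model_tag, x$rms_residual))
  invisible(x)
}

#' Predict a target's EM position with a leave-one-out accuracy estimate
#'
#' The accuracy estimate refits the transform n times, each time leaving one
#' fiducial out and measuring how far its predicted EM position falls from
#' its true one; the mean of those misses estimates the prediction error at
#' the target.
#'
#' @param transform a `fitted_transform` fitted from `matches`.
#' @param fm_point length-2 FM coordinate of the target.
#' @param matches the [point_match_set()] used for the fit.
#' @return object of class `predicted_target`: `em_position`,
#'   `loo_error_estimate` (EM px; NA with `loo_defined = FALSE` when there
#'   are too few pairs to leave one out).
#' @export
predict_target <- function(transform, fm_point, matches) {
  em_pos <- as.numeric(apply_transform(transform, fm_point))
  n <- nrow(matches$fm)
  min_n <- if (transform$model_tag == "affine") 3 else 2
  if (n < min_n + 1) {
    return(structure(list(em_position = em_pos,
                          loo_error_estimate = NA_real_,
                          loo_defined = FALSE),
                     class = "predicted_target"))
  }
  errs <- vapply(seq_len(n), function(i) {
    sub <- subset_matches(matches, setdiff(seq_len(n), i))
    tf_i <- fit_transform(sub, transform$model_tag)
    pred_i <- apply_transform(tf_i, matches$fm[i, ])
    sqrt(sum((matches$em[i, ] - pred_i)^2))
  }, numeric(1))
  structure(list(em_position = em_pos, loo_error_estimate = mean(errs),
                 loo_defined = TRUE, loo_per_point = errs),
            class = "predicted_target")
}

#' Localize spots with sub-pixel precision
#'
#' Fits an isotropic 2D Gaussian plus constant background to a window around
#' each approximate centre by least squares. Non-convergent or degenerate
#' windows are flagged, never raised as errors, so one bad bead cannot abort
#' a batch.
#'
#' @param image numeric matrix (row = y + 1, col = x + 1).
#' @param approx_centers n x 2 matrix of (x, y) approximate centres.
#' @param window_radius half-size of the fit window in pixels (recommend
#'   >= 3x the expected sigma).
#' @return data frame with columns x, y (sub-pixel centre), amplitude,
#'   background, sigma, fit_residual, ok.
#' @export
localize_spots <- function(image, approx_centers, window_radius = 7) {
  approx_centers <- rbind(approx_centers)
  h <- nrow(image); w <- ncol(image)
  out <- lapply(seq_len(nrow(approx_centers)), function(i) {
    cx <- round(approx_centers[i, 1]); cy <- round(approx_centers[i, 2])
    x0 <- cx - window_radius; x1 <- cx + window_radius
    y0 <- cy - window_radius; y1 <- cy + window_radius
    if (x0 < 0 || y0 < 0 || x1 > w - 1 || y1 > h - 1)
      stop("fit window outside image for spot ", i)
    win <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
    xs <- x0:x1; ys <- y0:y1
    fail <- data.frame(x = NA_real_, y = NA_real_, amplitude = NA_real_,
                       background = NA_real_, sigma = NA_real_,
                       fit_residual = NA_real_, ok = FALSE)
    rng <- diff(range(win))
    if (!is.finite(rng) || rng <= .Machine$double.eps) return(fail)
    bg0 <- stats::median(win)
    a0 <- max(win) - bg0
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    wpos <- pmax(win - bg0, 0)
    sw <- sum(wpos)
    mx <- sum(rep(xs, each = length(ys)) * wpos) / sw
    my <- sum(rep(ys, times = length(xs)) * wpos) / sw
    s0 <- max(sqrt(sum(((rep(xs, each = length(ys)) - mx)^2 +
                        (rep(ys, times = length(xs)) - my)^2) * wpos) /
                     (2 * sw)), 0.8)
    model <- function(p) {
      gx <- exp(-(xs - p[1])^2 / (2 * p[5]^2))
      gy <- exp(-(ys - p[2])^2 / (2 * p[5]^2))
      p[4] + p[3] * (gy %o% gx)
    }
    obj <- function(p) sum((win - model(p))^2)
    fit <- try(stats::optim(c(mx, my, a0, bg0, s0), obj, method = "L-BFGS-B",
                            lower = c(x0, y0, 0, -Inf, 0.3),
                            upper = c(x1, y1, Inf, Inf, window_radius),
                            control = list(maxit = 500, factr = 1e4)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(fail)
    p <- fit$par
    data.frame(x = p[1], y = p[2], amplitude = p[3], background = p[4],
               sigma = p[5],
               fit_residual = sqrt(fit$value / length(win)),
               ok = fit$convergence == 0)
  })
  do.call(rbind, out)
}

#' Estimate the focus height of a signal from a focal stack
#'
#' Evaluates a focus metric per plane in a small window around the signal's
#' (x, y) position and refines the peak by parabolic interpolation of the
#' three planes around the maximum. Signals whose metric is monotone across
#' the stack (focus outside the acquired range) are flagged.
#'
#' @param stack a `focal_stack` or plain array (z, y, x).
#' @param xy length-2 (x, y) position in pixels.
#' @param metric "peak_intensity" (max in window) or "sharpness" (local
#'   gradient energy).
#' @param z_step plane spacing in um (taken from the stack if available).
#' @param window half-size of the evaluation window.
#' @return list with `z` (um from plane 0), `plane` (0-based nearest plane),
#'   `in_range` (FALSE when the metric peaks at either end), `metric_values`.
#' @export
focus_z <- function(stack, xy, metric = c("peak_intensity", "sharpness"),
                    z_step = NULL, window = 3) {
  metric <- match.arg(metric)
  arr <- if (inherits(stack, "focal_stack")) stack$stack else stack
  z_step <- z_step %||% (if (inherits(stack, "focal_stack")) stack$z_step else 1)
  np <- dim(arr)[1]
  if (np < 3) stop("need at least 3 planes")
  h <- dim(arr)[2]; w <- dim(arr)[3]
  cx <- round(xy[1]); cy <- round(xy[2])
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) stop("xy outside field")
  x0 <- max(cx - window, 0); x1 <- min(cx + window, w - 1)
  y0 <- max(cy - window, 0); y1 <- min(cy + window, h - 1)
  vals <- vapply(seq_len(np), function(p) {
    win <- arr[p, (y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
    if (metric == "peak_intensity") max(win)
    else sum(diff(win)^2) + sum(t(diff(t(win)))^2)
  }, numeric(1))
  pk <- which.max(vals)
  if (pk == 1 || pk == np) {
    return(list(z = (pk - 1) * z_step, plane = pk - 1, in_range = FALSE,
                metric_values = vals))
  }
  a <- vals[pk - 1]; b <- vals[pk]; c <- vals[pk + 1]
  denom <- a - 2 * b + c
  delta <- if (abs(denom) < 1e-300) 0 else 0.5 * (a - c) / denom
  delta <- max(min(delta, 0.5), -0.5)
  list(z = (pk - 1 + delta) * z_step, plane = pk - 1, in_range = TRUE,
       metric_values = vals)
}

#' Score focal-plane attachment of targets against a reference
#'
#' A section area is considered flat and well attached when its signals focus
#' in the same plane as the reference (carbon film / fiducials); a large
#' focus offset indicates a detached, unstable area. The comparison is
#' inclusive: delta_z equal to the threshold still counts as attached.
#'
#' @param z_targets numeric vector of target focus heights (um).
#' @param z_reference reference focus height (um).
#' @param threshold attachment threshold in um (default 1).
#' @return data frame: z_target, z_reference, delta_z, threshold, attached.
#' @export
attachment_check <- function(z_targets, z_reference, threshold = 1) {
  stopifnot(threshold > 0)
  dz <- abs(z_targets - z_reference)
  data.frame(z_target = z_targets, z_reference = z_reference,
             delta_z = dz, threshold = threshold,
             attached = dz <= threshold)
}
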