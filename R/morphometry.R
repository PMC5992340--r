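# Morphometry of class averages: band profiles across the membrane, the
# peak/dip mean-level thickness rule, relative membrane thickness with
# eisosome/plasma-membrane pairing, Welch comparison of shallow vs curved
# cohorts, and least-squares circle fits for coat curvature.

#' Average band profile across a class average
#'
#' Averages the central `band_width` pixel columns (the membrane runs along
#' x after prior alignment), giving one density profile across the membrane
#' (along y). Density is mass-bright.
#'
#' @param class_average square (or rectangular) numeric matrix.
#' @param band_width number of central columns to average (odd; default 7).
#' @param pixel_size pixel size in Angstrom (taken from an attribute or a
#'   `collapsed_2d_stack` when available).
#' @param extracellular_direction "increasing_index" (default: extracellular
#'   side at larger y / row index, the package's collapse convention) or
#'   "decreasing_index".
#' @return object of class `band_profile`: `values`, `pixel_size`,
#'   `extracellular_direction`.
#' @export
band_profile <- function(class_average, band_width = 7, pixel_size = NULL,
                         extracellular_direction = c("increasing_index",
                                                     "decreasing_index")) {
  extracellular_direction <- match.arg(extracellular_direction)
  if (band_width %% 2 == 0)
    stop("band_width must be odd (centre column undefined)")
  if (band_width > ncol(class_average))
    stop("band_width exceeds image width")
  pixel_size <- pixel_size %||% attr(class_average, "pixel_size") %||% 7
  mid <- (ncol(class_average) + 1) / 2
  half <- (band_width - 1) / 2
  cols <- (floor(mid) - half):(floor(mid) + half)
  vals <- rowMeans(class_average[, cols, drop = FALSE])
  structure(list(values = as.numeric(vals), pixel_size = pixel_size,
                 extracellular_direction = extracellular_direction),
            class = "band_profile")
}

# Local minima of a vector; boundary samples count when below their single
# neighbour.
local_minima <- function(v) {
  n <- length(v)
  if (n < 2) return(integer(0))
  idx <- integer(0)
  if (v[1] < v[2]) idx <- c(idx, 1L)
  if (n > 2)
    idx <- c(idx, 1L + which(v[2:(n - 1)] <= v[1:(n - 2)] &
                             v[2:(n - 1)] <= v[3:n]))
  if (v[n] < v[n - 1]) idx <- c(idx, n)
  idx
}

#' Measure membrane (+ coat) thickness from a band profile
#'
#' Implements the mean-level width rule: the threshold is the mean of the
#' highest peak and the deepest local minimum on the extracellular side of
#' that peak; the width is the contiguous interval containing the peak where
#' the profile stays at or above the threshold, with sub-sample endpoints by
#' linear interpolation. Thickness = width * pixel_size / 10 (nm).
#'
#' @param profile a [band_profile()].
#' @param membrane_role "eisosome" or "pm_patch" (carried into records).
#' @param interpolate logical; linear sub-sample interpolation of the
#'   interval endpoints (default TRUE; FALSE counts whole samples).
#' @return object of class `thickness_record`: `peak_value`, `dip_value`,
#'   `threshold`, `width_px`, `thickness_nm`, `profile`, `membrane_role`,
#'   `ok`, `flags`.
#' @export
measure_thickness <- function(profile, membrane_role = c("eisosome",
                                                         "pm_patch"),
                              interpolate = TRUE) {
  membrane_role <- match.arg(membrane_role)
  v <- profile$values
  n <- length(v)
  flags <- character(0)
  fail <- function(reason) {
    structure(list(peak_value = NA_real_, dip_value = NA_real_,
                   threshold = NA_real_, width_px = NA_real_,
                   thickness_nm = NA_real_, profile = profile,
                   membrane_role = membrane_role, ok = FALSE,
                   flags = reason), class = "thickness_record")
  }
  pk_all <- which(v == max(v))
  if (length(pk_all) > 1) {
    runs <- split(pk_all, cumsum(c(1, diff(pk_all) != 1)))
    main <- runs[[which.max(lengths(runs))]]
    pk <- main[ceiling(length(main) / 2)]
    flags <- c(flags, "plateaued_max_center_convention")
  } else pk <- pk_all
  if (pk == 1 || pk == n) return(fail("peak_at_profile_end"))

  extr <- if (profile$extracellular_direction == "increasing_index")
    (pk + 1):n else 1:(pk - 1)
  side <- v[extr]
  mins <- local_minima(side)
  if (length(mins) == 0) return(fail("no_extracellular_dip"))
  dip_rel <- mins[which.min(side[mins])]
  dip <- side[dip_rel]
  if (dip >= v[pk]) return(fail("no_extracellular_dip"))
  thr <- (v[pk] + dip) / 2

  # contiguous >= threshold interval containing the peak
  lo <- pk
  while (lo > 1 && v[lo - 1] >= thr) lo <- lo - 1
  hi <- pk
  while (hi < n && v[hi + 1] >= thr) hi <- hi + 1
  left <- lo; right <- hi
  if (interpolate) {
    if (lo > 1) left <- lo - (v[lo] - thr) / (v[lo] - v[lo - 1])
    else flags <- c(flags, "interval_clipped_left")
    if (hi < n) right <- hi + (v[hi] - thr) / (v[hi] - v[hi + 1])
    else flags <- c(flags, "interval_clipped_right")
  } else {
    # whole-sample mode: each sample owns a unit pixel
    left <- lo - 0.5; right <- hi + 0.5
    if (lo == 1) flags <- c(flags, "interval_clipped_left")
    if (hi == n) flags <- c(flags, "interval_clipped_right")
  }
  width <- right - left
  structure(list(peak_value = v[pk], dip_value = dip, threshold = thr,
                 width_px = width,
                 thickness_nm = width * profile$pixel_size / 10,
                 profile = profile, membrane_role = membrane_role,
                 ok = TRUE, flags = flags),
            class = "thickness_record")
}

#' Relative membrane thickness of an eisosome vs its plasma-membrane patch
#'
#' @param eiso [measure_thickness()] record for the eisosome membrane.
#' @param pm record for the paired plasma-membrane patch (nearest patch,
#'   within the stated pairing distance).
#' @param category "shallow" or "curved".
#' @return object of class `relative_thickness`: `eisosome`, `pm`, `ratio`,
#'   `category`.
#' @export
relative_thickness <- function(eiso, pm, category = c("shallow", "curved")) {
  category <- match.arg(category)
  if (!isTRUE(eiso$ok) || !isTRUE(pm$ok))
    stop("both thickness measurements must be valid")
  if (!isTRUE(all.equal(eiso$profile$pixel_size, pm$profile$pixel_size)))
    stop("pixel sizes differ between eisosome and plasma-membrane records")
  if (pm$thickness_nm <= 0) stop("plasma-membrane thickness is zero")
  structure(list(eisosome = eiso, pm = pm,
                 ratio = eiso$thickness_nm / pm$thickness_nm,
                 category = category),
            class = "relative_thickness")
}

#' Two-tailed Welch test (unpooled variances, Satterthwaite df)
#'
#' @param group_a,group_b numeric vectors (n >= 2 each; at least one group
#'   with nonzero variance).
#' @return object of class `welch_result`: `t_statistic`, `df`,
#'   `p_two_tailed`, `group_means`, `group_sds`, `group_ns`, `degenerate`.
#' @export
welch_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 observations")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      degenerate <- TRUE
      t <- 0; df <- na + nb - 2; p <- 1
    } else stop("both variances zero with unequal means: t undefined")
  } else {
    se2 <- va / na + vb / nb
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t_statistic = t, df = df, p_two_tailed = p,
                 group_means = c(ma, mb), group_sds = c(sqrt(va), sqrt(vb)),
                 group_ns = c(na, nb), degenerate = degenerate),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-tailed t-test: t = %.4f, df = %.2f, p = %.4g\n",
              x$t_statistic, x$df, x$p_two_tailed))
  invisible(x)
}

#' Least-squares circle fit for coat curvature
#'
#' Algebraic (Kasa) seed refined by geometric Gauss-Newton minimization of
#' sum (|p_i - c| - r)^2; the least-squares circle through points clicked
#' along the densest part of the coat.
#'
#' @param points n x 2 matrix of (x, y) coordinates in pixels (n >= 3,
#'   non-collinear).
#' @param pixel_size pixel size in Angstrom.
#' @return object of class `coat_circle_fit`: `center` (px), `radius_px`,
#'   `diameter_nm`, `rms_residual` (px).
#' @export
fit_coat_circle <- function(points, pixel_size = 7) {
  points <- rbind(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  if (collinearity_check(points, tol = 1e-9))
    stop("collinear points: circle radius is infinite")
  # Kasa: x^2 + y^2 = a x + b y + c
  A <- cbind(x, y, 1)
  rhs <- x^2 + y^2
  sol <- qr.solve(A, rhs)
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r <- sqrt(sol[3] + cx^2 + cy^2)
  # geometric refinement
  par <- c(cx, cy, r)
  for (it in 1:50) {
    dx <- x - par[1]; dy <- y - par[2]
    di <- sqrt(dx^2 + dy^2)
    res <- di - par[3]
    J <- cbind(-dx / di, -dy / di, -1)
    step <- try(qr.solve(J, -res), silent = TRUE)
    if (inherits(step, "try-error")) break
    par <- par + step
    if (sqrt(sum(step^2)) < 1e-12 * max(1, par[3])) break
  }
  par <- unname(par)
  dx <- x - par[1]; dy <- y - par[2]
  res <- sqrt(dx^2 + dy^2) - par[3]
  structure(list(center = par[1:2], radius_px = par[3],
                 diameter_nm = 2 * par[3] * pixel_size / 10,
                 rms_residual = sqrt(mean(res^2))),
            class = "coat_circle_fit")
}

#' Pick points along the densest coat arc of a cross-section image
#'
#' Automated stand-in for clicking along the coat: casts rays from the
#' furrow centre over a fan of angles and records the sub-pixel radius of
#' the outermost radial local maximum inside the search window (the outer
#' density layer a annotator would click; the membrane shell lies further
#' in), refined by parabolic interpolation. Rays without an interior local
#' maximum (coat not discernible as a separate layer) are dropped.
#'
#' @param img cross-section image (matrix, pixel (x, y) = (col-1, row-1)).
#' @param center length-2 (x, y) centre of the furrow arc in pixels.
#' @param r_range c(min, max) search radii in pixels.
#' @param angles ray angles in degrees (0 = toward -y, the furrow tip
#'   direction; positive toward +x).
#' @return n x 2 matrix of (x, y) ridge points.
#' @export
coat_ridge_points <- function(img, center, r_range,
                              angles = seq(-60, 60, by = 10)) {
  rs <- seq(r_range[1], r_range[2], by = 0.25)
  pts <- matrix(NA_real_, length(angles), 2)
  h <- nrow(img); w <- ncol(img)
  for (i in seq_along(angles)) {
    a <- deg2rad(angles[i])
    dx <- sin(a); dy <- -cos(a)
    px <- center[1] + rs * dx
    py <- center[2] + rs * dy
    ok <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
    if (sum(ok) < 3) next
    x0 <- floor(px[ok]); y0 <- floor(py[ok])
    fx <- px[ok] - x0; fy <- py[ok] - y0
    vals <- (1 - fx) * (1 - fy) * img[cbind(y0 + 1, x0 + 1)] +
      fx * (1 - fy) * img[cbind(y0 + 1, pmin(x0 + 2, w))] +
      (1 - fx) * fy * img[cbind(pmin(y0 + 2, h), x0 + 1)] +
      fx * fy * img[cbind(pmin(y0 + 2, h), pmin(x0 + 2, w))]
    nv <- length(vals)
    lmax <- 1L + which(vals[2:(nv - 1)] >= vals[1:(nv - 2)] &
                       vals[2:(nv - 1)] >= vals[3:nv])
    if (length(lmax) == 0) next
    j <- max(lmax)                       # outermost layer
    rj <- rs[ok][j]
    a1 <- vals[j - 1]; b1 <- vals[j]; c1 <- vals[j + 1]
    den <- a1 - 2 * b1 + c1
    if (abs(den) > 1e-300)
      rj <- rj + 0.25 * max(min(0.5 * (a1 - c1) / den, 0.5), -0.5)
    pts[i, ] <- center + rj * c(dx, dy)
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

#' Cohort summary and Welch comparison of shallow vs curved eisosomes
#'
#' @param records list of [relative_thickness()] objects (>= 2 per
#'   category, both categories present).
#' @return object of class `cohort_report`: `table` (per-record data
#'   frame), `summary` (per-category mean, sd, n), `welch` (shallow vs
#'   curved comparison).
#' @export
cohort_report <- function(records) {
  if (length(records) == 0) stop("no records")
  df <- data.frame(
    category = vapply(records, `[[`, character(1), "category"),
    ratio = vapply(records, `[[`, numeric(1), "ratio"))
  for (cat in c("shallow", "curved"))
    if (sum(df$category == cat) < 2)
      stop("need at least 2 records in category '", cat, "'")
  summary <- do.call(rbind, lapply(split(df$ratio, df$category),
    function(r) data.frame(mean = mean(r), sd = stats::sd(r),
                           n = length(r))))
  summary$category <- rownames(summary)
  welch <- welch_test(df$ratio[df$category == "shallow"],
                      df$ratio[df$category == "curved"])
  structure(list(table = df, summary = summary, welch = welch),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Relative membrane thickness by category:\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-8s mean %.3f +/- %.3f (n = %d)\n",
                x$summary$category[i], x$summary$mean[i], x$summary$sd[i],
                x$summary$n[i]))
  print(x$welch)
  invisible(x)
}

#' Write a cohort report as CSV plus a Markdown summary
#' @param report a [cohort_report()].
#' @param csv_path per-record CSV output.
#' @param md_path Markdown report output.
#' @export
write_cohort_report <- function(report, csv_path, md_path) {
  utils::write.csv(report$table, csv_path, row.names = FALSE)
  md <- c("# Relative membrane thickness", "",
          "| category | mean | sd | n |", "|---|---|---|---|",
          sprintf("| %s | %.3f | %.3f | %d |", report$summary$category,
                  report$summary$mean, report$summary$sd,
                  report$summary$n), "",
          sprintf("Welch two-tailed test (shallow vs curved): t = %.4f, df = %.2f, p = %.4g",
                  report$welch$t_statistic, report$welch$df,
                  report$welch$p_two_tailed))
  writeLines(md, md_path)
  invisible(list(csv = csv_path, md = md_path))
}
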