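# Grouped dose-symmetric tilt schemes: generation, dose allocation, validation.

#' Generate a grouped dose-symmetric tilt scheme
#'
#' Acquisition starts at 0 degrees and alternates sides of the untilted view
#' in blocks of `group_size` images, each block continuing outward on its
#' side, so that low-tilt (high-value) images accumulate the least dose.
#' The 0-degree image counts as the first image of the first group: with
#' groups of four and a 1-degree increment the first block is {0, 1, 2, 3}.
#'
#' @param max_tilt maximum tilt in degrees (must be a multiple of
#'   `increment`).
#' @param increment tilt increment in degrees (> 0).
#' @param group_size images per side-block (>= 1).
#' @param start_side which side the first group tilts toward.
#' @return object of class `tilt_scheme`: `ordered_angles` (acquisition
#'   order), `group_size`, `increment`, `max_tilt`, `start_side`,
#'   `per_image_dose` (NULL until [allocate_dose()]).
#' @export
generate_scheme <- function(max_tilt = 60, increment = 1, group_size = 4,
                            start_side = c("positive", "negative")) {
  start_side <- match.arg(start_side)
  stopifnot(group_size >= 1, increment > 0, max_tilt > 0)
  n <- max_tilt / increment
  if (abs(n - round(n)) > 1e-9)
    stop("max_tilt must be a whole multiple of increment")
  n <- round(n)
  sgn <- if (start_side == "positive") 1 else -1
  first <- sgn * increment * (1:n)        # start side, outward
  second <- -sgn * increment * (1:n)      # other side, outward
  # 0 deg leads the first block; with groups of one it forms a block of its
  # own and the start side still takes the next turn
  k0 <- min(group_size - 1, n)
  ordered <- c(0, if (k0 > 0) first[seq_len(k0)])
  i1 <- k0 + 1; i2 <- 1
  take_first <- (k0 == 0)
  while (i1 <= n || i2 <= n) {
    if (take_first && i1 <= n) {
      k <- min(group_size, n - i1 + 1)
      ordered <- c(ordered, first[i1:(i1 + k - 1)])
      i1 <- i1 + k
    } else if (!take_first && i2 <= n) {
      k <- min(group_size, n - i2 + 1)
      ordered <- c(ordered, second[i2:(i2 + k - 1)])
      i2 <- i2 + k
    }
    take_first <- !take_first
  }
  structure(list(ordered_angles = ordered, group_size = as.integer(group_size),
                 increment = increment, max_tilt = max_tilt,
                 start_side = start_side, per_image_dose = NULL),
            class = "tilt_scheme")
}

#' @export
print.tilt_scheme <- function(x, ...) {
  cat(sprintf("<tilt_scheme> +/-%g deg, %g deg increment, groups of %d, %d images\n",
              x$max_tilt, x$increment, x$group_size, length(x$ordered_angles)))
  if (!is.null(x$per_image_dose))
    cat(sprintf("  total dose %.4g e-/A^2 (%.4g per image)\n",
                sum(x$per_image_dose), x$per_image_dose[1]))
  invisible(x)
}

#' Allocate a total electron dose uniformly over a tilt scheme
#'
#' @param scheme a [generate_scheme()] result.
#' @param total_dose total dose over the series in e-/A^2 (> 0).
#' @return the scheme with `per_image_dose` filled in (sum equals
#'   `total_dose` to 1e-9 relative).
#' @export
allocate_dose <- function(scheme, total_dose) {
  stopifnot(inherits(scheme, "tilt_scheme"), total_dose > 0)
  n <- length(scheme$ordered_angles)
  scheme$per_image_dose <- rep(total_dose / n, n)
  scheme
}

#' Validate a tilt scheme against its invariants
#'
#' @param scheme a `tilt_scheme` (possibly hand-edited or read from disk).
#' @return character vector of violations; empty when the scheme is valid.
#' @export
validate_scheme <- function(scheme) {
  v <- character(0)
  a <- scheme$ordered_angles
  dup <- which(duplicated(a))
  if (length(dup))
    v <- c(v, sprintf("duplicate angle at index %d (%g deg)", dup, a[dup]))
  expect <- seq(-scheme$max_tilt, scheme$max_tilt, by = scheme$increment)
  missing <- setdiff(round(expect, 9), round(a, 9))
  if (length(missing))
    v <- c(v, sprintf("coverage violation: angle %g deg missing", missing))
  extra <- setdiff(round(a, 9), round(expect, 9))
  if (length(extra))
    v <- c(v, sprintf("unexpected angle %g deg", extra))
  if (length(a) && abs(a[1]) > 1e-9)
    v <- c(v, "first acquired angle is not 0 deg")
  if (!is.null(scheme$per_image_dose)) {
    if (length(scheme$per_image_dose) != length(a))
      v <- c(v, "per_image_dose length does not match angle count")
    if (any(scheme$per_image_dose < 0))
      v <- c(v, "negative per-image dose")
  }
  v
}

#' Cumulative dose already applied when each angle is acquired
#' @param scheme a dosed `tilt_scheme`.
#' @return data frame (order, angle, dose, cumulative_dose_before).
#' @export
dose_table <- function(scheme) {
  stopifnot(!is.null(scheme$per_image_dose))
  data.frame(order = seq_along(scheme$ordered_angles),
             angle = scheme$ordered_angles,
             dose = scheme$per_image_dose,
             cumulative_dose_before = cumsum(scheme$per_image_dose) -
               scheme$per_image_dose)
}

#' Write a tilt scheme as a plain-text angle file (one angle per line)
#' @param scheme a `tilt_scheme`.
#' @param path output file.
#' @export
write_tilt_angles <- function(scheme, path) {
  writeLines(format(scheme$ordered_angles, trim = TRUE), path)
  invisible(path)
}

#' Write a tilt scheme as CSV with (order, angle, dose)
#' @param scheme a dosed `tilt_scheme`.
#' @param path output file.
#' @export
write_tilt_csv <- function(scheme, path) {
  utils::write.csv(dose_table(scheme)[, c("order", "angle", "dose")],
                   path, row.names = FALSE)
  invisible(path)
}
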