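# End-to-end phantom pipeline: phantom -> clicked traces -> extraction ->
# 2D collapse -> single-class averaging -> thickness morphometry -> paired
# relative thickness, and seeded cohorts thereof.

#' Class-average a collapsed stack and measure membrane thickness
#'
#' Runs single-class regularized-likelihood averaging on the collapsed
#' cross-sections (boxes with more than `max_pad` padded fraction are
#' excluded) and applies the band-profile mean-level thickness rule to the
#' resulting average.
#'
#' @param cs a `collapsed_2d_stack`.
#' @param membrane_role "eisosome" or "pm_patch".
#' @param config a [classify_config()]; default: K = 1, a narrow rotation
#'   search around the spline priors.
#' @param band_width band width for [band_profile()].
#' @param max_pad maximum tolerated padded fraction per box.
#' @return a `thickness_record` with the class average in attribute
#'   `class_average`.
#' @export
average_and_measure <- function(cs, membrane_role = "eisosome",
                                config = NULL, band_width = 7,
                                max_pad = 0.25) {
  keep <- which(cs$pad_fraction <= max_pad)
  if (length(keep) == 0) stop("all boxes exceed the padding limit")
  # apply the angle prior up front so a single narrow residual search
  # suffices regardless of each box's own prior
  imgs <- lapply(keep, function(i)
    rotate_image(cs$images[[i]], cs$angle_prior[i]))
  config <- config %||% classify_config(
    n_classes = 1, n_iterations = 8, angle_search_halfwidth = 4,
    angle_step = 2, max_shift = 1, shift_step = 1,
    regularization_weight = 1, seed = 1)
  res <- classify(list(images = imgs, angle_prior = rep(0, length(imgs)),
                       pixel_size = cs$pixel_size), config)
  avg <- res$class_averages[[1]]
  bp <- band_profile(avg, band_width = band_width,
                     pixel_size = cs$pixel_size)
  rec <- measure_thickness(bp, membrane_role)
  attr(rec, "class_average") <- avg
  attr(rec, "classification") <- res
  rec
}

#' Relative membrane thickness of one phantom, measured end to end
#'
#' Generates the phantom, clicks its eisosome membrane (the invagination)
#' and a nearby plasma-membrane patch along the ground-truth midline at the
#' nominal 15 nm interval, fits splines, extracts overlapping boxes,
#' collapses, class-averages, measures both thicknesses and returns their
#' ratio. Only the click coordinates come from the ground truth; every
#' measured quantity goes through the full pipeline.
#'
#' @param spec a [membrane_phantom_spec()].
#' @param box_size extraction box side (voxels).
#' @param overlap_fraction box overlap (default 0.4).
#' @param classify_seed seed for the class-average initialization.
#' @return a `relative_thickness` record.
#' @export
phantom_relative_thickness <- function(spec, box_size = 32,
                                       overlap_fraction = 0.4,
                                       classify_seed = 1) {
  ph <- make_membrane_phantom(spec)
  cfg <- classify_config(n_classes = 1, n_iterations = 8,
                         angle_search_halfwidth = 4, angle_step = 2,
                         max_shift = 1, shift_step = 1, seed = classify_seed)
  measure_one <- function(at, role) {
    tr <- fit_trace(trace_from_truth(ph$truth, at = at))
    st <- extract_boxes(ph$tomogram, tr, box_size, overlap_fraction)
    cs <- collapse_to_2d(st, tomogram = ph$tomogram)
    average_and_measure(cs, role, config = cfg)
  }
  eiso <- measure_one("ridge", "eisosome")
  pm <- measure_one("flat", "pm_patch")
  relative_thickness(eiso, pm, spec$category)
}

#' Simulate and measure a cohort of shallow and curved eisosomes
#'
#' Builds `n_shallow` uncoated shallow-indentation phantoms and `n_curved`
#' coated furrow phantoms (geometry jittered per phantom, seeded), runs the
#' full pipeline on each, and reports per-category statistics with the
#' shallow-vs-curved Welch comparison.
#'
#' @param n_shallow,n_curved phantoms per category (>= 2 each for the
#'   comparison; default 3 + 3, the desk-scale analogue of the study's
#'   cohort).
#' @param seed integer seed controlling phantom noise and geometry jitter.
#' @param noise_sigma phantom noise level.
#' @param box_size extraction box side.
#' @return a [cohort_report()] with the individual records attached as
#'   attribute "records".
#' @export
run_phantom_cohort <- function(n_shallow = 3, n_curved = 3, seed = 1,
                               noise_sigma = 0.5, box_size = 32) {
  par <- with_seed(seed, list(
    d_sh = stats::runif(n_shallow, 4, 7),
    r_sh = stats::runif(n_shallow, 25, 32),
    d_cu = stats::runif(n_curved, 27, 33),
    r_cu = stats::runif(n_curved, 16, 20),
    seeds = sample.int(1e6, n_shallow + n_curved)
  ))
  records <- vector("list", n_shallow + n_curved)
  for (i in seq_len(n_shallow)) {
    spec <- membrane_phantom_spec(
      furrow_depth = par$d_sh[i], furrow_radius = par$r_sh[i],
      coat_enabled = FALSE, noise_sigma = noise_sigma,
      seed = par$seeds[i])
    records[[i]] <- phantom_relative_thickness(spec, box_size,
                                               classify_seed = par$seeds[i])
  }
  for (j in seq_len(n_curved)) {
    spec <- membrane_phantom_spec(
      furrow_depth = par$d_cu[j], furrow_radius = par$r_cu[j],
      coat_enabled = TRUE, noise_sigma = noise_sigma,
      seed = par$seeds[n_shallow + j])
    records[[n_shallow + j]] <-
      phantom_relative_thickness(spec, box_size,
                                 classify_seed = par$seeds[n_shallow + j])
  }
  rep <- cohort_report(records)
  attr(rep, "records") <- records
  rep
}
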