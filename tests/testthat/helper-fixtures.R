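# Shared fixtures, built in code at test time.

# Random well-conditioned affine ground truth.
random_affine_truth <- function(seed) {
  eisoclem:::with_seed(seed, {
    repeat {
      A <- matrix(stats::runif(4, -2, 2), 2, 2)
      if (abs(det(A)) > 0.3) break
    }
    ground_truth_transform(A, stats::runif(2, -30, 30))
  })
}

# Brute-force box placement: walk along the arc placing boxes until the next
# one would overhang the end.
brute_force_centers <- function(L, B, o) {
  if (L < B) return(L / 2)
  s <- (1 - o) * B
  centers <- B / 2
  repeat {
    nxt <- centers[length(centers)] + s
    if (nxt + B / 2 > L + 1e-9) break
    centers <- c(centers, nxt)
  }
  centers
}

# Cached 64-px cross-section templates (coated / uncoated ridge), built once
# per test run from noiseless wedge-filtered phantoms.
.template_cache <- new.env(parent = emptyenv())
ridge_template <- function(coated, box = 64) {
  key <- paste0(coated, "_", box)
  if (is.null(.template_cache[[key]])) {
    spec <- membrane_phantom_spec(noise_sigma = 0, coat_enabled = coated)
    .template_cache[[key]] <- phantom_cross_section(spec, box, "ridge")
  }
  .template_cache[[key]]
}

# Slope (degrees) of the membrane band in an aligned cross-section image,
# from a straight-line fit to the per-column density argmax.
membrane_slope_deg <- function(img, cols = NULL) {
  p <- ncol(img)
  cols <- cols %||% seq(round(p * 0.3), round(p * 0.7))
  am <- apply(img[, cols, drop = FALSE], 2, which.max)
  atan(unname(stats::coef(stats::lm(am ~ seq_along(am)))[2])) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
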