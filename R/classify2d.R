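# Regularized-likelihood (expectation-maximization) 2D classification of
# collapsed membrane cross-sections, with the in-plane rotation search
# restricted to a window around each image's spline-derived angle prior.
#
# Model: image_i = T_m(mu_k) + white Gaussian noise, where T_m runs over a
# discrete grid of in-plane rotations (prior_i + delta) and shifts. The
# E-step marginalizes responsibilities over classes and transforms; the
# M-step updates class averages as responsibility-weighted aligned means with
# a ridge penalty pulling them toward zero, then re-estimates the noise sigma
# and class fractions. Internally each total rotation is snapped to the
# angle-step grid so resampling maps can be shared across images; reported
# rotations keep the exact prior + delta values.

#' Classification configuration
#'
#' @param n_classes number of class averages K (>= 1).
#' @param n_iterations EM iterations.
#' @param angle_search_halfwidth rotation search half-width around the prior
#'   (degrees).
#' @param angle_step rotation grid step (degrees, > 0).
#' @param max_shift maximum |shift| searched (pixels).
#' @param shift_step shift grid step (pixels, > 0).
#' @param regularization_weight ridge weight pulling class averages toward
#'   zero (>= 0); acts like `regularization_weight` extra zero-images per
#'   class.
#' @param noise_sigma_init initial noise sigma (NULL = estimated from data).
#' @param seed integer seed for the class initialization.
#' @return object of class `classify_config`.
#' @export
classify_config <- function(n_classes = 4, n_iterations = 25,
                            angle_search_halfwidth = 15, angle_step = 2,
                            max_shift = 3, shift_step = 1,
                            regularization_weight = 1,
                            noise_sigma_init = NULL, seed = 1) {
  stopifnot(n_classes >= 1, n_iterations >= 1, angle_step > 0,
            shift_step > 0, angle_search_halfwidth >= 0, max_shift >= 0,
            regularization_weight >= 0)
  structure(as.list(environment()), class = "classify_config")
}

# Normalize input to a plain stack: list(images=list, angle_prior=numeric,
# pixel_size).
as_image_stack <- function(images) {
  if (inherits(images, "collapsed_2d_stack"))
    return(list(images = images$images, angle_prior = images$angle_prior,
                pixel_size = images$pixel_size))
  if (is.list(images) && !is.null(images$images))
    return(list(images = images$images,
                angle_prior = images$angle_prior %||%
                  rep(0, length(images$images)),
                pixel_size = images$pixel_size %||% 1))
  list(images = images, angle_prior = rep(0, length(images)), pixel_size = 1)
}

#' Classify collapsed 2D membrane images
#'
#' @param images a `collapsed_2d_stack`, or a list with elements `images`
#'   and optionally `angle_prior`, or a bare list of square matrices.
#' @param config a [classify_config()].
#' @return object of class `classification_result`: `class_averages` (list
#'   of matrices), `responsibilities` (N x K, rows sum to 1), `rotation`,
#'   `shift` (per-image maximum-responsibility transform), `objective_trace`
#'   (non-decreasing penalized log-likelihood), `class_quality`,
#'   `class_fractions`, `noise_sigma`, `config`.
#' @export
classify <- function(images, config = classify_config()) {
  stk <- as_image_stack(images)
  imgs <- stk$images
  N <- length(imgs)
  K <- config$n_classes
  if (K > N) stop("more classes than images")
  p <- nrow(imgs[[1]])
  npix <- p * p
  X <- vapply(imgs, as.vector, numeric(npix))
  if (all(abs(X) < 1e-300)) stop("degenerate input: all images are zero")

  # transform grid: rotations prior_i + delta, shifts on a square grid
  deltas <- if (config$angle_search_halfwidth > 0)
    seq(-config$angle_search_halfwidth, config$angle_search_halfwidth,
        by = config$angle_step) else 0
  sgrid <- if (config$max_shift > 0)
    seq(-config$max_shift, config$max_shift, by = config$shift_step) else 0
  shifts <- as.matrix(expand.grid(dx = sgrid, dy = sgrid))
  M <- length(deltas) * nrow(shifts)

  prior <- stk$angle_prior
  snap <- function(a) round(a / config$angle_step) * config$angle_step
  prior_snap <- snap(prior)
  groups <- split(seq_len(N), prior_snap)
  rot_cache <- new.env(parent = emptyenv())
  get_rot_map <- function(ang) {
    key <- sprintf("%.6f", ang)
    if (is.null(rot_cache[[key]]))
      rot_cache[[key]] <- image_mapping(p, ang)
    rot_cache[[key]]
  }
  shift_maps <- lapply(seq_len(nrow(shifts)), function(s)
    image_mapping(p, 0, shifts[s, 1], shifts[s, 2]))

  # init: seeded random partition means plus a small noise floor
  lambda <- config$regularization_weight
  Mu <- with_seed(config$seed, {
    perm <- sample.int(N)
    parts <- split(perm, rep(seq_len(K), length.out = N))
    mu <- vapply(parts, function(ii)
      rowMeans(X[, ii, drop = FALSE]), numeric(npix))
    sdx <- stats::sd(X)
    mu + matrix(stats::rnorm(npix * K, 0, 0.01 * max(sdx, 1e-12)),
                npix, K)
  })
  sigma <- config$noise_sigma_init %||% max(stats::sd(X), 1e-6)
  log_pi <- rep(log(1 / K), K)

  objective <- numeric(config$n_iterations)
  d2 <- array(NA_real_, c(N, K, M))
  for (iter in seq_len(config$n_iterations)) {
    ss_mu <- colSums(Mu^2)
    # E: squared distances for every (image, class, transform)
    for (g in seq_along(groups)) {
      ii <- groups[[g]]
      pa <- as.numeric(names(groups)[g])
      for (di in seq_along(deltas)) {
        R <- apply_mapping(X[, ii, drop = FALSE],
                           get_rot_map(pa + deltas[di]), p)
        for (si in seq_len(nrow(shifts))) {
          Tm <- if (nrow(shifts) == 1 && all(shifts[1, ] == 0)) R
            else apply_mapping(R, shift_maps[[si]], p)
          m <- (di - 1) * nrow(shifts) + si
          ssT <- colSums(Tm^2)
          cr <- crossprod(Tm, Mu)              # |ii| x K
          d2[ii, , m] <- pmax(ssT - 2 * cr +
                                rep(ss_mu, each = length(ii)), 0)
        }
      }
    }
    logw <- sweep(-d2 / (2 * sigma^2), 2, log_pi, "+") - log(M)
    lse <- apply(matrix(logw, N, K * M), 1, logsumexp)
    gamma <- exp(logw - array(lse, c(N, K, M)))
    pen <- lambda * sum(ss_mu) / (2 * sigma^2)
    objective[iter] <- sum(lse) - N * npix * log(sigma) -
      N * npix / 2 * log(2 * pi) - pen

    # M: sigma first (closed form at current Mu), then ridge means
    S <- max(sum(gamma * d2) + lambda * sum(ss_mu), 0)
    sigma <- max(sqrt(S / (N * npix)), 1e-8)
    gk <- apply(gamma, c(1, 2), sum)           # N x K
    Nk <- colSums(gk)
    log_pi <- log(pmax(Nk, 1e-12) / sum(pmax(Nk, 1e-12)))
    Anum <- matrix(0, npix, K)
    for (g in seq_along(groups)) {
      ii <- groups[[g]]
      pa <- as.numeric(names(groups)[g])
      for (di in seq_along(deltas)) {
        R <- apply_mapping(X[, ii, drop = FALSE],
                           get_rot_map(pa + deltas[di]), p)
        for (si in seq_len(nrow(shifts))) {
          Tm <- if (nrow(shifts) == 1 && all(shifts[1, ] == 0)) R
            else apply_mapping(R, shift_maps[[si]], p)
          m <- (di - 1) * nrow(shifts) + si
          Anum <- Anum + Tm %*% gamma[ii, , m, drop = FALSE][, , 1]
        }
      }
    }
    Mu <- sweep(Anum, 2, Nk + lambda, "/")
  }

  # hard assignments (ties toward the lower class index via which.max)
  best <- t(vapply(seq_len(N), function(i) {
    sl <- matrix(logw[i, , ], K, M)
    kk <- which(sl == max(sl), arr.ind = TRUE)[1, ]
    c(kk[1], kk[2])
  }, numeric(2)))
  si <- (best[, 2] - 1) %% nrow(shifts) + 1
  di <- (best[, 2] - si) / nrow(shifts) + 1
  rotation <- prior + deltas[di]
  shift <- shifts[si, , drop = FALSE]

  averages <- lapply(seq_len(K), function(k) matrix(Mu[, k], p, p))
  structure(list(
    class_averages = averages,
    responsibilities = gk,
    assignment = best[, 1],
    rotation = rotation, shift = shift,
    objective_trace = objective,
    class_quality = vapply(averages, class_quality_score, numeric(1)),
    class_fractions = exp(log_pi),
    noise_sigma = sigma,
    config = config
  ), class = "classification_result")
}

#' High-frequency-energy quality score of a class average
#'
#' High-frequency energy within a central horizontal band mask (where the
#' membrane lies after prior alignment): the energy of the image minus its
#' 5x5 box-smoothed version, normalized by the squared band peak and the
#' band area so the score is invariant to intensity scale and image size.
#' Sharp, well-aligned membrane/coat edges score high; blurred misaligned
#' averages score low, and an added coat layer raises the score. A
#' reproducible aid for class selection; never applied automatically.
#'
#' @param img square matrix.
#' @param band_fraction central rows included in the mask.
#' @return non-negative scalar.
#' @export
class_quality_score <- function(img, band_fraction = 0.5) {
  p <- nrow(img)
  k <- 5
  pad <- (k - 1) / 2
  padded <- matrix(0, p + 2 * pad, p + 2 * pad)
  padded[(pad + 1):(pad + p), (pad + 1):(pad + p)] <- img
  sm <- matrix(0, p, p)
  for (i in -pad:pad) for (j in -pad:pad)
    sm <- sm + padded[(pad + 1 + i):(pad + p + i),
                      (pad + 1 + j):(pad + p + j)]
  sm <- sm / k^2
  rows <- seq(floor(p / 2 - band_fraction * p / 2) + 1,
              ceiling(p / 2 + band_fraction * p / 2))
  hi <- sum((img - sm)[rows, ]^2)
  pk <- max(abs(img[rows, ]))
  if (pk <= 0) return(0)
  hi / (pk^2 * length(rows) * p)
}

#' Run several classifications with different configurations
#'
#' Mirrors the practice of classifying each membrane site several times with
#' different class counts to control for varying curvature, then comparing.
#'
#' @param images input stack (see [classify()]).
#' @param configs non-empty list of [classify_config()] objects.
#' @return object of class `multi_classification`: `results` (list of
#'   [classify()] outputs) and `summary` (data frame: run, n_classes,
#'   mean/max class quality, within-class variance).
#' @export
run_multi <- function(images, configs) {
  if (length(configs) == 0) stop("empty config list")
  results <- lapply(configs, function(cf) classify(images, cf))
  summary <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(run = i, n_classes = r$config$n_classes,
               mean_quality = mean(r$class_quality),
               max_quality = max(r$class_quality),
               within_class_variance = within_class_variance(r, images))
  }))
  structure(list(results = results, summary = summary),
            class = "multi_classification")
}

# Responsibility-weighted mean squared distance between each aligned image
# and its class average, per pixel.
within_class_variance <- function(result, images) {
  stk <- as_image_stack(images)
  p <- nrow(stk$images[[1]])
  tot <- 0
  for (i in seq_along(stk$images)) {
    Tm <- rotate_image(stk$images[[i]], result$rotation[i],
                       result$shift[i, 1], result$shift[i, 2])
    k <- result$assignment[i]
    tot <- tot + sum((as.vector(Tm) -
                      as.vector(result$class_averages[[k]]))^2)
  }
  tot / (length(stk$images) * p * p)
}

#' Select classes for downstream morphometry
#'
#' Selection is an explicit user decision recorded in provenance; the
#' quality scores are shown alongside to aid it but are never auto-applied.
#'
#' @param result a [classify()] output.
#' @param indices class indices to keep (>= 1 required).
#' @param images the stack that was classified (for membership filtering);
#'   optional.
#' @return list: `selected_classes`, `class_quality` (full table),
#'   `member_index` (images whose best class was selected), `images`
#'   (filtered, when `images` supplied), `provenance`.
#' @export
select_classes <- function(result, indices, images = NULL) {
  K <- length(result$class_averages)
  if (length(indices) == 0)
    stop("no classes selected; downstream morphometry needs at least one")
  if (any(indices < 1 | indices > K)) stop("class index out of range")
  members <- which(result$assignment %in% indices)
  out <- list(selected_classes = sort(unique(indices)),
              class_quality = data.frame(class = seq_len(K),
                                         quality = result$class_quality,
                                         selected = seq_len(K) %in% indices),
              member_index = members,
              provenance = sprintf(
                "classes %s of %d selected explicitly (%d of %d images)",
                paste(sort(unique(indices)), collapse = ","), K,
                length(members), length(result$assignment)))
  if (!is.null(images)) {
    stk <- as_image_stack(images)
    out$images <- stk$images[members]
  }
  out
}
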