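# Smaller stacks than the production-scale runs: 32-48 px templates and a
# handful of iterations keep each property check fast while exercising the
# same EM code path.

test_that("single-class averaging of identical aligned images is exact", {
  tmpl <- ridge_template(TRUE, 48)[9:40, 9:40]
  imgs <- replicate(8, tmpl, simplify = FALSE)
  cf <- classify_config(n_classes = 1, n_iterations = 5,
                        angle_search_halfwidth = 0, max_shift = 0,
                        regularization_weight = 0, seed = 3)
  res <- classify(imgs, cf)
  expect_equal(res$class_averages[[1]], tmpl, tolerance = 1e-9,
               ignore_attr = TRUE)
  # objective is non-decreasing and settles once the noise estimate floors
  ot <- res$objective_trace
  expect_true(all(diff(ot) >= -1e-6 * abs(ot[1])))
  expect_equal(ot[length(ot)], ot[length(ot) - 1],
               tolerance = 1e-9)
})

test_that("classification is deterministic and validates its inputs", {
  tmpl <- ridge_template(TRUE, 48)[9:40, 9:40]
  stk <- make_cross_section_stack(tmpl, 12, rot_range = 8, snr = 1, seed = 2)
  cf <- classify_config(n_classes = 2, n_iterations = 4,
                        angle_search_halfwidth = 8, max_shift = 0, seed = 9)
  r1 <- classify(stk, cf)
  r2 <- classify(stk, cf)
  expect_identical(r1$class_averages, r2$class_averages)
  expect_identical(r1$responsibilities, r2$responsibilities)

  expect_error(classify(stk$images[1:3],
                        classify_config(n_classes = 5, n_iterations = 2)),
               "more classes")
  zeros <- replicate(4, matrix(0, 16, 16), simplify = FALSE)
  expect_error(classify(zeros, classify_config(n_classes = 1,
                                               n_iterations = 2)),
               "degenerate")
  # responsibilities are row-normalized
  expect_equal(rowSums(r1$responsibilities), rep(1, 12), tolerance = 1e-9)
})

test_that("the EM objective is non-decreasing on noisy stacks", {
  tmpl <- ridge_template(TRUE, 48)[9:40, 9:40]
  for (seed in 1:3) {
    stk <- make_cross_section_stack(tmpl, 20, rot_range = 10, shift_max = 1,
                                    snr = 0.5, seed = seed)
    res <- classify(stk, classify_config(n_classes = 2, n_iterations = 8,
                                         angle_search_halfwidth = 10,
                                         max_shift = 1, seed = seed))
    ot <- res$objective_trace
    expect_true(all(diff(ot) >= -1e-6 * abs(ot[1])))
  }
})

test_that("classification is equivariant under a global rotation of inputs and priors", {
  tmpl <- ridge_template(TRUE, 48)
  stk <- make_cross_section_stack(tmpl, 16, rot_range = 0, snr = Inf,
                                  seed = 5)
  cf <- classify_config(n_classes = 1, n_iterations = 6,
                        angle_search_halfwidth = 6, angle_step = 2,
                        max_shift = 0, seed = 4)
  res0 <- classify(stk, cf)
  rot <- 10
  stk_r <- stk
  stk_r$images <- lapply(stk$images, rotate_image, deg = rot)
  stk_r$angle_prior <- stk$angle_prior - rot
  res_r <- classify(stk_r, cf)
  # averages live in the prior-aligned frame, whose absolute orientation is
  # a gauge freedom of the model; adjusting the priors by the same global
  # rotation must reproduce the original average up to that gauge and the
  # extra resampling passes the rotated route incurs
  a_ref <- rotate_image(rotate_image(res0$class_averages[[1]], rot), -rot)
  ar <- res_r$class_averages[[1]]
  ctr <- 13:36  # compare away from interpolation borders
  best <- max(vapply(seq(-6, 6, 2), function(g) {
    cor(as.vector(a_ref[ctr, ctr]),
        as.vector(rotate_image(ar, g)[ctr, ctr]))
  }, numeric(1)))
  expect_gt(best, 0.99)
})

test_that("a zero-width search honours the angle priors exactly", {
  tmpl <- ridge_template(TRUE, 48)[9:40, 9:40]
  stk <- make_cross_section_stack(tmpl, 6, rot_range = 0, snr = 5, seed = 6)
  stk$angle_prior <- c(-7.3, 0, 3.1, 12.2, -1.6, 5.5)
  res <- classify(stk, classify_config(n_classes = 1, n_iterations = 3,
                                       angle_search_halfwidth = 0,
                                       max_shift = 0, seed = 2))
  expect_identical(res$rotation, stk$angle_prior)
})

test_that("injected shifts are recovered within a pixel at moderate SNR", {
  tmpl <- ridge_template(TRUE, 48)
  stk <- make_cross_section_stack(tmpl, 24, rot_range = 0, shift_max = 2,
                                  snr = 0.5, seed = 8)
  res <- classify(stk, classify_config(n_classes = 1, n_iterations = 8,
                                       angle_search_halfwidth = 0,
                                       max_shift = 3, shift_step = 1,
                                       seed = 3))
  # the alignment shift undoes the injected one, up to the global
  # translation gauge of the class average (unobservable for K = 1)
  g <- res$shift + stk$true_shift
  g <- sweep(g, 2, round(colMeans(g)))
  expect_gte(mean(apply(abs(g), 1, max) <= 1), 0.9)
})

test_that("multi-run summaries rank a homogeneous stack correctly", {
  tmpl <- ridge_template(TRUE, 48)[9:40, 9:40]
  stk <- make_cross_section_stack(tmpl, 24, rot_range = 5, snr = 1, seed = 12)
  cfgs <- lapply(c(1, 2, 4), function(k)
    classify_config(n_classes = k, n_iterations = 6,
                    angle_search_halfwidth = 6, max_shift = 0, seed = 7))
  mr <- run_multi(stk, cfgs)
  expect_equal(nrow(mr$summary), 3)
  wv <- mr$summary$within_class_variance
  expect_lte(wv[1], min(wv) + 1e-9)  # K = 1 attains the lowest variance
  expect_error(run_multi(stk, list()), "empty")
  mr2 <- run_multi(stk, cfgs[1])
  expect_identical(mr$results[[1]]$class_averages,
                   mr2$results[[1]]$class_averages)
})

test_that("class selection is explicit and quality scores separate coat from no-coat", {
  # regime where the coat is a discernible second layer, as in the class
  # averages on which visual selection operates
  mk <- function(coat) membrane_phantom_spec(
    noise_sigma = 0, coat_enabled = coat, furrow_radius = 16,
    furrow_depth = 22.4, coat_offset = 6.5)
  t_coat <- phantom_cross_section(mk(TRUE), 48, "ridge")
  t_bare <- phantom_cross_section(mk(FALSE), 48, "ridge")
  s1 <- make_cross_section_stack(t_coat, 20, rot_range = 10, snr = 2,
                                 seed = 31)
  s2 <- make_cross_section_stack(t_bare, 20, rot_range = 10, snr = 2,
                                 seed = 32)
  mix <- list(images = c(s1$images, s2$images), angle_prior = rep(0, 40),
              pixel_size = 7)
  res <- classify(mix, classify_config(n_classes = 2, n_iterations = 8,
                                       angle_search_halfwidth = 10,
                                       max_shift = 0, seed = 5))
  lab <- rep(1:2, each = 20)
  tab <- table(lab, factor(res$assignment, levels = 1:2))
  coat_class <- which.max(tab[1, ])
  # the coated class average carries more band-limited high-frequency energy
  expect_gt(res$class_quality[coat_class],
            res$class_quality[setdiff(1:2, coat_class)])

  sel <- select_classes(res, 1:2, mix)
  expect_equal(sel$member_index, 1:40)
  expect_error(select_classes(res, integer(0)), "at least one")
  sel1 <- select_classes(res, coat_class, mix)
  expect_true(all(res$assignment[sel1$member_index] == coat_class))
})
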