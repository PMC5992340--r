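#!/usr/bin/env Rscript
# Multi-reference 2D averaging of the collapsed cross-sections. For each
# stack several class counts are run (the production practice for handling
# curvature heterogeneity) and the per-class quality scores reported; class
# selection stays an explicit choice, here: all classes of the K = 1 run.

suppressPackageStartupMessages(library(eisoclem))
dir.create("results/classes", recursive = TRUE, showWarnings = FALSE)

for (tag in c("curved", "shallow")) {
  for (at in c("ridge", "flat")) {
    mrc <- sprintf("results/stacks/%s_%s.mrcs", tag, at)
    star <- sprintf("results/stacks/%s_%s.star", tag, at)
    vols <- read_mrc(mrc)
    meta <- read_star(star)
    imgs <- lapply(seq_len(dim(vols$data)[3]), function(i)
      rotate_image(t(vols$data[, , i]), meta$rlnAnglePsiPrior[i]))
    stk <- list(images = imgs, angle_prior = rep(0, length(imgs)),
                pixel_size = vols$voxel_size)
    ks <- unique(pmin(c(1, 2), length(imgs)))
    cfgs <- lapply(ks, function(k)
      classify_config(n_classes = k, n_iterations = 10,
                      angle_search_halfwidth = 4, angle_step = 2,
                      max_shift = 1, shift_step = 1, seed = 7))
    mr <- run_multi(stk, cfgs)
    print(cbind(stack = paste(tag, at, sep = "/"), mr$summary))
    sel <- select_classes(mr$results[[1]], 1, stk)
    avg <- mr$results[[1]]$class_averages[[1]]
    write_mrc(tomogram(array(t(avg), c(dim(avg), 1)), vols$voxel_size),
              sprintf("results/classes/%s_%s_K1.mrc", tag, at))
    cat(sel$provenance, "\n")
  }
}
cat("class averages written to results/classes/\n")
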