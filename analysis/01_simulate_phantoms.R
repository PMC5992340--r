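#!/usr/bin/env Rscript
# Generate the synthetic inputs the rest of the workflow consumes: a paired
# FM/EM fiducial scene, a two-channel focal stack, and membrane tomogram
# phantoms (one coated curved furrow, one uncoated shallow indentation),
# all with recorded ground truth.

suppressPackageStartupMessages(library(eisoclem))
dir.create("results/phantoms", recursive = TRUE, showWarnings = FALSE)
seed <- 42

# fiducial scene under a mildly anisotropic affine truth
truth <- ground_truth_transform(matrix(c(1.9, 0.08, -0.12, 2.1), 2, 2),
                                c(25, -14))
scene <- make_fiducial_scene(8, truth, noise_sigma_fm = 0.5, seed = seed)
write.csv(data.frame(label = sprintf("bead_%02d", 1:8),
                     fm_x = scene$fm_points[, 1], fm_y = scene$fm_points[, 2],
                     em_x = scene$em_points[, 1], em_y = scene$em_points[, 2]),
          "results/phantoms/fiducials.csv", row.names = FALSE)

# focal stack: a well-attached and a detached signal, 0.3 um steps
emitters <- data.frame(x = c(16, 48, 32), y = c(16, 48, 32),
                       z_focus = c(2.4, 2.4, 6.0),
                       channel = c("red", "green", "green"),
                       brightness = c(2, 1, 1))
stack <- make_focal_stack(emitters, z_step = 0.3, planes = 30, seed = seed)
write.csv(emitters, "results/phantoms/emitters.csv", row.names = FALSE)

# membrane phantoms
for (cfg in list(list(tag = "curved", coat = TRUE),
                 list(tag = "shallow", coat = FALSE))) {
  spec <- membrane_phantom_spec(coat_enabled = cfg$coat,
                                furrow_depth = if (cfg$coat) 30 else 5,
                                furrow_radius = if (cfg$coat) 18 else 28,
                                seed = seed)
  ph <- make_membrane_phantom(spec)
  write_mrc(ph$tomogram,
            sprintf("results/phantoms/%s_synthetic.mrc", cfg$tag))
  mid <- as.data.frame(ph$truth$midline_points)
  write.csv(mid, sprintf("results/phantoms/%s_midline.csv", cfg$tag),
            row.names = FALSE)
  cat(sprintf("%s phantom: %d x %d x %d voxels, true thickness %.2f nm%s\n",
              cfg$tag, dim(ph$tomogram$data)[1], dim(ph$tomogram$data)[2],
              dim(ph$tomogram$data)[3], ph$truth$true_membrane_thickness,
              if (cfg$coat) sprintf(", coat diameter %.1f nm",
                                    ph$truth$true_coat_diameter) else ""))
}
cat("phantom inputs written to results/phantoms/\n")
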