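#!/usr/bin/env Rscript
# Trace the clicked membranes of both phantoms, extract 40%-overlapping
# sub-volumes along the splines and collapse them to 2D cross-sections with
# angle priors; write image stacks plus STAR metadata.

suppressPackageStartupMessages(library(eisoclem))
dir.create("results/stacks", recursive = TRUE, showWarnings = FALSE)
seed <- 42

for (tag in c("curved", "shallow")) {
  spec <- membrane_phantom_spec(
    coat_enabled = tag == "curved",
    furrow_depth = if (tag == "curved") 30 else 5,
    furrow_radius = if (tag == "curved") 18 else 28, seed = seed)
  ph <- make_membrane_phantom(spec)
  for (at in c("ridge", "flat")) {
    clicks <- trace_from_truth(ph$truth, at = at, spacing_nm = 15)
    write_clicks_csv(clicks, sprintf("results/stacks/%s_%s_clicks.csv",
                                     tag, at))
    trace <- resample_trace(fit_trace(clicks), 15)
    stack <- extract_boxes(ph$tomogram, trace, box_size = 32,
                           overlap_fraction = 0.4)
    cs <- collapse_to_2d(stack, tomogram = ph$tomogram)
    write_collapsed_stack(cs,
                          sprintf("results/stacks/%s_%s.mrcs", tag, at),
                          sprintf("results/stacks/%s_%s.star", tag, at))
    cat(sprintf("%s/%s: arc %.1f nm, %d boxes, priors %s deg\n",
                tag, at, trace$arc_length, length(stack$boxes),
                paste(round(stack$angle_prior), collapse = "/")))
  }
}
cat("collapsed stacks written to results/stacks/\n")
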