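#!/usr/bin/env Rscript
# Plan the grouped dose-symmetric acquisition: +/-60 degrees in 1 degree
# increments, groups of four per side, 110 e-/A^2 split uniformly.

suppressPackageStartupMessages(library(eisoclem))
dir.create("results", showWarnings = FALSE)

scheme <- allocate_dose(generate_scheme(60, 1, 4, "positive"), 110)
print(scheme)
stopifnot(length(validate_scheme(scheme)) == 0)
write_tilt_angles(scheme, "results/tilt_angles.tlt")
write_tilt_csv(scheme, "results/tilt_scheme.csv")
dt <- dose_table(scheme)
cat(sprintf("first 9 angles: %s\n",
            paste(scheme$ordered_angles[1:9], collapse = ", ")))
cat(sprintf("dose before acquiring 0 deg: %.2f; before +60 deg: %.2f e-/A^2\n",
            dt$cumulative_dose_before[dt$angle == 0],
            dt$cumulative_dose_before[dt$angle == 60]))
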