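#!/usr/bin/env Rscript
# Stage 1: simulate the study data.
#
# Generates the morphometrics sample (74 individuals spanning juveniles to
# adults) and one representative sidewinding trial for each of 26 kinematics
# individuals chosen across the size range, then writes the raw
# marker-coordinate CSVs, trial metadata, morphometrics table and the
# ground-truth sidecar under results/fixtures/.

suppressMessages(library(sidewindr))

seed <- 20160701L  # field season the sampling design emulates
out_dir <- "results/fixtures"

study <- simulate_study(n_individuals = 74, n_kinematics = 26, seed = seed)
manifest <- write_fixture_set(study$ground_truths,
                              morpho_gen_config(74, seed = seed), out_dir)
# the fixture metadata knows the coordinate files; add SVL for the ANCOVAs
meta <- read_trial_metadata(manifest$metadata)
meta$svl_cm <- study$trial_meta$svl_cm[match(meta$trial_id,
                                             study$trial_meta$trial_id)]
utils::write.csv(meta, manifest$metadata, row.names = FALSE)

message("individuals: ", nrow(study$morpho),
        " (", sum(study$morpho$age_class == "adult"), " adults, ",
        sum(study$morpho$sex == "F"), " females)")
message("SVL range: ", paste(round(range(study$morpho$svl_cm), 1), collapse = "-"),
        " cm")
message("kinematics trials written: ", length(manifest$trials))
f <- vapply(study$ground_truths, function(g) g$wave$frequency_hz, numeric(1))
message("cycle frequency range: ", paste(round(range(f), 2), collapse = "-"), " Hz")
message("fixtures under ", out_dir)
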