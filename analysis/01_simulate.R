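#!/usr/bin/env Rscript
# Stage 1: simulate a synthetic NPT study and check its interchange files.
#
# A reduced cohort (6 HC, 5 PDnP, 5 PDP; 40 images, 10 with faces) keeps
# the full workflow runnable in minutes; the generator's behavioural and
# EEG parameters are the package defaults. Intermediate objects go to
# scratch/ (not part of the deliverable); tables go to results/.

suppressPackageStartupMessages(library(nptfrp))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- sim_config(n_images = 40, n_face_images = 10,
                  subjects = c(HC = 6, PDnP = 5, PDP = 5),
                  seed = 20260920L)

message("simulating ", sum(cfg$subjects), " subjects x ", cfg$n_images,
        " images ...")
study <- simulate_study(cfg)
saveRDS(list(cfg = cfg, study = study), "scratch/study.rds")

# write one session in the interchange formats and validate it
dir <- file.path("results", "example_session")
write_session(study$sessions$PDP01, study$stimuli, dir)
report <- validate_inputs(dir)
write.csv(report, "results/validation_report.csv", row.names = FALSE)

message("sessions: ", length(study$sessions))
message("example session written to ", dir,
        "; validation ", if (all(report$ok)) "clean" else "FAILED")
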