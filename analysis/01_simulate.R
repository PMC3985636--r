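#!/usr/bin/env Rscript
# Stage 1: simulate the two study designs the downstream analyses use.
#
# (a) A kinetic toxicogenomics study: 7 timepoints (days 1..91) x
#     treated/control x 2 replicates, 500 promoters, 20 motifs whose
#     planted activities mix four characteristic temporal programs.
# (b) A two-group knockout study (WT/KO x treated/control, 3 replicates)
#     used to illustrate pathway-dependence calls.
#
# Everything is written as TSV under results/study_kinetic/ and
# results/study_ko/ together with the planted truth.

library(maraprog)

seed <- 20140101L

kinetic <- generate_study(generator_config(
  n_promoters = 500L, n_motifs = 20L,
  design_spec = list(type = "kinetic", timepoints = c(1, 3, 7, 14, 28, 57, 91),
                     conditions = c("treated", "control"), replicates = 2L,
                     dataset = "kinetic"),
  seed = seed))
paths <- write_study(kinetic, "results/study_kinetic")
cat(sprintf("kinetic study: %d promoters x %d samples, %d motifs, noise sd %.4f\n",
            nrow(kinetic$expr), ncol(kinetic$expr), nrow(kinetic$truth$A_true),
            kinetic$truth$noise_sd))
cat("  programs planted:", paste(rownames(kinetic$truth$B), collapse = ", "), "\n")
cat("  files:", paste(basename(paths), collapse = ", "), "\n\n")

# knockout study: motifs 1-6 respond to treatment in WT only (the "CAR
# downstream" pattern is planted by giving KO samples flat activities)
ko_design <- list(type = "two_group",
                  conditions = c("WT_control", "WT_treated", "KO_control", "KO_treated"),
                  replicates = 3L, dataset = "ko")
cfg_ko <- generator_config(
  n_promoters = 400L, n_motifs = 12L, design_spec = ko_design,
  n_programs = 1L,
  shapes = matrix(rep(c(-1, 1, 0, 0), each = 3L), nrow = 1,
                  dimnames = list("wt_treatment_response", NULL)),
  program_assignment = c(rep(1L, 6L), rep(0L, 6L)),
  signal_scale = 1.5, seed = seed + 1L)
ko <- generate_study(cfg_ko)
write_study(ko, "results/study_ko")
cat(sprintf("KO study: %d samples over %d condition cells; motifs 1-6 respond to treatment in WT only\n",
            nrow(ko$design), length(unique(ko$design$condition))))
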