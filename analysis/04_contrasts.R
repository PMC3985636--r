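#!/usr/bin/env Rscript
# Stage 4: differential motif activity. For the kinetic study, the
# per-timepoint treated-vs-control z matrix; for the KO study, the
# four-way contrast scheme that classifies motifs as downstream of, or
# independent of, the knocked-out pathway.

library(maraprog)

threshold <- 2.0

## kinetic study: per-timepoint z
dirk <- "results/study_kinetic"
tab <- read_activity_table(file.path(dirk, "activities"))
design <- read_sample_design(file.path(dirk, "design.tsv"))
tz <- timepoint_contrasts(tab, design, "kinetic")
maraprog:::write_tsv_matrix(tz, file.path(dirk, "timepoint_z.tsv"), "motif_id")
n_sig <- rowSums(abs(tz) >= threshold)
cat(sprintf("kinetic: %d of %d motifs pass |z| >= %.1f at >= 4 of 7 timepoints\n",
            sum(n_sig >= 4), nrow(tz), threshold))

## KO study: treatment response in WT vs in KO
dirko <- "results/study_ko"
tabko <- read_activity_table(file.path(dirko, "activities"))
dko <- read_sample_design(file.path(dirko, "design.tsv"))
zc <- function(c1, c2) differential_z(
  summarize_condition(tabko, dko, condition_key("ko", c1)),
  summarize_condition(tabko, dko, condition_key("ko", c2)))
call_wt <- classify_motifs(zc("WT_treated", "WT_control"), threshold)
call_ko <- classify_motifs(zc("KO_treated", "KO_control"), threshold)
dep <- dependency_call(call_wt, call_ko)
res <- data.frame(motif_id = names(dep), call_wt = call_wt, call_ko = call_ko,
                  dependence = dep, row.names = NULL)
utils::write.table(res, file.path(dirko, "dependence_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("KO study: %d motifs respond to treatment in WT; %d of those are silent in KO (downstream of the pathway)\n",
            sum(call_wt != "ns"), sum(dep == "downstream")))
print(table(dep))
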