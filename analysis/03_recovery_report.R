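#!/usr/bin/env Rscript
# Stage 3: score the assignments of stage 2 against the planted ground
# truth and write results/recovery.tsv.

suppressPackageStartupMessages(library(lncLandscape))

assignments <- read.delim("results/run/categories.tsv", stringsAsFactors = FALSE)
truth <- read.delim("results/sim/truth.tsv", stringsAsFactors = FALSE)
rec <- score_recovery(assignments, truth)
write_table(rec, "results/recovery.tsv")

message("Recovery of planted categories:")
for (i in seq_len(nrow(rec))) {
  message(sprintf("  %-16s planted=%2d predicted=%2d sensitivity=%.2f precision=%s",
                  rec$category[i], rec$n_planted[i], rec$n_predicted[i],
                  rec$sensitivity[i],
                  ifelse(is.na(rec$precision[i]), "NA",
                         sprintf("%.2f", rec$precision[i]))))
}
message(sprintf("Mean sensitivity %.3f, mean precision %.3f",
                mean(rec$sensitivity),
                mean(rec$precision, na.rm = TRUE)))
message("Written to results/recovery.tsv")
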