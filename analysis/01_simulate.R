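#!/usr/bin/env Rscript
# Stage 1: simulate the three-dataset study and write its plain-text
# fixtures (expression matrices, sample metadata, probe map, annotation,
# gene sets, ground truth) under results/sim/.

suppressPackageStartupMessages(library(lncLandscape))

SEED <- 2026
cfg <- sim_config(seed = SEED)
study <- simulate_study(cfg)
write_study(study, "results/sim")
saveRDS(cfg, "results/sim_config.rds")

message("Simulated study (seed ", SEED, "):")
for (id in names(study$rnaseq)) {
  ds <- study$rnaseq[[id]]
  message("  ", id, " [RNA-seq]: ", nrow(ds$values), " genes x ",
          ncol(ds$values), " samples (",
          paste(names(table(ds$samples$group)), table(ds$samples$group),
                sep = "=", collapse = ", "), ")")
}
for (id in names(study$arrays)) {
  a <- study$arrays[[id]]
  message("  ", id, " [microarray]: ", nrow(a$probes), " probes / ",
          length(unique(a$probe_map$gene_id)), " genes x ",
          nrow(a$samples), " samples (",
          paste(names(table(a$samples$group)), table(a$samples$group),
                sep = "=", collapse = ", "), ")")
}
tab <- table(study$truth$true_category)
message("  planted lncRNAs per category: ",
        paste(names(tab[names(tab) != "none"]),
              tab[names(tab) != "none"], sep = "=", collapse = ", "))
message("  genes without array probes: ",
        sum(!study$truth$measured_on_array))
message("Fixtures written to results/sim/")
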