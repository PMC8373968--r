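#!/usr/bin/env Rscript
# Stage 4: summarise the guilt-by-association results of stage 2 —
# coexpressed partners per top lncRNA and significantly enriched terms
# per category. Writes results/function_summary.tsv.

suppressPackageStartupMessages(library(lncLandscape))

cx <- read.delim("results/run/coexpression.tsv", stringsAsFactors = FALSE)
en <- read.delim("results/run/enrichment.tsv", stringsAsFactors = FALSE)

partners <- aggregate(gene_id ~ lncrna_id + category, cx, length)
names(partners)[3] <- "n_partners"
message("Coexpressed coding partners per queried lncRNA: median ",
        median(partners$n_partners), " (range ",
        paste(range(partners$n_partners), collapse = "-"), ")")

sig <- en[en$significant, ]
summary <- aggregate(term_id ~ category, sig, function(x) length(unique(x)))
names(summary)[2] <- "n_significant_terms"
write_table(merge(partners, summary, all.x = TRUE), "results/function_summary.tsv")

message("Significantly enriched terms per category:")
for (cc in unique(en$category)) {
  s <- sig[sig$category == cc, ]
  top <- s[order(s$p_adj), ]
  top <- top[!duplicated(top$term_id), ][1, ]
  message("  ", cc, ": ", length(unique(s$term_id)), " term(s)",
          if (nrow(s)) paste0("; strongest: ", top$term_id, " (",
                              top$term_name, ", p_adj=",
                              signif(top$p_adj, 3), ")") else "")
}
message("Written to results/function_summary.tsv")
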