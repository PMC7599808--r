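#!/usr/bin/env Rscript
# D7 vs D0 differential expression per (cell type, compartment) stratum,
# at both feature levels: miRNA (|log2FC| >= 1 and p < 0.05) and tsRNA
# isoacceptor (BH-adjusted p < 0.05 and |log2FC| >= 1), after removing
# features below 50 raw reads in every sample.

library(evsmallrna)

des <- read.delim("results/sim/samples.tsv")
out <- "results/de"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ann <- lapply(setNames(des$sample_id, des$sample_id), function(sid)
  read.delim(file.path("results/annotation", paste0(sid, ".ann.tsv"))))

for (level in c("miRNA", "tsRNA")) {
  cm <- filter_low_expression(build_count_matrix(ann, des, level), 50)
  rule <- if (level == "miRNA") "mirna" else "tsrna"
  for (ct in unique(des$cell_type)) for (cp in unique(des$compartment)) {
    de <- call_significant(nb_wald_test(cm, ct, cp), rule)
    f <- file.path(out, sprintf("%s_%s_%s.tsv", tolower(level), ct, cp))
    write.table(de, f, sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%-6s %-4s %-4s: %d/%d features significant\n",
                level, ct, cp, sum(de$significant),
                sum(!is.na(de$wald_p))))
  }
}
cat("\nSignificance rules: miRNA |log2FC|>=1 & p<0.05; tsRNA padj<0.05 & |log2FC|>=1\n")
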