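#!/usr/bin/env Rscript
# tsRNA typing of tRNA-mapped reads: 5'/3' halves vs fragments,
# isoacceptor abundance tables per sample group, coverage meta-profiles
# and length distributions.

library(evsmallrna)

seed <- 20260926L %% 100000L
refs <- generate_references(20, 12, 8, seed = seed)
des <- read.delim("results/sim/samples.tsv")
out <- "results/tsrna"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

groups <- split(des$sample_id,
                paste(des$cell_type, des$compartment, sep = "_"))
tabs <- NULL
for (g in names(groups)) {
  recs <- do.call(rbind, lapply(groups[[g]], function(sid) {
    ann <- read.delim(file.path("results/annotation",
                                paste0(sid, ".ann.tsv")))
    tsrna_records(ann, refs)
  }))
  tab <- isoacceptor_abundance(recs)
  tabs <- rbind(tabs, cbind(group = g, tab))
  hist <- tsrna_length_histogram(recs)
  write.table(hist, file.path(out, paste0(g, ".lengths.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cov <- coverage_profiles(recs, refs)
  write.table(cov$meta, file.path(out, paste0(g, ".meta_coverage.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(tabs, file.path(out, "isoacceptor_abundance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

top <- do.call(rbind, lapply(split(tabs, tabs$group), head, 3))
cat("Top-3 isoacceptors per group (percent of tRNA-mapped reads):\n")
print(top[, c("group", "trna_name", "percentage", "dominant_type")],
      row.names = FALSE)
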