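#!/usr/bin/env Rscript
# Adapter trimming and quality filtering of the simulated libraries:
# FASTQ in, clean FASTQ + per-sample trim statistics out.

library(evsmallrna)

sim_dir <- "results/sim"
out <- "results/clean"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

des <- read.delim(file.path(sim_dir, "samples.tsv"))
stats <- NULL
for (sid in des$sample_id) {
  pp <- preprocess_fastq(file.path(sim_dir, paste0(sid, ".fastq")))
  write_fastq(pp$reads, file.path(out, paste0(sid, ".clean.fastq")))
  stats <- rbind(stats, cbind(sample_id = sid, pp$stats))
}
write.table(stats, file.path(out, "trim_stats.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Cleaned %d libraries: %.1f%% of reads survive on average\n",
            nrow(stats), 100 * mean(stats$n_clean / stats$n_input)))
cat(sprintf("Adapter found in %.1f%% of reads\n",
            100 * mean(stats$n_adapter_found / stats$n_input)))
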