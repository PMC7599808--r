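#!/usr/bin/env Rscript
# Cross-contrast overlap reporting on the published tables (the desk-scale
# ground truth) and on the simulated experiment: shared significant
# features, direction concordance, abundance slices and fragment/half
# tallies, plus PCA / clustering of the simulated samples.

library(evsmallrna)

out <- "results/report"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## published tables
t1 <- load_table_fixture("table1")
t2 <- load_table_fixture("table2")
t5 <- load_table_fixture("table5")

ov_cells <- overlap(de_set(t1, "ASC_cells"), de_set(t1, "BMSC_cells"),
                    "ASC cells", "BMSC cells")
print(ov_cells)
ov_bmsc <- overlap(de_set(t1, c("BMSC_cells", "BMSC_cells_vs_EV")),
                   de_set(t1, "BMSC_EVs"), "BMSC cells", "BMSC EVs")
print(ov_bmsc)
cat(sprintf("EV-only changed miRNAs: %d, of which %d with baseMean > 20000\n",
            length(setdiff(t2$feature, ov_bmsc$shared)),
            nrow(abundance_slice(t2, 20000))))
for (blk in unique(t5$block)) {
  tl <- type_tally(t5[t5$block == blk, ])
  cat(sprintf("%s tsRNAs: %s\n", blk,
              paste(names(tl), tl, sep = "=", collapse = ", ")))
}

## simulated experiment: sample structure
des <- read.delim("results/sim/samples.tsv")
ann <- lapply(setNames(des$sample_id, des$sample_id), function(sid)
  read.delim(file.path("results/annotation", paste0(sid, ".ann.tsv"))))
cm <- filter_low_expression(build_count_matrix(ann, des, "tsRNA"), 10)

p <- pca_samples(cm)
coords <- data.frame(sample_id = rownames(p$coords), p$coords)
write.table(coords, file.path(out, "pca_tsrna.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nPCA on tsRNA profiles: PC1 %.0f%%, PC2 %.0f%% of variance\n",
            100 * p$var_explained[1], 100 * p$var_explained[2]))

hc <- hclust_samples(cm)
split2 <- stats::cutree(hc, 2)
cat("Top-level split of the tsRNA dendrogram vs compartment:\n")
print(table(cluster = split2, compartment = des$compartment))
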