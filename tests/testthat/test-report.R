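test_that("table fixtures round-trip through the TSV reader/writer", {
  for (nm in paste0("table", 1:5)) {
    df <- load_table_fixture(nm)
    expect_gt(nrow(df), 0)
    tmp <- tempfile(fileext = ".tsv")
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_equal(read.delim(tmp, stringsAsFactors = FALSE), df)
  }
  t5 <- load_table_fixture("table5")
  expect_true(all(t5$note %in% c("fragment", "halve")))
})

test_that("overlap decomposes shared features into concordance classes", {
  a <- data.frame(feature = c("x", "y", "z", "w"), log2fc = c(2, -1, 1, 0.5))
  b <- data.frame(feature = c("x", "y", "z", "v"), log2fc = c(1, -2, -3, 2))
  ov <- overlap(a, b)
  expect_equal(ov$n_shared, 3)
  expect_equal(ov$n_up_up, 1)
  expect_equal(ov$n_down_down, 1)
  expect_equal(ov$n_opposite, 1)
  expect_equal(ov$n_shared, ov$n_up_up + ov$n_down_down + ov$n_opposite +
                 ov$n_neutral)
  expect_equal(ov$a_only, "w")
  expect_equal(ov$b_only, "v")

  same <- overlap(a, a)
  expect_equal(same$n_shared, 4)
  expect_equal(same$n_opposite, 0)
  disjoint <- overlap(a, data.frame(feature = "q", log2fc = 1))
  expect_equal(disjoint$n_shared, 0)

  # zero fold change is neutral, not a direction
  z <- overlap(data.frame(feature = "x", log2fc = 0),
               data.frame(feature = "x", log2fc = 2))
  expect_equal(z$n_neutral, 1)
  expect_equal(z$n_up_up + z$n_down_down + z$n_opposite, 0)
  expect_error(overlap(rbind(a, a), b), "duplicate")
})

test_that("abundance slices use a strict threshold and preserve order", {
  t2 <- load_table_fixture("table2")
  expect_equal(nrow(abundance_slice(t2, 0)), nrow(t2))
  expect_equal(nrow(abundance_slice(t2, max(t2$baseMean))), 0)
  sl <- abundance_slice(t2, 20000)
  expect_equal(sl$feature, head(t2$feature, nrow(sl)))  # ordered by abundance
})

test_that("type tallies validate their notes", {
  expect_equal(type_tally(data.frame(note = character(0))), integer(0))
  expect_error(type_tally(data.frame(note = "chimera")), "unknown note")
})

test_that("PCA separates planted groups deterministically", {
  set.seed(61)
  # two groups expressing disjoint high-abundance feature sets
  gA <- t(vapply(1:30, function(i) rnbinom(3, mu = 2000, size = 10),
                 numeric(3)))
  gB <- t(vapply(1:30, function(i) rnbinom(3, mu = 2000, size = 10),
                 numeric(3)))
  base <- matrix(rnbinom(40 * 6, mu = 100, size = 10), nrow = 40)
  counts <- rbind(cbind(gA, matrix(1L, 30, 3)),
                  cbind(matrix(1L, 30, 3), gB),
                  base)
  rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", 1:6)
  cm <- make_cm(counts)
  p <- pca_samples(cm)
  expect_false(any(is.na(p$coords)))
  r1 <- range(p$coords[1:3, 1]); r2 <- range(p$coords[4:6, 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])  # no overlap on PC1
  # variance explained is non-increasing and bounded
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1)
  # duplicated sample lands on identical coordinates; runs are identical
  counts2 <- counts
  counts2[, 2] <- counts2[, 1]
  p2 <- pca_samples(make_cm(counts2))
  expect_equal(p2$coords[1, ], p2$coords[2, ])
  expect_identical(p, pca_samples(cm))
  expect_error(pca_samples(make_cm(counts[, 1:2])), ">= 3 samples")
})

test_that("clustering groups compartments by their tsRNA profiles", {
  counts <- matrix(c(100L, 100L), 1, 2,
                   dimnames = list("f1", c("s1", "s2")))
  hc <- hclust_samples(make_cm(counts, day = c("D0", "D0")))
  expect_equal(hc$height[1], 0)

  refs <- generate_references(10, 10, 6, seed = 62)
  des <- design_table(cell_types = "BMSC")
  exp <- simulate_experiment(refs, des, n_reads = 3000, error_rate = 0,
                             seed = 63)
  ann <- lapply(exp$samples, function(s)
    cascade_annotate(preprocess_fastq(s$reads)$reads, refs))
  cm <- build_count_matrix(ann, des, level = "tsRNA")
  hc <- hclust_samples(cm)
  split2 <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(split2[des$compartment == "EV"])), 1)
  expect_equal(length(unique(split2[des$compartment == "cell"])), 1)
  expect_false(split2[des$compartment == "EV"][1] ==
                 split2[des$compartment == "cell"][1])
})

test_that("the pipeline is reproducible and validates its configuration", {
  refs <- generate_references(8, 6, 4, seed = 64)
  cfg <- list(refs = refs, design = design_table(cell_types = "BMSC"),
              n_reads = 600, error_rate = 0, seed = 65,
              count_threshold = 5)
  out1 <- run_pipeline(cfg)
  out2 <- run_pipeline(cfg)
  expect_identical(out1$summary, out2$summary)
  expect_true(all(c("composition", "de_counts", "overlaps") %in%
                    names(out1$summary)))
  expect_error(run_pipeline(list(seed = 1)), "ref_params")

  d <- tempfile()
  run_pipeline(cfg, out_dir = d)
  expect_true(file.exists(file.path(d, "summary.json")))
  expect_true(file.exists(file.path(d, "composition.tsv")))
})

test_that("a null simulation yields near-nominal false-positive calls", {
  refs <- generate_references(15, 8, 4, seed = 66)
  des <- design_table(cell_types = "BMSC")
  cfg <- list(refs = refs, design = des, n_reads = 4000, error_rate = 0,
              seed = 67, count_threshold = 50,
              composition_override = c(miRNA = 0.4, tRNA = 0.3, rRNA = 0.2,
                                       mRNA = 0.1))
  # no day effect anywhere: composition identical across D0/D7
  sim <- simulate_experiment(refs, des, n_reads = 4000, error_rate = 0,
                             composition_override = cfg$composition_override,
                             seed = 67)
  ann <- lapply(sim$samples, function(s)
    cascade_annotate(preprocess_fastq(s$reads)$reads, refs))
  cm <- filter_low_expression(build_count_matrix(ann, des, "miRNA"), 50)
  n_sig <- 0; n_tested <- 0
  for (comp in c("cell", "EV")) {
    de <- call_significant(nb_wald_test(cm, "BMSC", comp), "mirna")
    n_sig <- n_sig + sum(de$significant)
    n_tested <- n_tested + sum(!is.na(de$wald_p))
  }
  # the |log2fc| >= 1 condition makes calls rarer than the p < 0.05 rate
  expect_lte(n_sig, 0.05 * n_tested + 3 * sqrt(0.05 * 0.95 * n_tested))
})
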