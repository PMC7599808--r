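test_that("tsRNA typing follows the length and anchor rules", {
  # 33 nt from the 5' end of a 76-nt tRNA: 5' half
  expect_equal(classify_tsrna(0, 33, 76)$tsrna_type, "half_5p")
  # ragged 5' end within the 1-nt anchor tolerance
  expect_equal(classify_tsrna(1, 34, 76)$tsrna_type, "half_5p")
  # 31 nt ending at the CCA end: 3' half
  expect_equal(classify_tsrna(45, 76, 76)$tsrna_type, "half_3p")
  # 18 nt internal read: fragment
  expect_equal(classify_tsrna(5, 23, 76)$tsrna_type, "fragment")
  # 27-29 nt falls between the published ranges: fragment, not flagged
  cl29 <- classify_tsrna(10, 39, 76)
  expect_equal(cl29$tsrna_type, "fragment")
  expect_false(cl29$nonstandard)
  # >= 30 nt anchored at neither end: nonstandard fragment
  odd <- classify_tsrna(10, 42, 76)
  expect_equal(odd$tsrna_type, "fragment")
  expect_true(odd$nonstandard)
})

test_that("typed records reproduce the simulator's ground truth", {
  refs <- generate_references(6, 10, 4, seed = 41)
  cfg <- simulation_config(n_reads = 2000, composition = c(tRNA = 1),
                           error_rate = 0, seed = 42)
  sim <- simulate_sample(refs, cfg)
  pp <- preprocess_fastq(sim$reads)
  ann <- cascade_annotate(pp$reads, refs)
  rec <- tsrna_records(ann, refs)
  m <- merge(rec, sim$truth, by = "read_id")
  expect_equal(nrow(m), 2000)
  expect_gte(mean(m$tsrna_type.x == m$tsrna_type.y), 0.99)
  expect_error(
    tsrna_records(transform(ann, ref_name = "nope"), refs), "not in")
})

test_that("isoacceptor table recovers planted abundances and handles ties", {
  rec1 <- data.frame(read_id = paste0("r", 1:10), trna_name = "Gly-GCC",
                     ref_start = 0, ref_end = 33, length = 33,
                     tsrna_type = "half_5p", nonstandard = FALSE)
  tab1 <- isoacceptor_abundance(rec1)
  expect_equal(tab1$percentage, 100)
  expect_equal(tab1$dominant_type, "half_5p")
  expect_error(isoacceptor_abundance(rec1[0, ]), "empty")

  # planted Table-4-style composition, n = 10,000
  set.seed(43)
  names4 <- c("Gly-GCC", "Glu-CTC", "Gly-CCC", "Val-AAC")
  draw <- sample(names4, 10000, replace = TRUE,
                 prob = c(0.55, 0.16, 0.16, 0.13))
  rec <- data.frame(read_id = paste0("r", seq_along(draw)), trna_name = draw,
                    ref_start = 0, ref_end = 32, length = 32,
                    tsrna_type = "half_5p", nonstandard = FALSE)
  tab <- isoacceptor_abundance(rec)
  expect_equal(tab$trna_name[1], "Gly-GCC")
  got <- setNames(tab$percentage, tab$trna_name)[names4]
  expect_true(all(abs(got - c(55, 16, 16, 13)) < 2))
  expect_equal(sum(tab$percentage), 100)

  # equal counts: both listed, ordered by name; type tie prefers halves
  rec_tie <- data.frame(read_id = paste0("r", 1:4),
                        trna_name = rep(c("Val-CAC", "Ala-TGC"), each = 2),
                        ref_start = 0, ref_end = c(33, 20, 33, 20),
                        length = c(33, 20, 33, 20),
                        tsrna_type = rep(c("half_5p", "fragment"), 2),
                        nonstandard = FALSE)
  tab_tie <- isoacceptor_abundance(rec_tie)
  expect_equal(tab_tie$trna_name, c("Ala-TGC", "Val-CAC"))
  expect_equal(tab_tie$dominant_type, c("half_5p", "half_5p"))
})

test_that("coverage profiles obey interval arithmetic and conservation", {
  refs <- generate_references(2, 3, 0, seed = 44)
  nm <- refs$trnas$name[1]
  len1 <- nchar(refs$trnas$sequence[1])
  rec <- data.frame(read_id = c("a", "b"), trna_name = nm,
                    ref_start = c(0, 10), ref_end = c(30, 40),
                    length = c(30, 30), tsrna_type = "half_5p",
                    nonstandard = FALSE)
  cov <- coverage_profiles(rec, refs)
  depth <- cov$per_trna[[nm]]
  expect_equal(depth[1:10], rep(1, 10))
  expect_equal(depth[11:30], rep(2, 20))
  expect_equal(depth[31:40], rep(1, 10))
  expect_true(all(depth[41:len1] == 0))
  expect_equal(sum(depth), sum(rec$length))
  expect_error(coverage_profiles(transform(rec, ref_end = 1000), refs),
               "outside")

  # 5'-half-only sample: meta-profile mass sits in the 5' bins
  refs2 <- generate_references(2, 6, 0, seed = 45)
  cfg <- simulation_config(n_reads = 1000, composition = c(tRNA = 1),
                           half_fraction = 1, error_rate = 0, seed = 46)
  sim <- simulate_sample(refs2, cfg)
  ann <- cascade_annotate(preprocess_fastq(sim$reads)$reads, refs2)
  rec5 <- tsrna_records(ann, refs2)
  rec5 <- rec5[rec5$tsrna_type == "half_5p", ]
  cov5 <- coverage_profiles(rec5, refs2)
  lo <- sum(cov5$meta$depth[cov5$meta$bin < 45])
  hi <- sum(cov5$meta$depth[cov5$meta$bin >= 55])
  expect_gt(lo, 0)
  expect_lt(hi, 0.02 * sum(cov5$meta$depth))
})

test_that("tsRNA length histograms are bimodal for half/fragment mixtures", {
  refs <- generate_references(2, 5, 0, seed = 47)
  mk <- function(half_fraction, seed) {
    cfg <- simulation_config(n_reads = 800, composition = c(tRNA = 1),
                             half_fraction = half_fraction, error_rate = 0,
                             seed = seed)
    sim <- simulate_sample(refs, cfg)
    ann <- cascade_annotate(preprocess_fastq(sim$reads)$reads, refs)
    tsrna_length_histogram(tsrna_records(ann, refs))
  }
  halves <- mk(1, 48)
  expect_equal(sum(halves$count[halves$length >= 30 & halves$length <= 40]),
               sum(halves$count))
  frags <- mk(0, 49)
  expect_equal(sum(frags$count[frags$length >= 17 & frags$length <= 26]),
               sum(frags$count))
  mix <- mk(0.5, 50)
  expect_gt(sum(mix$count[mix$length >= 30 & mix$length <= 40]), 0)
  expect_gt(sum(mix$count[mix$length >= 17 & mix$length <= 26]), 0)
})
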