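test_that("count matrices reproduce planted counts and conserve totals", {
  ann <- list(
    s1 = data.frame(read_id = paste0("r", 1:6),
                    category = c("miRNA", "miRNA", "miRNA", "tRNA", "tRNA",
                                 "rRNA"),
                    ref_name = c("mir-a", "mir-a", "mir-b", "Gly-GCC",
                                 "Gly-GCC", "rRNA-1"),
                    stringsAsFactors = FALSE),
    s2 = data.frame(read_id = paste0("r", 1:2),
                    category = c("miRNA", "tRNA"),
                    ref_name = c("mir-a", "Val-AAC"),
                    stringsAsFactors = FALSE))
  md <- data.frame(sample_id = c("s1", "s2"), cell_type = "ASC",
                   compartment = "cell", day = c("D0", "D7"), donor = 1:2)
  cm <- build_count_matrix(ann, md, "miRNA")
  expect_equal(cm$counts["mir-a", ], c(s1 = 2L, s2 = 1L))
  expect_equal(cm$counts["mir-b", ], c(s1 = 1L, s2 = 0L))  # absent -> 0
  cmt <- build_count_matrix(ann, md, "tsRNA")
  expect_equal(unname(colSums(cmt$counts)),
               c(2L, 1L))  # per-sample tRNA-annotated read totals
  expect_equal(cmt$counts["Val-AAC", "s1"], 0L)
  expect_error(build_count_matrix(ann, transform(md, sample_id = "s1")),
               "duplicate")
  expect_error(build_count_matrix(ann, transform(md, day = "D9")), "unknown")
})

test_that("low-expression filter keeps exactly features reaching 50 anywhere", {
  counts <- rbind(all49 = rep(49L, 4), one50 = c(50L, 0L, 0L, 0L),
                  zero = rep(0L, 4), big = rep(500L, 4))
  colnames(counts) <- paste0("s", 1:4)
  cm <- make_cm(counts)
  kept <- rownames(filter_low_expression(cm)$counts)
  expect_equal(kept, c("one50", "big"))
  # one-line oracle on random matrices
  set.seed(51)
  for (i in 1:10) {
    m <- matrix(rnbinom(60, mu = 40, size = 2), nrow = 10,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
    got <- rownames(filter_low_expression(make_cm(m), 50)$counts)
    want <- rownames(m)[apply(m, 1, function(x) any(x >= 50))]
    expect_equal(got, want)
  }
})

test_that("size factors are symmetric, equivariant and match DESeq2", {
  same <- matrix(rep(c(10L, 20L, 400L), 4), ncol = 4,
                 dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  expect_equal(unname(estimate_size_factors(same)), rep(1, 4))

  set.seed(52)
  m <- matrix(rnbinom(120, mu = 200, size = 5) + 1L, nrow = 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:6)))
  sf <- estimate_size_factors(m)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  m2 <- m
  m2[, 3] <- m2[, 3] * 2L
  sf2 <- estimate_size_factors(m2)
  expect_equal(sf2[3] / sf2[1], 2 * sf[3] / sf[1], tolerance = 1e-12)

  skip_if_not_installed("DESeq2")
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rnbinom(120, mu = 150, size = 3) + 1L, nrow = 20,
                dimnames = list(paste0("f", 1:20), paste0("s", 1:6)))
    # one zeroed cell: that feature drops out of the median-of-ratios set
    # in both implementations, leaving an odd count where the ratio-scale
    # and log-scale medians coincide exactly
    m[1, 1] <- 0L
    ours <- estimate_size_factors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    ref <- ref / exp(mean(log(ref)))
    expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
  }
})

test_that("the Wald test is exact on constants and sane on degenerate input", {
  # balanced design: up and down mirror each other so size factors are 1
  counts <- rbind(flat = rep(100L, 6),
                  up = c(10L, 10L, 10L, 80L, 80L, 80L),
                  down = c(80L, 80L, 80L, 10L, 10L, 10L),
                  zero = rep(0L, 6))
  colnames(counts) <- paste0("s", 1:6)
  cm <- make_cm(counts, day = rep(c("D0", "D7"), each = 3))
  expect_equal(unname(estimate_size_factors(cm)), rep(1, 6))
  res <- nb_wald_test(cm)
  expect_equal(res$log2fc[res$feature == "flat"], 0)
  expect_true(is.na(res$wald_p[res$feature == "zero"]))
  expect_false(anyNA(res$padj[res$feature != "zero"]))
  # positive log2fc means higher at D7
  expect_gt(res$log2fc[res$feature == "up"], 0)
  expect_lt(res$log2fc[res$feature == "down"], 0)
  expect_error(nb_wald_test(make_cm(counts, day = rep("D0", 6))),
               ">= 2 samples")
})

test_that("null simulation p-values are approximately uniform", {
  set.seed(1)
  mu <- exp(rnorm(500, log(500), 1))
  counts <- t(vapply(mu, function(m) rnbinom(6, mu = m, size = 20),
                     numeric(6)))
  colnames(counts) <- paste0("s", 1:6)
  rownames(counts) <- paste0("f", 1:500)
  res <- nb_wald_test(make_cm(counts))
  ks <- suppressWarnings(stats::ks.test(res$wald_p, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("BH adjustment agrees exactly with the step-up definition", {
  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p))
  }
  counts <- matrix(rnbinom(600, mu = 300, size = 5), nrow = 100,
                   dimnames = list(paste0("f", 1:100), paste0("s", 1:6)))
  res <- nb_wald_test(make_cm(counts))
  expect_equal(res$padj, oracle_bh(res$wald_p))
})

test_that("significance rules apply the published thresholds at the boundary", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    log2fc = c(1.0, 0.9, 2.0, -1.2),
                    wald_p = c(0.049, 0.001, 0.02, 0.06),
                    padj = c(0.2, 0.01, 0.051, 0.03))
  mir <- call_significant(res, "mirna")
  expect_equal(mir$significant, c(TRUE, FALSE, TRUE, FALSE))
  tsr <- call_significant(res, "tsrna")
  expect_equal(tsr$significant, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(call_significant(res, "bogus"))
})
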