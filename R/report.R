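# Cross-contrast reporting: overlap and direction concordance between
# differential-expression sets, abundance slices, fragment/half tallies,
# PCA and hierarchical clustering of samples, and the end-to-end pipeline
# driver. The published differential-expression tables are shipped as
# plain-text fixtures and re-analysed with the same operations.

#' Load a published-table fixture
#'
#' Transcriptions of the published differential-expression and abundance
#' tables, shipped as TSV under `inst/extdata/`:
#' \describe{
#'   \item{table1}{miRNAs changed D7 vs D0; blocks ASC_cells / BMSC_cells
#'     (the 10 miRNAs shared by both cell types), ASC_cells_vs_EV /
#'     ASC_EVs and BMSC_cells_vs_EV / BMSC_EVs (the cell-EV pair blocks).}
#'   \item{table2}{all 21 miRNAs changed in BMSC-EVs.}
#'   \item{table3}{the 4 miRNAs changed in ASC-EVs.}
#'   \item{table4}{top-3 isoacceptor percentages per sample group.}
#'   \item{table5}{tsRNAs changed in BMSC-EVs and ASC-EVs with their
#'     fragment/halve note.}
#' }
#'
#' @param name one of "table1".."table5".
#' @return data.frame.
#' @export
load_table_fixture <- function(name = c("table1", "table2", "table3",
                                        "table4", "table5")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "evsmallrna", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Extract a differential-expression set from a fixture
#'
#' Selects the requested blocks and deduplicates rows that are exact
#' repeats (the same feature printed with identical baseMean and log2fc
#' in two blocks); remaining duplicate features are an error.
#'
#' @param fixture data.frame with columns block, feature, baseMean,
#'   log2fc (table1/table5 layout) or feature, baseMean, log2fc.
#' @param blocks blocks to keep (NULL = all rows).
#' @return data.frame with one row per feature.
#' @export
de_set <- function(fixture, blocks = NULL) {
  df <- fixture
  if (!is.null(blocks)) {
    stopifnot("block" %in% names(df))
    df <- df[df$block %in% blocks, , drop = FALSE]
  }
  keep <- c("feature", "baseMean", "log2fc")
  df <- unique(df[, intersect(keep, names(df)), drop = FALSE])
  if (anyDuplicated(df$feature))
    stop("conflicting duplicate feature in DE set: ",
         df$feature[duplicated(df$feature)][1])
  rownames(df) <- NULL
  df
}

#' Overlap and direction concordance of two DE sets
#'
#' @param a,b data.frames with columns feature and log2fc (e.g. from
#'   [de_set()] or a significant subset of [nb_wald_test()] output).
#' @param a_name,b_name labels for the report.
#' @return list of class `overlap_summary`: shared features, n_shared,
#'   n_up_up, n_down_down, n_opposite, n_neutral (zero fold change,
#'   excluded from the three concordance classes), a_only, b_only.
#' @export
overlap <- function(a, b, a_name = "A", b_name = "B") {
  if (anyDuplicated(a$feature)) stop("duplicate feature in set A")
  if (anyDuplicated(b$feature)) stop("duplicate feature in set B")
  shared <- intersect(a$feature, b$feature)
  fa <- a$log2fc[match(shared, a$feature)]
  fb <- b$log2fc[match(shared, b$feature)]
  neutral <- fa == 0 | fb == 0
  structure(list(
    set_a_name = a_name, set_b_name = b_name,
    shared = shared, n_shared = length(shared),
    n_up_up = sum(!neutral & fa > 0 & fb > 0),
    n_down_down = sum(!neutral & fa < 0 & fb < 0),
    n_opposite = sum(!neutral & sign(fa) != sign(fb)),
    n_neutral = sum(neutral),
    a_only = setdiff(a$feature, shared),
    b_only = setdiff(b$feature, shared)), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("%s vs %s: %d shared (%d up/up, %d down/down, %d opposite)\n",
              x$set_a_name, x$set_b_name, x$n_shared, x$n_up_up,
              x$n_down_down, x$n_opposite))
  invisible(x)
}

#' Slice a DE set by abundance
#'
#' @param de_set data.frame carrying a baseMean column.
#' @param base_mean_min strict lower bound on baseMean.
#' @return rows with baseMean > `base_mean_min`, original order.
#' @export
abundance_slice <- function(de_set, base_mean_min) {
  stopifnot("baseMean" %in% names(de_set))
  de_set[de_set$baseMean > base_mean_min, , drop = FALSE]
}

#' Tally fragment/halve notes of a tsRNA table block
#'
#' @param block data.frame with a `note` column in {fragment, halve}.
#' @return named integer vector of counts per note value.
#' @export
type_tally <- function(block) {
  if (nrow(block) == 0) return(integer(0))
  if (!all(block$note %in% c("fragment", "halve")))
    stop("unknown note value: ",
         paste(setdiff(block$note, c("fragment", "halve")), collapse = ", "))
  tab <- table(block$note)
  setNames(as.integer(tab), names(tab))
}

log2_normalized <- function(cm) {
  sf <- estimate_size_factors(cm)
  log2(normalized_counts(cm, sf) + 1)
}

#' PCA of samples on normalized log2 expression
#'
#' Size-factor normalisation, log2(x + 1), restriction to the `n_top`
#' most variable features, per-feature centering, then singular value
#' decomposition. The sign of each component is fixed by making the
#' loading of the most variable feature non-negative, so coordinates are
#' fully deterministic.
#'
#' @param cm a `count_matrix` with >= 3 samples and >= 2 features.
#' @param n_top number of most-variable features used.
#' @param n_comp number of components returned.
#' @return list: `coords` (samples x components), `var_explained`.
#' @export
pca_samples <- function(cm, n_top = 500L, n_comp = 2L) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 3) stop("PCA needs >= 3 samples")
  if (nrow(cm$counts) < 2) stop("PCA needs >= 2 features")
  lm2 <- log2_normalized(cm)
  rv <- apply(lm2, 1, var)
  sel <- order(rv, decreasing = TRUE)[seq_len(min(n_top, nrow(lm2)))]
  x <- lm2[sel, , drop = FALSE]
  x <- x - rowMeans(x)
  sv <- svd(t(x))                       # rows = samples
  n_comp <- min(n_comp, length(sv$d))
  coords <- sv$u[, seq_len(n_comp), drop = FALSE] %*%
    diag(sv$d[seq_len(n_comp)], n_comp)
  for (k in seq_len(n_comp)) {          # sign anchored on top-variance feature
    ld <- sv$v[1, k]
    if (ld == 0) ld <- sv$v[which(sv$v[, k] != 0)[1], k]
    if (ld < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- colnames(cm$counts)
  colnames(coords) <- paste0("PC", seq_len(n_comp))
  list(coords = coords,
       var_explained = sv$d[seq_len(n_comp)]^2 / sum(sv$d^2))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering (stats::hclust) of Euclidean distances
#' between normalized log2 expression profiles.
#'
#' @param cm a `count_matrix` with >= 2 samples.
#' @param linkage agglomeration method, default "average".
#' @return an `hclust` object; leaf order via `$order`.
#' @export
hclust_samples <- function(cm, linkage = "average") {
  stopifnot(inherits(cm, "count_matrix"), ncol(cm$counts) >= 2)
  lm2 <- log2_normalized(cm)
  if (any(!is.finite(lm2))) stop("NaN in input")
  hclust(dist(t(lm2)), method = linkage)
}

#' Run the full simulated-experiment pipeline
#'
#' Simulate -> trim -> annotate -> tsRNA typing -> count matrices ->
#' abundance filter -> NB-Wald differential expression per stratum ->
#' overlap reporting. Writes a machine-readable `summary.json` (plus
#' per-stage TSVs) when `out_dir` is given; the run is fully determined
#' by `config$seed`.
#'
#' @param config list with elements: `refs` (a `reference_set`) or
#'   `ref_params` (list n_mirna/n_trna/n_background), `design` (sample
#'   sheet; default [design_table()]), `n_reads`, `error_rate`, `seed`,
#'   optional `contrasts` (list of list(cell_type, compartment)),
#'   `count_threshold` (default 50).
#' @param out_dir optional output directory.
#' @return invisible list with all intermediate results and the summary.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  need <- function(x, nm, default = NULL) {
    if (!is.null(x[[nm]])) return(x[[nm]])
    if (!is.null(default)) return(default)
    stop("pipeline config is missing '", nm, "'")
  }
  seed <- need(config, "seed", 1L)
  refs <- if (!is.null(config$refs)) {
    config$refs
  } else {
    rp <- need(config, "ref_params")
    generate_references(need(rp, "n_mirna"), need(rp, "n_trna"),
                        need(rp, "n_background"), seed = seed)
  }
  design <- need(config, "design", design_table())
  n_reads <- need(config, "n_reads", 5000L)
  error_rate <- need(config, "error_rate", 0.001)
  threshold <- need(config, "count_threshold", 50)
  contrasts <- need(config, "contrasts", {
    u <- unique(design[, c("cell_type", "compartment")])
    lapply(seq_len(nrow(u)), function(i)
      list(cell_type = u$cell_type[i], compartment = u$compartment[i]))
  })

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- stage("simulate",
    simulate_experiment(refs, design, n_reads = n_reads,
                        error_rate = error_rate, seed = seed))
  clean <- stage("trim", lapply(sim$samples, function(s)
    preprocess_fastq(s$reads)))
  ann <- stage("annotate", lapply(clean, function(cl)
    cascade_annotate(cl$reads, refs)))
  comps <- stage("composition", do.call(rbind, lapply(names(ann), function(sid)
    composition(ann[[sid]], sid))))
  tsr <- stage("tsrna", lapply(ann, tsrna_records, refs = refs))

  cm_mirna <- stage("counts",
    build_count_matrix(ann, design, level = "miRNA"))
  cm_tsrna <- stage("counts",
    build_count_matrix(ann, design, level = "tsRNA"))
  cm_mirna_f <- filter_low_expression(cm_mirna, threshold)
  cm_tsrna_f <- filter_low_expression(cm_tsrna, threshold)

  de <- stage("diffexp", lapply(contrasts, function(ct) {
    lab <- paste(ct$cell_type, ct$compartment, sep = "_")
    mir <- call_significant(
      nb_wald_test(cm_mirna_f, ct$cell_type, ct$compartment), "mirna")
    tsr <- call_significant(
      nb_wald_test(cm_tsrna_f, ct$cell_type, ct$compartment), "tsrna")
    list(label = lab, mirna = mir, tsrna = tsr)
  }))
  names(de) <- vapply(de, `[[`, character(1), "label")

  sig_sets <- lapply(de, function(d)
    d$mirna[d$mirna$significant, c("feature", "log2fc"), drop = FALSE])
  overlaps <- list()
  if (length(sig_sets) >= 2) {
    cmb <- utils::combn(names(sig_sets), 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      overlaps[[paste(a, b, sep = "__")]] <-
        overlap(sig_sets[[a]], sig_sets[[b]], a, b)
    }
  }

  summary <- list(
    seed = seed,
    n_samples = nrow(design),
    n_reads_per_sample = n_reads,
    composition = comps,
    de_counts = lapply(de, function(d)
      list(mirna_significant = sum(d$mirna$significant),
           tsrna_significant = sum(d$tsrna$significant),
           mirna_tested = sum(!is.na(d$mirna$wald_p)),
           tsrna_tested = sum(!is.na(d$tsrna$wald_p)))),
    overlaps = lapply(overlaps, function(o)
      o[c("set_a_name", "set_b_name", "n_shared", "n_up_up",
          "n_down_down", "n_opposite")]))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(comps, file.path(out_dir, "composition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in names(de)) {
      write.table(de[[nm]]$mirna,
                  file.path(out_dir, paste0("de_mirna_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(de[[nm]]$tsrna,
                  file.path(out_dir, paste0("de_tsrna_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(list(refs = refs, design = design, sim = sim, clean = clean,
                 annotations = ann, composition = comps, tsrna = tsr,
                 counts = list(miRNA = cm_mirna, tsRNA = cm_tsrna),
                 counts_filtered = list(miRNA = cm_mirna_f,
                                        tsRNA = cm_tsrna_f),
                 de = de, overlaps = overlaps, summary = summary))
}
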