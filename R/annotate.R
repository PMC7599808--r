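# Hierarchical read annotation: tRNA (<=1 mismatch) first, then miRNA
# (0 mismatches, untemplated 3' A/T tail tolerated), then background
# transcript classes and a genome stage, each read assigned at the first
# stage with any hit. Mirrors the mapping order small RNA studies use so
# that tRNA-derived reads are never absorbed by downstream classes.

#' Best ungapped placement of a read within one reference
#'
#' Scans every offset of the reference for an end-to-end, ungapped,
#' sense-strand placement of the read and returns the one with the fewest
#' mismatches (leftmost on ties), provided it needs at most `max_mismatch`.
#'
#' @param read_seq,ref_seq sequences (ACGT alphabet).
#' @param max_mismatch 0 or 1.
#' @return list(start, mismatches) with 0-based start, or NULL if no
#'   placement qualifies (including reads longer than the reference).
#' @export
match_substring <- function(read_seq, ref_seq, max_mismatch = 1L) {
  hit <- cpp_best_match(read_seq, ref_seq, as.integer(max_mismatch))
  if (length(hit) == 0) return(NULL)
  list(start = hit[1], mismatches = hit[2])
}

#' Match a read to a mature miRNA allowing an untemplated 3' A/T tail
#'
#' Finds the smallest tail length t in 0..`max_tail` such that the read's
#' last t bases are all A/T and the remaining prefix matches inside the
#' mature miRNA with zero mismatches. Preferring the smallest t means a
#' read whose terminal bases are templated is never called tailed.
#'
#' @param read_seq read sequence.
#' @param mirna_seq mature miRNA sequence.
#' @param max_tail maximum untemplated addition length.
#' @return list(tail_len, ref_start, ref_end) covering only the templated
#'   part, or NULL.
#' @export
match_mirna_with_tail <- function(read_seq, mirna_seq, max_tail = 3L) {
  n <- nchar(read_seq)
  if (n == 0) stop("empty read")
  for (t in 0:max_tail) {
    if (t >= n) break
    if (t > 0) {
      tail <- substr(read_seq, n - t + 1L, n)
      if (grepl("[^AT]", tail)) next
    }
    core <- substr(read_seq, 1L, n - t)
    if (nchar(core) > nchar(mirna_seq)) next
    hit <- cpp_best_match(core, mirna_seq, 0L)
    if (length(hit) > 0)
      return(list(tail_len = t, ref_start = hit[1],
                  ref_end = hit[1] + nchar(core)))
  }
  NULL
}

# stage -> data.frame(name, sequence), names sorted, for cascade_annotate
cascade_stage_refs <- function(refs) {
  bg <- refs$background
  pick <- function(df) df[order(df$name), c("name", "sequence"), drop = FALSE]
  list(
    tRNA = pick(refs$trnas),
    miRNA = pick(refs$mirnas),
    rRNA = pick(bg[bg$class == "rRNA", ]),
    mRNA = pick(bg[bg$class == "mRNA", ]),
    other_sRNA = pick(bg[bg$class == "other_sRNA", ]),
    genome = pick(bg[bg$class == "genome_decoy", ]))
}

annotate_one <- function(seq, stages, max_mismatch, max_tail) {
  for (stage in names(stages)) {
    st <- stages[[stage]]
    if (nrow(st) == 0) next
    if (stage == "miRNA") {
      # smallest tail first; within a tail length, 0-mismatch placements
      # tie-broken by start then name (refs are name-sorted)
      for (t in 0:max_tail) {
        n <- nchar(seq)
        if (t >= n) break
        if (t > 0 && grepl("[^AT]", substr(seq, n - t + 1L, n))) next
        core <- substr(seq, 1L, n - t)
        hit <- cpp_best_match_set(core, st$sequence, 0L)
        if (length(hit) > 0)
          return(list(category = "miRNA", ref_name = st$name[hit[1]],
                      ref_start = hit[2], ref_end = hit[2] + nchar(core),
                      mismatches = hit[3], tail_len = t))
      }
    } else {
      hit <- cpp_best_match_set(seq, st$sequence, max_mismatch)
      if (length(hit) > 0)
        return(list(category = stage, ref_name = st$name[hit[1]],
                    ref_start = hit[2], ref_end = hit[2] + nchar(seq),
                    mismatches = hit[3], tail_len = 0L))
    }
  }
  list(category = "unmapped", ref_name = "", ref_start = NA_integer_,
       ref_end = NA_integer_, mismatches = NA_integer_, tail_len = 0L)
}

#' Annotate clean reads through the class cascade
#'
#' Stages are tried strictly in the order tRNA (<= `max_mismatch`
#' mismatches), miRNA (0 mismatches, 3' A/T tail up to `max_tail`), rRNA,
#' mRNA, other small RNA, genome (all <= `max_mismatch`); a read is
#' assigned at the first stage with any hit. Within a stage, ties are
#' broken by fewest mismatches, then smallest reference start, then
#' lexicographically smallest reference name. Each read is counted once.
#'
#' @param reads clean reads data.frame (read_id, sequence) or character
#'   vector of sequences.
#' @param refs a `reference_set`.
#' @param max_mismatch mismatch budget for the non-miRNA stages (0 or 1).
#' @param max_tail maximum untemplated 3' A/T addition for the miRNA stage.
#' @return data.frame: read_id, category, ref_name, ref_start, ref_end
#'   (0-based half-open, templated part only), mismatches, tail_len.
#' @export
cascade_annotate <- function(reads, refs, max_mismatch = 1L, max_tail = 3L) {
  if (is.character(reads))
    reads <- data.frame(read_id = paste0("r", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  stopifnot(inherits(refs, "reference_set"),
            max_mismatch %in% c(0L, 1L))
  stages <- cascade_stage_refs(refs)
  if (all(vapply(stages, nrow, integer(1)) == 0))
    stop("reference set is empty")

  uniq <- unique(reads$sequence)
  ann <- lapply(uniq, annotate_one, stages = stages,
                max_mismatch = as.integer(max_mismatch),
                max_tail = as.integer(max_tail))
  idx <- match(reads$sequence, uniq)
  get <- function(fld, proto) vapply(ann, `[[`, proto, fld)[idx]
  data.frame(
    read_id = reads$read_id,
    category = get("category", character(1)),
    ref_name = get("ref_name", character(1)),
    ref_start = get("ref_start", integer(1)),
    ref_end = get("ref_end", integer(1)),
    mismatches = get("mismatches", integer(1)),
    tail_len = get("tail_len", integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-class composition of an annotated sample
#'
#' @param annotated output of [cascade_annotate()].
#' @param sample_id label carried into the output.
#' @return data.frame: sample_id, category, count, fraction (over all
#'   clean reads, unmapped included in the denominator).
#' @export
composition <- function(annotated, sample_id = "sample") {
  if (nrow(annotated) == 0) stop("empty annotation list")
  counts <- table(factor(annotated$category, levels = ALL_CATEGORIES))
  data.frame(sample_id = sample_id, category = names(counts),
             count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(annotated),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Insert length histogram of clean reads
#'
#' @param reads clean reads data.frame or character vector of sequences.
#' @param range inclusive length range of the histogram bins.
#' @return data.frame: length, count (all lengths in `range`, zeros kept).
#' @export
length_histogram <- function(reads, range = c(15L, 45L)) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  lens <- factor(nchar(seqs), levels = seq(range[1], range[2]))
  data.frame(length = seq(range[1], range[2]),
             count = as.integer(table(lens)), row.names = NULL)
}
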