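# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (full enumeration, no early exits) so they cannot
# share a bug with the package's optimised code paths.

# all (start, mismatches) placements of read in ref, 0-based
oracle_all_placements <- function(read, ref) {
  n <- nchar(read); m <- nchar(ref)
  if (n > m) return(data.frame(start = integer(0), mm = integer(0)))
  rs <- utf8ToInt(read)
  rf <- utf8ToInt(ref)
  starts <- 0:(m - n)
  mm <- vapply(starts, function(s) sum(rs != rf[(s + 1):(s + n)]), integer(1))
  data.frame(start = starts, mm = mm)
}

oracle_best_match <- function(read, ref, max_mm) {
  pl <- oracle_all_placements(read, ref)
  pl <- pl[pl$mm <= max_mm, , drop = FALSE]
  if (nrow(pl) == 0) return(NULL)
  pl <- pl[order(pl$mm, pl$start), , drop = FALSE]
  list(start = pl$start[1], mismatches = pl$mm[1])
}

# exhaustive cascade oracle: enumerates every stage/reference/offset/tail
oracle_annotate <- function(seq, refs, max_mm = 1L, max_tail = 3L) {
  stage_refs <- list(
    tRNA = refs$trnas[, c("name", "sequence")],
    miRNA = refs$mirnas[, c("name", "sequence")],
    rRNA = refs$background[refs$background$class == "rRNA",
                           c("name", "sequence")],
    mRNA = refs$background[refs$background$class == "mRNA",
                           c("name", "sequence")],
    other_sRNA = refs$background[refs$background$class == "other_sRNA",
                                 c("name", "sequence")],
    genome = refs$background[refs$background$class == "genome_decoy",
                             c("name", "sequence")])
  for (stage in names(stage_refs)) {
    st <- stage_refs[[stage]]
    if (nrow(st) == 0) next
    if (stage == "miRNA") {
      for (t in 0:max_tail) {
        n <- nchar(seq)
        if (t >= n) break
        if (t > 0 && grepl("[^AT]", substr(seq, n - t + 1, n))) next
        core <- substr(seq, 1, n - t)
        hits <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
          pl <- oracle_all_placements(core, st$sequence[i])
          pl <- pl[pl$mm == 0, , drop = FALSE]
          if (nrow(pl) == 0) return(NULL)
          data.frame(name = st$name[i], start = pl$start, mm = pl$mm)
        }))
        if (!is.null(hits) && nrow(hits) > 0) {
          hits <- hits[order(hits$mm, hits$start, hits$name), , drop = FALSE]
          return(list(category = "miRNA", ref_name = hits$name[1],
                      ref_start = hits$start[1],
                      ref_end = hits$start[1] + nchar(core),
                      mismatches = hits$mm[1], tail_len = t))
        }
      }
    } else {
      hits <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
        pl <- oracle_all_placements(seq, st$sequence[i])
        pl <- pl[pl$mm <= max_mm, , drop = FALSE]
        if (nrow(pl) == 0) return(NULL)
        data.frame(name = st$name[i], start = pl$start, mm = pl$mm)
      }))
      if (!is.null(hits) && nrow(hits) > 0) {
        hits <- hits[order(hits$mm, hits$start, hits$name), , drop = FALSE]
        return(list(category = stage, ref_name = hits$name[1],
                    ref_start = hits$start[1],
                    ref_end = hits$start[1] + nchar(seq),
                    mismatches = hits$mm[1], tail_len = 0L))
      }
    }
  }
  list(category = "unmapped", ref_name = "", ref_start = NA_integer_,
       ref_end = NA_integer_, mismatches = NA_integer_, tail_len = 0L)
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- (n / seq_len(n)) * p[o]
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# reconstruct the true insert of a simulated read from refs + truth row
truth_insert <- function(refs, truth_row) {
  seqs <- c(setNames(refs$mirnas$sequence, refs$mirnas$name),
            setNames(refs$trnas$sequence, refs$trnas$name),
            setNames(refs$background$sequence, refs$background$name))
  paste0(substr(seqs[[truth_row$ref_name]], truth_row$ref_start + 1,
                truth_row$ref_end),
         truth_row$tail_seq)
}

# count matrix straight from planted counts
make_cm <- function(counts, day = NULL, cell_type = "BMSC",
                    compartment = "cell") {
  ns <- ncol(counts)
  if (is.null(day)) day <- rep(c("D0", "D7"), each = ns / 2)
  md <- data.frame(sample_id = colnames(counts), cell_type = cell_type,
                   compartment = compartment, day = day,
                   donor = seq_len(ns), stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = md), class = "count_matrix")
}

# small hand-built reference set with no sequence screening
manual_refs <- function(mirnas = NULL, trnas = NULL, background = NULL) {
  empty_bg <- data.frame(name = character(0), class = character(0),
                         sequence = character(0), stringsAsFactors = FALSE)
  structure(list(
    mirnas = if (is.null(mirnas))
      data.frame(name = character(0), sequence = character(0),
                 stringsAsFactors = FALSE) else mirnas,
    trnas = if (is.null(trnas))
      data.frame(name = character(0), sequence = character(0),
                 anticodon_start = integer(0), loop_start = integer(0),
                 loop_end = integer(0), stringsAsFactors = FALSE) else trnas,
    background = if (is.null(background)) empty_bg else background),
    class = "reference_set")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
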