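# Quality filtering and 3' adapter trimming ("clean reads").

#' Locate and trim the 3' adapter from a read
#'
#' The adapter may occur in full or as a prefix overlapping the read's 3'
#' end by at least `min_overlap` bases; an occurrence passes if its
#' mismatch fraction over the overlap is at most `max_mismatch_rate`.
#' Among passing occurrences the one with the fewest mismatches wins,
#' leftmost on ties; the insert preceding it is returned.
#'
#' @param sequence read sequence (character scalar).
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum 3'-end overlap for a partial occurrence.
#' @param max_mismatch_rate maximum mismatches per overlapped base.
#' @return the insert (possibly ""), or NA_character_ when no adapter
#'   occurrence passes.
#' @export
trim_adapter <- function(sequence, adapter = DEFAULT_ADAPTER,
                         min_overlap = 10L, max_mismatch_rate = 0.1) {
  if (nchar(sequence) == 0) stop("empty read")
  if (nchar(adapter) == 0) stop("empty adapter")
  pos <- cpp_find_adapter(sequence, adapter, as.integer(min_overlap),
                          max_mismatch_rate)
  if (pos < 0) return(NA_character_)
  substr(sequence, 1L, pos)
}

phred_scores <- function(quality) utf8ToInt(quality) - 33L

#' Mean-quality and N-content filter
#'
#' @param sequence,quality read and Phred+33 quality of equal length.
#' @param mean_q_min minimum mean Phred score (boundary inclusive).
#' @param max_n_frac maximum tolerated fraction of N calls.
#' @return TRUE when the read passes.
#' @export
quality_filter <- function(sequence, quality, mean_q_min = 20,
                           max_n_frac = 0.1) {
  if (nchar(sequence) != nchar(quality))
    stop("sequence and quality lengths differ")
  q <- phred_scores(quality)
  n_frac <- lengths(regmatches(sequence, gregexpr("N", sequence))) /
    nchar(sequence)
  mean(q) >= mean_q_min && n_frac <= max_n_frac
}

#' Preprocess a FASTQ library into clean reads
#'
#' Applies, in order: the mean-quality/N filter, adapter trimming, and the
#' insert length window. Reads in which no adapter is found are retained
#' at full length provided they fit the length window (full-length tsRNA
#' inserts can lack adapter read-through); too-short or too-long survivors
#' are dropped and tallied. Input order is preserved.
#'
#' @param input FASTQ path or a reads data.frame
#'   (read_id/sequence/quality).
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len inclusive insert length window.
#' @param mean_q_min,max_n_frac quality-filter settings.
#' @param min_overlap,max_mismatch_rate adapter-matching settings.
#' @return list with `reads` (read_id, sequence, quality,
#'   original_length) and `stats` (n_input, n_low_quality,
#'   n_adapter_found, n_no_adapter, n_too_short, n_too_long, n_clean).
#' @export
preprocess_fastq <- function(input, adapter = DEFAULT_ADAPTER,
                             min_len = 15L, max_len = 45L,
                             mean_q_min = 20, max_n_frac = 0.1,
                             min_overlap = 10L, max_mismatch_rate = 0.1) {
  reads <- if (is.character(input)) read_fastq(input) else input
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  n_input <- nrow(reads)
  if (n_input == 0) {
    return(list(
      reads = data.frame(read_id = character(0), sequence = character(0),
                         quality = character(0), original_length = integer(0),
                         stringsAsFactors = FALSE),
      stats = data.frame(n_input = 0L, n_low_quality = 0L,
                         n_adapter_found = 0L, n_no_adapter = 0L,
                         n_too_short = 0L, n_too_long = 0L, n_clean = 0L)))
  }
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("malformed record: sequence/quality length mismatch at index ",
         which(nchar(reads$sequence) != nchar(reads$quality))[1])

  ok_qual <- vapply(seq_len(n_input), function(i)
    quality_filter(reads$sequence[i], reads$quality[i], mean_q_min,
                   max_n_frac), logical(1))
  n_low_quality <- sum(!ok_qual)

  kept <- reads[ok_qual, , drop = FALSE]
  pos <- if (nrow(kept) > 0)
    cpp_find_adapter(kept$sequence, adapter, as.integer(min_overlap),
                     max_mismatch_rate)
  else integer(0)
  has_adapter <- pos >= 0
  ins_len <- ifelse(has_adapter, pos, nchar(kept$sequence))

  too_short <- ins_len < min_len
  too_long <- ins_len > max_len
  keep <- !too_short & !too_long

  out <- data.frame(
    read_id = kept$read_id[keep],
    sequence = substr(kept$sequence[keep], 1L, ins_len[keep]),
    quality = substr(kept$quality[keep], 1L, ins_len[keep]),
    original_length = nchar(kept$sequence[keep]),
    stringsAsFactors = FALSE, row.names = NULL)

  stats <- data.frame(
    n_input = n_input,
    n_low_quality = n_low_quality,
    n_adapter_found = sum(has_adapter),
    n_no_adapter = sum(!has_adapter),
    n_too_short = sum(too_short),
    n_too_long = sum(too_long),
    n_clean = nrow(out))
  stopifnot(stats$n_clean ==
              n_input - n_low_quality - stats$n_too_short - stats$n_too_long)
  list(reads = out, stats = stats)
}
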