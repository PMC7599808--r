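# Typing of tRNA-mapped reads into 5'/3' halves and fragments, coverage
# profiles along mature tRNAs, and isoacceptor abundance tables.
#
# Halves are 30-40 nt cleavage products anchored at a mature tRNA
# terminus (anticodon-loop cleavage leaves the 5' piece starting at the
# 5' end and the 3' piece ending at the CCA end); fragments are shorter
# internal species. Reads of 27-29 nt fall between the two published
# ranges and are typed as fragments ("shorter than 30 nt"); anchored
# reads of >= 30 nt failing both anchors are flagged nonstandard.

#' Type one tRNA-mapped read
#'
#' @param ref_start,ref_end 0-based half-open coordinates on the mature
#'   tRNA (vectors allowed).
#' @param trna_len length of the mature tRNA (recycled).
#' @param anchor_tol terminus anchor tolerance in nt (ragged ends).
#' @return data.frame: tsrna_type in {half_5p, half_3p, fragment} and a
#'   logical `nonstandard` flag for >= 30 nt reads anchored at neither end.
#' @export
classify_tsrna <- function(ref_start, ref_end, trna_len, anchor_tol = 1L) {
  len <- ref_end - ref_start
  type <- rep("fragment", length(len))
  nonstandard <- rep(FALSE, length(len))
  is5 <- len >= 30 & ref_start <= anchor_tol
  is3 <- len >= 30 & !is5 & ref_end >= trna_len - anchor_tol
  type[is5] <- "half_5p"
  type[is3] <- "half_3p"
  odd <- len >= 30 & !is5 & !is3
  nonstandard[odd] <- TRUE
  data.frame(tsrna_type = type, nonstandard = nonstandard)
}

#' Extract typed tsRNA records from an annotated sample
#'
#' @param annotated output of [cascade_annotate()].
#' @param refs a `reference_set` (for mature tRNA lengths).
#' @return data.frame: read_id, trna_name, ref_start, ref_end, length,
#'   tsrna_type, nonstandard.
#' @export
tsrna_records <- function(annotated, refs) {
  tr <- annotated[annotated$category == "tRNA", , drop = FALSE]
  if (nrow(tr) == 0)
    return(data.frame(read_id = character(0), trna_name = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      length = integer(0), tsrna_type = character(0),
                      nonstandard = logical(0)))
  lens <- setNames(nchar(refs$trnas$sequence), refs$trnas$name)
  if (!all(tr$ref_name %in% names(lens)))
    stop("annotated tRNA reference not in reference set")
  trna_len <- lens[tr$ref_name]
  if (any(tr$ref_end > trna_len))
    stop("record coordinates outside reference length")
  cls <- classify_tsrna(tr$ref_start, tr$ref_end, trna_len)
  data.frame(read_id = tr$read_id, trna_name = tr$ref_name,
             ref_start = tr$ref_start, ref_end = tr$ref_end,
             length = tr$ref_end - tr$ref_start,
             tsrna_type = cls$tsrna_type, nonstandard = cls$nonstandard,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Isoacceptor abundance table
#'
#' Read counts and percentages of all tRNA-mapped reads per isoacceptor,
#' sorted by decreasing percentage (ties by name), with the dominant
#' tsRNA type of each isoacceptor (majority vote; ties resolved in favour
#' of halves, 5' before 3').
#'
#' @param records output of [tsrna_records()].
#' @return data.frame: trna_name, count, percentage, dominant_type.
#' @export
isoacceptor_abundance <- function(records) {
  if (nrow(records) == 0) stop("empty tsRNA record list")
  counts <- table(records$trna_name)
  type_pref <- c("half_5p", "half_3p", "fragment")
  dominant <- vapply(names(counts), function(nm) {
    tt <- table(factor(records$tsrna_type[records$trna_name == nm],
                       levels = type_pref))
    type_pref[which.max(tt)]          # which.max takes the first max: 5' half
  }, character(1))
  out <- data.frame(trna_name = names(counts), count = as.integer(counts),
                    percentage = 100 * as.integer(counts) / sum(counts),
                    dominant_type = dominant,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$percentage, out$trna_name), , drop = FALSE]
}

#' Read coverage along mature tRNAs
#'
#' Per-position read depth for each tRNA plus a meta-profile aggregating
#' depth into 100 percentile bins across tRNAs of different lengths
#' (position p on a tRNA of length L contributes to bin
#' floor(100 p / L)).
#'
#' @param records output of [tsrna_records()].
#' @param refs a `reference_set`.
#' @return list with `per_trna` (named list of depth vectors, position
#'   1..L) and `meta` (data.frame bin 0..99, depth).
#' @export
coverage_profiles <- function(records, refs) {
  lens <- setNames(nchar(refs$trnas$sequence), refs$trnas$name)
  if (nrow(records) > 0 && !all(records$trna_name %in% names(lens)))
    stop("record references unknown tRNA")
  per <- lapply(names(lens), function(nm) {
    depth <- integer(lens[[nm]])
    rr <- records[records$trna_name == nm, , drop = FALSE]
    if (nrow(rr) > 0 && (any(rr$ref_start < 0) || any(rr$ref_end > lens[[nm]])))
      stop("record coordinates outside reference length for ", nm)
    for (i in seq_len(nrow(rr))) {
      span <- (rr$ref_start[i] + 1L):rr$ref_end[i]
      depth[span] <- depth[span] + 1L
    }
    depth
  })
  names(per) <- names(lens)
  meta <- numeric(100)
  for (nm in names(per)) {
    L <- lens[[nm]]
    bin <- pmin(floor(100 * (seq_len(L) - 1L) / L), 99)
    agg <- tapply(per[[nm]], bin, sum)
    meta[as.integer(names(agg)) + 1L] <- meta[as.integer(names(agg)) + 1L] +
      as.numeric(agg)
  }
  list(per_trna = per,
       meta = data.frame(bin = 0:99, depth = meta, row.names = NULL))
}

#' Length histogram of tsRNA records
#'
#' @param records output of [tsrna_records()].
#' @param range inclusive length range of the histogram bins.
#' @return data.frame: length, count.
#' @export
tsrna_length_histogram <- function(records, range = c(15L, 45L)) {
  lens <- factor(records$length, levels = seq(range[1], range[2]))
  data.frame(length = seq(range[1], range[2]),
             count = as.integer(table(lens)), row.names = NULL)
}
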