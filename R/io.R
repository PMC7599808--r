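# FASTA/FASTQ I/O, thin wrappers over Biostrings.

#' Write reads as Phred+33 FASTQ
#'
#' @param reads data.frame with read_id, sequence, quality.
#' @param path output path (".gz" compresses).
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)),
            all(nchar(reads$sequence) == nchar(reads$quality)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with read_id, sequence, quality.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ file: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a reference set as per-class FASTA files
#'
#' Writes trna.fa, mirna.fa, rrna.fa, mrna.fa, other.fa and genome.fa
#' under `dir`.
#'
#' @param refs a `reference_set`.
#' @param dir output directory (created if absent).
#' @export
write_reference_fasta <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(names, seqs, file) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names
    Biostrings::writeXStringSet(x, file.path(dir, file))
  }
  w(refs$trnas$name, refs$trnas$sequence, "trna.fa")
  w(refs$mirnas$name, refs$mirnas$sequence, "mirna.fa")
  bg <- refs$background
  map <- c(rRNA = "rrna.fa", mRNA = "mrna.fa", other_sRNA = "other.fa",
           genome_decoy = "genome.fa")
  for (cls in names(map)) {
    sub <- bg[bg$class == cls, ]
    if (nrow(sub) > 0) w(sub$name, sub$sequence, map[[cls]])
  }
  invisible(dir)
}

#' Read a FASTA file into a name/sequence data.frame
#'
#' @param path FASTA path.
#' @return data.frame with name, sequence.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(name = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}
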