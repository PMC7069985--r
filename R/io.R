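## FASTQ and TSV plumbing.  FASTQ goes through Biostrings; tables are plain
## TSV so every artifact of a run is a text file.

#' Write reads to a FASTQ file (Sanger/Phred+33)
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$quality)
  ## qualities travel separately; the (empty) mcols of x are irrelevant
  suppressWarnings(
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q))
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file (Sanger/Phred+33).
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = sub(" .*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)))
}

#' Write an amplicon reference to FASTA
#' @param amplicon amplicon bundle.
#' @param path output file.
#' @export
write_amplicon_fasta <- function(amplicon, path) {
  r <- amplicon$reference
  x <- Biostrings::DNAStringSet(r$sequence)
  names(x) <- sprintf("%s %s:%d-%d", r$amplicon_id, r$chrom,
                      r$start_coord, r$end_coord)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
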