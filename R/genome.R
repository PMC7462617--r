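#' Read a genome FASTA
#'
#' The genome travels through the package as a named character vector of
#' upper-case sequences (one element per chromosome); FASTA IO is delegated
#' to Biostrings. First whitespace-separated token of each header is the
#' chromosome name.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  assert_that(file.exists(path), "genome FASTA not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a genome FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract a genome slice (0-based half-open)
#' @param genome named character vector.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates; clipped to the chromosome.
#' @return Character scalar.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  assert_that(chrom %in% names(genome), "unknown chromosome: %s", chrom)
  n <- nchar(genome[[chrom]])
  substr(genome[[chrom]], max(0L, start) + 1L, min(n, end))
}

#' Write named sequences as FASTA
#' @param seqs named character vector (ids -> sequences).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  write_genome(seqs, path)
}

#' Read sequences from FASTA as a named character vector
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  read_genome(path)
}
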