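#' Genome sequence container
#'
#' A `genome_sequence` is a named character vector of uppercase chromosome
#' sequences over the alphabet A, C, G, T, N. It is the substrate for all PAM
#' scanning and primer extraction. Lowercase (soft-masked) input is uppercased;
#' masking is ignored.
#'
#' @param x Named character vector of DNA sequences, one per chromosome.
#' @return A validated `genome_sequence` object.
#' @examples
#' g <- genome_sequence(c(chrI = "acgtACGTacgt"))
#' chrom_length(g, "chrI")
#' @export
genome_sequence <- function(x) {
  if (!is.character(x) || length(x) == 0L) {
    ko_error("invalid_genome", "genome must be a non-empty named character vector")
  }
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm)) || anyNA(nm)) {
    ko_error("invalid_genome", "every chromosome must be named")
  }
  if (anyDuplicated(nm)) {
    ko_error("invalid_genome", sprintf(
      "duplicate chromosome name(s): %s",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  x <- toupper(x)
  if (any(!nzchar(x)) || anyNA(x)) {
    ko_error("invalid_genome", "chromosome sequences must be non-empty")
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    ko_error("invalid_genome", sprintf(
      "chromosome '%s' contains characters outside A,C,G,T,N", nm[which(bad)[1]]
    ))
  }
  structure(x, class = "genome_sequence")
}

#' Read a genome from a FASTA file
#'
#' Multi-record, wrapped-line and CRLF-tolerant FASTA reading (via
#' [Biostrings::readDNAStringSet]); record names are truncated at the first
#' whitespace, as is conventional for assembly FASTA headers.
#'
#' @param path Path to a (possibly soft-masked) FASTA file.
#' @return A [genome_sequence] object.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    ko_error("missing_file", sprintf("genome FASTA not found: %s", path))
  }
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) ko_error("malformed_fasta", conditionMessage(e))
  )
  if (length(ss) == 0L) ko_error("malformed_fasta", "FASTA contains no records")
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome_sequence(seqs)
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence: %d chromosome(s), %s nt total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in names(x)) cat(sprintf("  %s: %s nt\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

#' Chromosome length lookup
#' @param genome A [genome_sequence].
#' @param chrom Chromosome name.
#' @return Integer length in nucleotides.
#' @export
chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    ko_error("unknown_chromosome", sprintf(
      "unknown chromosome '%s'; genome has: %s", chrom,
      paste(names(genome), collapse = ", ")
    ))
  }
  nchar(genome[[chrom]])
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick reverse complement over A,C,G,T with N mapping to N.
#' Vectorised over `seq`; an empty string returns an empty string. Applying
#' the function twice returns the input (involution).
#'
#' @param seq Character vector of DNA strings (A,C,G,T,N; case-insensitive).
#' @return Character vector of reverse complements (uppercase).
#' @examples
#' reverse_complement("AAGG")  # "CCTT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  up <- toupper(seq)
  bad <- regexpr("[^ACGTN]", up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    ko_error("invalid_sequence", sprintf(
      "non-IUPAC character '%s' at position %d of sequence %d",
      substr(up[i], bad[i], bad[i]), bad[i], i
    ))
  }
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up))))
}

# Checksum binding an index cache to the genome it was built from.
genome_checksum <- function(genome) {
  digest::digest(list(names(genome), unname(unclass(genome))), algo = "md5")
}
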