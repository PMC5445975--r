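# Shared fixture builders. Everything is generated in code at test time;
# nothing is downloaded and nothing large is stored.

# pay the one-off Biostrings S4 lazy-load cost here so timed acceptance
# blocks measure the operations, not package loading
invisible(reverse_complement("ACGT"))

# spacers with no GG/CC dinucleotide anywhere, so planting one on a GG/CC-free
# background adds exactly one PAM-adjacent site (its own AGG PAM); aperiodic
# and mutually non-overlapping (no rotations/palindromes, unlike e.g. ACGT
# repeats, whose rotations collide with each other)
QUIET_SPACERS <- c(
  "ATCGATAGCTGATCAGTACG",
  "TGACTGTAGATCGTACATGA",
  "CATAGCGATATGCTAGTCAT",
  "GTCATAGTACGATCTAGCAT",
  "ACTGATCGTATCAGCTATGC"
)

# plant spacer+AGG elements onto a GG/CC-free AT-repeat background, returning
# the genome and the plus-strand spacer start positions
plant_on_quiet_background <- function(positions, spacers, chrom_len = 300L,
                                      chrom = "c1") {
  stopifnot(length(positions) == length(spacers))
  ch <- strsplit(strrep("AT", ceiling(chrom_len / 2)), "")[[1]][1:chrom_len]
  for (i in seq_along(positions)) {
    el <- paste0(spacers[i], "AGG")
    idx <- positions[i]:(positions[i] + 22L)
    stopifnot(max(idx) <= chrom_len)
    ch[idx] <- strsplit(el, "")[[1]]
  }
  genome_sequence(stats::setNames(paste(ch, collapse = ""), chrom))
}

# temporary FASTA for CLI/reader tests
write_tmp_fasta <- function(genome, path = tempfile(fileext = ".fa"), width = 60L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  path
}

write_tmp_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

demo_file <- function(name) {
  system.file("extdata", name, package = "crisprko", mustWork = TRUE)
}

random_dna <- function(n, gc = 0.36) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# order-normalise a site table for set comparisons
normalize_sites <- function(sites) {
  sites <- as.data.frame(sites)[, c("chrom", "strand", "pam_start", "pam_end",
                                    "spacer", "spacer_start", "spacer_end", "pam")]
  sites <- sites[order(sites$chrom, sites$pam_start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}
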