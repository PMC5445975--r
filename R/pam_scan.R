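#' Scan a genome for PAM-adjacent sgRNA spacers
#'
#' Finds every position on either strand where a 5'-NGG-3' PAM (the
#' S. pyogenes Cas9 protospacer-adjacent motif) is immediately preceded, on
#' the same strand, by a complete 20-nt spacer. Sites whose spacer or PAM
#' contains a literal N, or whose spacer would run off the chromosome end,
#' are skipped (their number is reported via a message when `quiet = FALSE`).
#'
#' All coordinates are 1-based inclusive on the plus strand. For a '-'-strand
#' site the PAM occupies plus-strand bases reading CCN and the spacer lies
#' immediately 3' of it in plus-strand coordinates; `spacer` and `pam` columns
#' always hold the site's own-strand sequence (spacer then NGG, 5'->3').
#'
#' @param genome A [genome_sequence].
#' @param quiet Suppress the skipped-site summary message.
#' @return A data frame of class `pam_sites` with columns `chrom`, `strand`,
#'   `pam_start`, `pam_end`, `spacer`, `spacer_start`, `spacer_end`, `pam`,
#'   sorted by (chrom, pam_start, strand; '+' first).
#' @examples
#' g <- genome_sequence(c(c1 = paste0(strrep("A", 20), "TGG")))
#' scan_pams(g)
#' @export
scan_pams <- function(genome, quiet = TRUE) {
  if (!inherits(genome, "genome_sequence")) genome <- genome_sequence(genome)
  res <- lapply(names(genome), function(chrom) {
    scan_chromosome(genome[[chrom]], chrom)
  })
  skipped <- sum(vapply(res, function(r) attr(r, "n_skipped"), numeric(1)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  # genome order for chrom, then PAM position, '+' before '-'
  ord <- order(match(out$chrom, names(genome)), out$pam_start,
               match(out$strand, c("+", "-")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet && skipped > 0) {
    message(sprintf("scan_pams: skipped %d site(s) with N in spacer/PAM", skipped))
  }
  class(out) <- c("pam_sites", "data.frame")
  out
}

# Single-chromosome scan; vectorised on the byte representation.
scan_chromosome <- function(seq, chrom) {
  n <- nchar(seq)
  empty <- data.frame(
    chrom = character(0), strand = character(0),
    pam_start = integer(0), pam_end = integer(0),
    spacer = character(0), spacer_start = integer(0), spacer_end = integer(0),
    pam = character(0), stringsAsFactors = FALSE
  )
  if (n < 23L) {
    attr(empty, "n_skipped") <- 0
    return(empty)
  }
  b <- charToRaw(seq)
  G <- charToRaw("G"); C <- charToRaw("C")

  # '+': PAM at p..p+2 == NGG, spacer at p-20..p-1
  # b[-c(1,2)][i] == b[i+2], b[-c(1,n)][i] == b[i+1], so matches give p = i
  p_plus <- which(b[-c(1L, 2L)] == G & b[-c(1L, n)] == G)
  p_plus <- p_plus[p_plus >= 21L]
  # '-': plus strand reads CCN at p..p+2, spacer at p+3..p+22
  p_minus <- which(b[-c(n - 1L, n)] == C & b[-c(1L, n)] == C)   # b[p]==C & b[p+1]==C
  p_minus <- p_minus[p_minus + 22L <= n]

  n_skipped <- 0L
  plus <- empty
  if (length(p_plus)) {
    spacer <- substring(seq, p_plus - 20L, p_plus - 1L)
    pam <- substring(seq, p_plus, p_plus + 2L)
    keep <- !grepl("N", spacer, fixed = TRUE) & !grepl("N", pam, fixed = TRUE)
    n_skipped <- n_skipped + sum(!keep)
    if (any(keep)) {
      p <- p_plus[keep]
      plus <- data.frame(
        chrom = chrom, strand = "+",
        pam_start = p, pam_end = p + 2L,
        spacer = spacer[keep], spacer_start = p - 20L, spacer_end = p - 1L,
        pam = pam[keep], stringsAsFactors = FALSE
      )
    }
  }
  minus <- empty
  if (length(p_minus)) {
    spacer_fwd <- substring(seq, p_minus + 3L, p_minus + 22L)
    pam_fwd <- substring(seq, p_minus, p_minus + 2L)
    keep <- !grepl("N", spacer_fwd, fixed = TRUE) & !grepl("N", pam_fwd, fixed = TRUE)
    n_skipped <- n_skipped + sum(!keep)
    if (any(keep)) {
      p <- p_minus[keep]
      minus <- data.frame(
        chrom = chrom, strand = "-",
        pam_start = p, pam_end = p + 2L,
        spacer = reverse_complement(spacer_fwd[keep]),
        spacer_start = p + 3L, spacer_end = p + 22L,
        pam = reverse_complement(pam_fwd[keep]), stringsAsFactors = FALSE
      )
    }
  }
  out <- rbind(plus, minus)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Suffix lengths used by the similarity profile (PAM-proximal)
#' @export
SIMILARITY_KS <- c(20L, 18L, 16L, 14L, 12L, 10L, 8L)

#' Build the genome-wide sgRNA suffix-count index
#'
#' Counts, over all PAM-adjacent spacers found by [scan_pams()], how many
#' sites share each PAM-proximal suffix of length k for
#' k = 8, 10, 12, 14, 16, 18, 20. The k = 20 table doubles as the full-spacer
#' occurrence count used for the genome-uniqueness filter.
#'
#' @param sites A `pam_sites` data frame from [scan_pams()].
#' @param genome Optional [genome_sequence]; when given, its checksum is
#'   embedded so a serialised cache can be matched to its genome.
#' @return An `sgrna_index` object: list with `spacer_counts` (named integer
#'   vector, full 20-nt spacer -> count), `suffix_counts` (list keyed
#'   "8".."20" of named integer vectors), `n_sites`, `checksum`.
#' @export
build_index <- function(sites, genome = NULL) {
  if (nrow(sites) > 0 && any(nchar(sites$spacer) != 20L)) {
    ko_error("internal_consistency", "index input contains a spacer of length != 20")
  }
  suffix_counts <- lapply(SIMILARITY_KS, function(k) {
    if (nrow(sites) == 0) return(integer(0))
    tab <- table(substring(sites$spacer, 21L - k, 20L))
    stats::setNames(as.integer(tab), names(tab))
  })
  names(suffix_counts) <- as.character(SIMILARITY_KS)
  structure(list(
    spacer_counts = suffix_counts[["20"]],
    suffix_counts = suffix_counts,
    n_sites = nrow(sites),
    checksum = if (!is.null(genome)) genome_checksum(genome) else NA_character_
  ), class = "sgrna_index")
}

#' @export
print.sgrna_index <- function(x, ...) {
  cat(sprintf("sgrna_index: %d PAM-adjacent sites, %d distinct spacers\n",
              x$n_sites, length(x$spacer_counts)))
  invisible(x)
}

#' Similarity profile of a spacer against the genome-wide index
#'
#' For each PAM-proximal suffix length k in 20, 18, 16, 14, 12, 10, 8
#' (counting from the PAM end of the spacer), the number of PAM-adjacent
#' spacers genome-wide sharing that suffix. The queried spacer's own genomic
#' occurrence(s) are included, so a genome-unique spacer has count 1 at
#' k = 20; a spacer absent from the genome may report 0 there. Counts are
#' non-decreasing from k = 20 toward k = 8.
#'
#' @param index An `sgrna_index` from [build_index()].
#' @param spacer A 20-nt spacer (no N).
#' @return Named integer vector `c(k20=..., k18=..., ..., k8=...)`.
#' @export
similarity_profile <- function(index, spacer) {
  if (!is_scalar_string(spacer) || nchar(spacer) != 20L) {
    ko_error("invalid_sequence", "spacer must be a single 20-nt string")
  }
  spacer <- toupper(spacer)
  if (grepl("[^ACGT]", spacer)) {
    ko_error("invalid_sequence", "spacer must contain only A,C,G,T")
  }
  counts <- vapply(SIMILARITY_KS, function(k) {
    suf <- substring(spacer, 21L - k, 20L)
    cnt <- index$suffix_counts[[as.character(k)]][suf]
    if (is.na(cnt)) 0L else as.integer(cnt)
  }, integer(1))
  stats::setNames(counts, paste0("k", SIMILARITY_KS))
}

#' Serialise an sgRNA index to a JSON-lines cache
#'
#' Line 1 is a metadata header holding the genome checksum; each following
#' line holds the suffix-count table for one k. [load_index()] refuses a
#' cache whose checksum does not match the genome it is asked to serve.
#'
#' @param index An `sgrna_index` built with its `genome` argument set.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  if (is.na(index$checksum)) {
    ko_error("invalid_index", "index was built without a genome checksum; rebuild with build_index(sites, genome)")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(
    format = "crisprko-index", version = 1L,
    checksum = index$checksum, n_sites = index$n_sites
  ), auto_unbox = TRUE), con)
  for (k in names(index$suffix_counts)) {
    writeLines(jsonlite::toJSON(list(
      k = as.integer(k), counts = as.list(index$suffix_counts[[k]])
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Load an sgRNA index cache, verifying it matches the genome
#'
#' @param path Cache file written by [save_index()].
#' @param genome The [genome_sequence] the cache must correspond to.
#' @return An `sgrna_index`.
#' @export
load_index <- function(path, genome) {
  if (!file.exists(path)) ko_error("missing_file", sprintf("index cache not found: %s", path))
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  if (!identical(meta$format, "crisprko-index")) {
    ko_error("invalid_index", "not a crisprko index cache")
  }
  if (!identical(meta$checksum, genome_checksum(genome))) {
    ko_error("stale_index", "index cache checksum does not match the supplied genome; rebuild the index")
  }
  suffix_counts <- list()
  for (ln in lines[-1]) {
    rec <- jsonlite::fromJSON(ln)
    cnt <- unlist(rec$counts)
    suffix_counts[[as.character(rec$k)]] <-
      stats::setNames(as.integer(cnt), names(cnt)) %||% integer(0)
  }
  # keep canonical k order
  suffix_counts <- suffix_counts[as.character(SIMILARITY_KS)]
  structure(list(
    spacer_counts = suffix_counts[["20"]] %||% integer(0),
    suffix_counts = suffix_counts,
    n_sites = meta$n_sites,
    checksum = meta$checksum
  ), class = "sgrna_index")
}
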