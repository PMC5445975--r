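#' Enumerate genome-unique sgRNA candidates inside a target region
#'
#' Scans the target region for PAM-adjacent 20-nt spacers (both strands),
#' keeps only spacers whose full 20-mer occurs exactly once among all
#' PAM-adjacent spacers genome-wide, and annotates each candidate with its
#' similarity profile, seed uniqueness (12-nt PAM-proximal suffix unique
#' genome-wide), predicted cut site and mutable window. Candidates are
#' returned ranked (see [rank_candidates()]).
#'
#' In the default `"contain"` mode both spacer and PAM must lie fully inside
#' the region; `"overhang"` mode only requires the PAM inside the region and
#' lets the spacer extend past the region boundary.
#'
#' An empty result is legal (and warned about, class
#' `crisprko_no_candidates`); a region shorter than 23 nt cannot hold a
#' spacer+PAM in contain mode and yields an empty result with a warning
#' rather than an error.
#'
#' @param region A `target_region` from [parse_region()]/[resolve_gene()].
#' @param genome The [genome_sequence] the index was built from.
#' @param index The genome-wide `sgrna_index` from [build_index()].
#' @param mode Containment mode, `"contain"` (default) or `"overhang"`.
#' @return An `sgrna_candidates` data frame with columns `rank`, `chrom`,
#'   `strand`, `spacer`, `pam`, `spacer_start`, `spacer_end`, `pam_start`,
#'   `pam_end`, `cut_position`, `mut_start`, `mut_end`, `seed_unique`,
#'   `k20` .. `k8`.
#' @export
enumerate_candidates <- function(region, genome, index,
                                 mode = c("contain", "overhang")) {
  mode <- match.arg(mode)
  stopifnot(inherits(region, "target_region"))
  len <- chrom_length(genome, region$chrom)

  if (mode == "contain" && region_length(region) < 23L) {
    ko_warning("no_candidates", sprintf(
      "region %s is %d nt, shorter than the 23 nt needed for a spacer+PAM; no candidates",
      format_region(region), region_length(region)
    ))
    return(rank_candidates(empty_candidates()))
  }

  win_start <- if (mode == "contain") region$start else max(1L, region$start - 20L)
  win_end <- if (mode == "contain") region$end else min(len, region$end + 20L)
  sub <- genome_sequence(stats::setNames(
    subseq1(genome[[region$chrom]], win_start, win_end), region$chrom
  ))
  sites <- scan_pams(sub)
  off <- win_start - 1L
  for (col in c("pam_start", "pam_end", "spacer_start", "spacer_end")) {
    sites[[col]] <- sites[[col]] + off
  }
  if (mode == "overhang") {
    keep <- sites$pam_start >= region$start & sites$pam_end <= region$end
    sites <- sites[keep, , drop = FALSE]
  }

  if (nrow(sites) == 0L) {
    ko_warning("no_candidates", sprintf("no PAM site with a full spacer in region %s",
                                        format_region(region)))
    return(rank_candidates(empty_candidates()))
  }

  prof <- t(vapply(sites$spacer, function(sp) similarity_profile(index, sp),
                   integer(length(SIMILARITY_KS))))
  rownames(prof) <- NULL
  cand <- cbind(sites, as.data.frame(prof))
  cand <- cand[cand$k20 == 1L, , drop = FALSE]
  if (nrow(cand) == 0L) {
    ko_warning("no_candidates", sprintf(
      "all %d PAM-adjacent spacer(s) in region %s occur more than once genome-wide",
      nrow(sites), format_region(region)
    ))
    return(rank_candidates(empty_candidates()))
  }
  cand$seed_unique <- cand$k12 == 1L
  cand <- annotate_cut_and_window(cand)
  rank_candidates(cand)
}

empty_candidates <- function() {
  out <- data.frame(
    chrom = character(0), strand = character(0),
    pam_start = integer(0), pam_end = integer(0),
    spacer = character(0), spacer_start = integer(0), spacer_end = integer(0),
    pam = character(0), stringsAsFactors = FALSE
  )
  for (k in SIMILARITY_KS) out[[paste0("k", k)]] <- integer(0)
  out$seed_unique <- logical(0)
  out$cut_position <- integer(0)
  out$mut_start <- integer(0)
  out$mut_end <- integer(0)
  out
}

#' Annotate Cas9 cut site and mutable window
#'
#' Cas9 cuts bluntly 3 bp upstream of the PAM, i.e. between spacer positions
#' 17 and 18 counted from the spacer's 5' end. The stored `cut_position` is
#' the plus-strand coordinate of spacer base 17 (the last base of the 17-nt
#' PAM-distal segment, on the site's own strand): for a '+' site with PAM at
#' p..p+2 this is p-4; for a '-' site with PAM at plus-strand p..p+2 it is
#' p+6. The mutable window (`mut_start`..`mut_end`) is the plus-strand
#' interval of the 10 spacer bases adjacent to the PAM — the only positions
#' where point mutations can be introduced while still blocking re-cutting.
#'
#' @param cand A data frame of PAM sites/candidates (from [scan_pams()] or
#'   [enumerate_candidates()]).
#' @return The input with `cut_position`, `mut_start`, `mut_end` columns.
#' @export
annotate_cut_and_window <- function(cand) {
  plus <- cand$strand == "+"
  cand$cut_position <- ifelse(plus,
                              cand$spacer_start + 16L,   # == pam_start - 4
                              cand$spacer_end - 16L)     # == pam_start + 6
  cand$mut_start <- ifelse(plus, cand$pam_start - 10L, cand$pam_start + 3L)
  cand$mut_end <- ifelse(plus, cand$pam_start - 1L, cand$pam_start + 12L)
  cand$cut_position <- as.integer(cand$cut_position)
  cand$mut_start <- as.integer(cand$mut_start)
  cand$mut_end <- as.integer(cand$mut_end)
  cand
}

#' Rank sgRNA candidates by genome-wide similarity
#'
#' Ascending lexicographic order on the profile tuple
#' (k20, k18, k16, k14, k12, k10, k8): fewer suffix-sharing spacers at longer
#' shared lengths means lower off-target risk, so the most unique guide is
#' ranked first. Ties are broken by ascending `spacer_start`, then '+' strand
#' before '-'. The ordering is total, so the output never depends on input
#' order.
#'
#' @param cand An `sgrna_candidates` data frame with profile columns.
#' @return The same rows reordered, with `rank` assigned 1..n and moved to
#'   the first column.
#' @export
rank_candidates <- function(cand) {
  keys <- c(paste0("k", SIMILARITY_KS))
  ord <- do.call(order, c(unname(as.list(cand[keys])),
                          list(cand$spacer_start, match(cand$strand, c("+", "-")))))
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  first <- c("rank", "chrom", "strand", "spacer", "pam",
             "spacer_start", "spacer_end", "pam_start", "pam_end",
             "cut_position", "seed_unique", keys, "mut_start", "mut_end")
  cand <- cand[, c(first, setdiff(names(cand), first)), drop = FALSE]
  class(cand) <- c("sgrna_candidates", "data.frame")
  cand
}
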