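#' Seeded synthetic genome with planted sgRNA sites
#'
#' Generates a deterministic random genome in which specific spacer+PAM
#' elements are planted at known coordinates, returning both the genome and
#' the exact truth table of planted sites. Background sequence is
#' rejection-sampled until no planted 20-mer occurs anywhere (either strand)
#' other than where it was planted, so the truth table's occurrence counts
#' are exact by construction. This emulates the only genome features the
#' design pipeline reads — base composition, PAM density and spacer
#' uniqueness — not chromatin, repeats or annotation realism.
#'
#' The default GC fraction of 0.36 matches the fission-yeast genome.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param planted Optional data frame with one row per planted site:
#'   `chrom`, `spacer` (20 nt, own strand), `pam` (NGG, own strand),
#'   `position` (plus-strand start of the 23-nt element), `strand`. A spacer
#'   planted in several rows yields a deliberately non-unique spacer.
#' @param seed Integer seed; same seed, same genome, byte for byte.
#' @param gc Background GC fraction.
#' @param n_runs Optional data frame `chrom`, `position`, `length` of N runs
#'   to splice into the background (they must not touch planted elements).
#' @param max_tries Rejection-sampling attempts before giving up.
#' @return List with `genome` (a [genome_sequence]) and `truth` (a
#'   `pam_sites`-shaped data frame of the planted sites).
#' @export
synth_genome <- function(chrom_lengths, planted = NULL, seed = 1L, gc = 0.36,
                         n_runs = NULL, max_tries = 50L) {
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)))
  if (!is.null(planted) && nrow(planted) > 0L) {
    if (any(nchar(planted$spacer) != 20L) || any(!grepl("^[ACGT]{20}$", planted$spacer))) {
      ko_error("invalid_fixture", "planted spacers must be 20 nt of A,C,G,T")
    }
    if (any(!grepl("^[ACGT]GG$", planted$pam))) {
      ko_error("invalid_fixture", "planted PAMs must match NGG")
    }
    if (any(!planted$strand %in% c("+", "-"))) {
      ko_error("invalid_fixture", "planted strand must be '+' or '-'")
    }
    for (cn in unique(planted$chrom)) {
      rows <- planted[planted$chrom == cn, , drop = FALSE]
      if (!cn %in% names(chrom_lengths)) {
        ko_error("invalid_fixture", sprintf("planted chromosome '%s' has no length", cn))
      }
      if (any(rows$position < 1L | rows$position + 22L > chrom_lengths[[cn]])) {
        ko_error("invalid_fixture", "planted element extends outside its chromosome")
      }
      iv <- rows[order(rows$position), "position"]
      if (length(iv) > 1L && any(diff(iv) < 23L)) {
        ko_error("invalid_fixture", "planted elements overlap")
      }
    }
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  planted_mers <- if (!is.null(planted) && nrow(planted) > 0L) {
    unique(planted$spacer)
  } else character(0)

  assemble_once <- function() {
    chroms <- vapply(names(chrom_lengths), function(cn) {
      ch <- sample(names(probs), chrom_lengths[[cn]], replace = TRUE, prob = probs)
      if (!is.null(n_runs)) {
        nr <- n_runs[n_runs$chrom == cn, , drop = FALSE]
        for (i in seq_len(nrow(nr))) {
          idx <- nr$position[i]:(nr$position[i] + nr$length[i] - 1L)
          ch[idx] <- "N"
        }
      }
      if (!is.null(planted)) {
        rows <- planted[planted$chrom == cn, , drop = FALSE]
        for (i in seq_len(nrow(rows))) {
          el <- if (rows$strand[i] == "+") {
            paste0(rows$spacer[i], rows$pam[i])
          } else {
            reverse_complement(paste0(rows$spacer[i], rows$pam[i]))
          }
          idx <- rows$position[i]:(rows$position[i] + 22L)
          ch[idx] <- strsplit(el, "")[[1]]
        }
      }
      paste(ch, collapse = "")
    }, character(1))
    genome_sequence(chroms)
  }

  # occurrences of a 20-mer on either strand, as distinct plus-strand
  # positions (a revcomp-palindromic mer must not be counted twice)
  count_mer <- function(genome, mer) {
    rc <- reverse_complement(mer)
    sum(vapply(unclass(genome), function(s) {
      hits <- c(gregexpr(mer, s, fixed = TRUE)[[1]],
                gregexpr(rc, s, fixed = TRUE)[[1]])
      length(unique(hits[hits > 0]))
    }, numeric(1)))
  }

  genome <- NULL
  for (try in seq_len(max_tries)) {
    g <- assemble_once()
    ok <- TRUE
    for (mer in planted_mers) {
      expected <- sum(planted$spacer == mer)
      if (count_mer(g, mer) != expected) { ok <- FALSE; break }
    }
    if (ok) { genome <- g; break }
  }
  if (is.null(genome)) {
    ko_error("infeasible_fixture", sprintf(
      "could not place planted spacers without accidental duplicates in %d tries", max_tries
    ))
  }

  truth <- if (is.null(planted) || nrow(planted) == 0L) {
    empty_candidates()[, c("chrom", "strand", "pam_start", "pam_end",
                           "spacer", "spacer_start", "spacer_end", "pam")]
  } else {
    plus <- planted$strand == "+"
    data.frame(
      chrom = planted$chrom, strand = planted$strand,
      pam_start = ifelse(plus, planted$position + 20L, planted$position),
      pam_end = ifelse(plus, planted$position + 22L, planted$position + 2L),
      spacer = planted$spacer,
      spacer_start = ifelse(plus, planted$position, planted$position + 3L),
      spacer_end = ifelse(plus, planted$position + 19L, planted$position + 22L),
      pam = planted$pam, stringsAsFactors = FALSE
    )
  }
  list(genome = genome, truth = truth)
}

#' Draw a random 20-nt spacer with a random NGG PAM
#' @param gc GC fraction for the draw.
#' @return List with `spacer` and `pam` strings.
#' @export
random_spacer <- function(gc = 0.36) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  list(
    spacer = paste(sample(names(probs), 20L, replace = TRUE, prob = probs), collapse = ""),
    pam = paste0(sample(c("A", "C", "G", "T"), 1L), "GG")
  )
}

# -- independent brute-force oracles ------------------------------------------
# Deliberately share no code with scan_pams()/build_index(): character-level
# window checks and endsWith() counting, used only to cross-validate.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

#' Brute-force PAM-site oracle
#'
#' Window-by-window scan over every position of every chromosome, with an
#' independent reverse complement. Quadratic-ish and only for small genomes
#' (property tests); returns the same site table shape as [scan_pams()].
#'
#' @param genome A [genome_sequence].
#' @return A data frame shaped like the [scan_pams()] output.
#' @export
naive_oracle <- function(genome) {
  rows <- list()
  for (cn in names(genome)) {
    s <- genome[[cn]]
    n <- nchar(s)
    if (n < 23L) next
    for (i in seq_len(n - 22L)) {
      win <- substr(s, i, i + 22L)
      # '+': [20-nt spacer][NGG], no N anywhere in spacer or PAM
      if (substr(win, 22L, 22L) == "G" && substr(win, 23L, 23L) == "G" &&
          !grepl("N", win, fixed = TRUE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cn, strand = "+", pam_start = i + 20L, pam_end = i + 22L,
          spacer = substr(win, 1L, 20L), spacer_start = i, spacer_end = i + 19L,
          pam = substr(win, 21L, 23L), stringsAsFactors = FALSE
        )
      }
      # '-': plus strand reads [CCN][20-nt spacer-revcomp]
      if (substr(win, 1L, 1L) == "C" && substr(win, 2L, 2L) == "C" &&
          !grepl("N", win, fixed = TRUE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cn, strand = "-", pam_start = i, pam_end = i + 2L,
          spacer = oracle_revcomp(substr(win, 4L, 23L)),
          spacer_start = i + 3L, spacer_end = i + 22L,
          pam = oracle_revcomp(substr(win, 1L, 3L)), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(empty_candidates()[, c("chrom", "strand", "pam_start", "pam_end",
                                  "spacer", "spacer_start", "spacer_end", "pam")])
  }
  do.call(rbind, rows)
}

#' Write the demonstration fixture files
#'
#' Single entry point that regenerates the small plain-text fixtures shipped
#' under `inst/extdata/`: a two-chromosome synthetic genome (`genome.fa`), a
#' matching GFF3 with one coding and one non-coding gene
#' (`annotation.gff3`), and the synthetic demo plasmid (`plasmid.fa`). The
#' generating seed is recorded in each file header; everything is
#' deterministic given the seed.
#'
#' The two gene loci are placed at fixed coordinates: the coding gene `cdc2`
#' with an mRNA whose CDS span is I:601-1400 (two exons), and the non-coding
#' gene `SPNCRNA.01` spanning II:901-1500.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param gc Background GC fraction. The demo default is GC-balanced (0.5)
#'   rather than the fission-yeast-like 0.36 so that the checking-primer
#'   constraints (Tm 57-63 under the nearest-neighbor model) are satisfiable
#'   in every 250-nt flank of the demo loci; strongly AT-rich flanks can
#'   legitimately have no conforming primer window.
#' @return Invisibly, the paths written.
#' @export
write_demo_fixtures <- function(dir, seed = 4242L, gc = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sg <- synth_genome(c(I = 3000L, II = 3000L), seed = seed, gc = gc)
  fa <- file.path(dir, "genome.fa")
  con <- file(fa, "wt")
  for (nm in names(sg$genome)) {
    writeLines(sprintf(">%s synthetic demo genome, seed %d (not a real assembly)", nm, seed), con)
    s <- sg$genome[[nm]]
    writeLines(substring(s, seq(1, nchar(s), 70), pmin(seq(1, nchar(s), 70) + 69, nchar(s))), con)
  }
  close(con)

  gff <- file.path(dir, "annotation.gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf("# synthetic demo annotation, seed %d", seed),
    "I\tdemo\tgene\t551\t1450\t.\t+\t.\tID=SPBC11B10.09;Name=cdc2;synonyms=cdk1",
    "I\tdemo\tmRNA\t551\t1450\t.\t+\t.\tID=SPBC11B10.09.1;Parent=SPBC11B10.09",
    "I\tdemo\tCDS\t601\t900\t.\t+\t0\tID=SPBC11B10.09.1:cds1;Parent=SPBC11B10.09.1",
    "I\tdemo\tCDS\t1001\t1400\t.\t+\t0\tID=SPBC11B10.09.1:cds2;Parent=SPBC11B10.09.1",
    "II\tdemo\tgene\t901\t1500\t.\t-\t.\tID=SPNCRNA.01;Name=SPNCRNA.01"
  ), gff)

  pl <- file.path(dir, "plasmid.fa")
  toy <- toy_plasmid()
  writeLines(c(
    sprintf(">demo_plasmid synthetic stand-in (not the real Cas9/sgRNA vector), circular, insertion point %d",
            toy$insertion_point),
    toy$seq
  ), pl)
  invisible(c(fa, gff, pl))
}

#' Brute-force similarity profile oracle
#'
#' Counts suffix sharing by direct [endsWith()] comparison of one spacer
#' against every site's spacer; no suffix tables involved.
#'
#' @param sites Site table from [naive_oracle()] (or [scan_pams()]).
#' @param spacer 20-nt query.
#' @return Named integer vector `k20` .. `k8`.
#' @export
oracle_profile <- function(sites, spacer) {
  counts <- vapply(SIMILARITY_KS, function(k) {
    sum(endsWith(sites$spacer, substr(spacer, 21L - k, 20L)))
  }, integer(1))
  stats::setNames(counts, paste0("k", SIMILARITY_KS))
}
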