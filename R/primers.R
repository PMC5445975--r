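# Unified nearest-neighbor thermodynamics (Allawi & SantaLucia 1997).
# dH kcal/mol, dS cal/(mol K), keyed by the top-strand dinucleotide.
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# Duplex initiation with a terminal A·T vs G·C pair
NN_INIT_DH <- c(AT = 2.3, GC = 0.1)
NN_INIT_DS <- c(AT = 4.1, GC = -2.8)

#' Oligo melting temperature (nearest-neighbor model)
#'
#' Duplex Tm from unified nearest-neighbor thermodynamics with terminal
#' initiation penalties, an entropic salt correction
#' 0.368 (N-1) ln[Na+], and Tm = 1000 dH / (dS + R ln(C_T/4)) - 273.15 for a
#' non-self-complementary oligo at total strand concentration C_T. Defaults
#' are the Primer3 conditions: 50 mM monovalent cation, 50 nM oligo.
#' Deterministic and strand-symmetric (a sequence and its reverse complement
#' give the same Tm).
#'
#' @param seq Character vector of primer sequences (A,C,G,T only, length >= 8).
#' @param Na Monovalent cation concentration, mol/L.
#' @param oligo_conc Total oligo concentration C_T, mol/L.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("TGTAAAACGACGGCCAGT")
#' @export
melting_temperature <- function(seq, Na = 0.05, oligo_conc = 5e-8) {
  if (length(seq) == 0L) return(numeric(0))
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) {
    ko_error("invalid_sequence", "Tm is defined only for A,C,G,T sequences")
  }
  n <- nchar(seq)
  if (any(n < 8L)) {
    ko_error("invalid_sequence", "Tm requires sequences of at least 8 nt")
  }
  R <- 1.987  # cal/(mol K)
  k <- oligo_conc / 4
  vapply(seq, function(s) {
    len <- nchar(s)
    di <- substring(s, 1:(len - 1L), 2:len)
    ends <- ifelse(c(substr(s, 1, 1), substr(s, len, len)) %in% c("A", "T"), "AT", "GC")
    dH <- sum(NN_DH[di]) + sum(NN_INIT_DH[ends])
    dS <- sum(NN_DS[di]) + sum(NN_INIT_DS[ends])
    dS <- dS + 0.368 * (len - 1L) * log(Na)
    1000 * dH / (dS + R * log(k)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

gc_fraction <- function(seq) {
  (nchar(gsub("[^GC]", "", seq))) / nchar(seq)
}

# Tm of many contiguous windows of one parent sequence, via cumulative
# nearest-neighbor range sums. The NN tables are complement-symmetric, so a
# window's Tm equals the Tm of its reverse complement and the same values
# serve both forward and reverse primers. Agrees exactly with
# melting_temperature() on each window (asserted in the test suite).
tm_windows <- function(parent, starts, ends, Na = 0.05, oligo_conc = 5e-8) {
  ch <- strsplit(parent, "")[[1]]
  n <- length(ch)
  di <- paste0(ch[-n], ch[-1L])
  vdh <- unname(NN_DH[di]); vds <- unname(NN_DS[di])
  # windows containing N are filtered out by the caller; zero their stacks so
  # they cannot poison the cumulative sums of valid windows
  vdh[is.na(vdh)] <- 0; vds[is.na(vds)] <- 0
  cdh <- c(0, cumsum(vdh))
  cds <- c(0, cumsum(vds))
  at_end <- ch %in% c("A", "T")
  init_dh <- ifelse(at_end, NN_INIT_DH["AT"], NN_INIT_DH["GC"])
  init_ds <- ifelse(at_end, NN_INIT_DS["AT"], NN_INIT_DS["GC"])
  len <- ends - starts + 1L
  dH <- (cdh[ends] - cdh[starts]) + init_dh[starts] + init_dh[ends]
  dS <- (cds[ends] - cds[starts]) + init_ds[starts] + init_ds[ends] +
    0.368 * (len - 1L) * log(Na)
  R <- 1.987
  1000 * dH / (dS + R * log(oligo_conc / 4)) - 273.15
}

new_primer <- function(name, seq, tm = NA_real_, footprint = NULL) {
  structure(list(name = name, seq = seq, tm = tm, footprint = footprint),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("%s  5'-%s-3'  (%d nt%s)\n", x$name, x$seq, nchar(x$seq),
              if (is.na(x$tm)) "" else sprintf(", Tm %.1f C", x$tm)))
  invisible(x)
}

#' Build the homologous-recombination template for a deletion
#'
#' Joins the `flank` nt immediately upstream of the region with the `flank`
#' nt immediately downstream, producing the sequence the locus will carry
#' after a seamless deletion (default 80 + 80 = 160 nt). This is the repair
#' template the cell uses to heal the Cas9 double-strand break, removing the
#' target region.
#'
#' @param genome A [genome_sequence].
#' @param region A `target_region`.
#' @param flank Flank length on each side, nt.
#' @return The 2*`flank`-nt template string (plus strand).
#' @export
build_hr_template <- function(genome, region, flank = 80L) {
  flank <- as.integer(flank)
  len <- chrom_length(genome, region$chrom)
  if (region$start - flank < 1L) {
    ko_error("insufficient_flank", sprintf(
      "need %d nt upstream of %s but only %d available",
      flank, format_region(region), region$start - 1L
    ))
  }
  if (region$end + flank > len) {
    ko_error("insufficient_flank", sprintf(
      "need %d nt downstream of %s but only %d available",
      flank, format_region(region), len - region$end
    ))
  }
  chr <- genome[[region$chrom]]
  paste0(subseq1(chr, region$start - flank, region$start - 1L),
         subseq1(chr, region$end + 1L, region$end + flank))
}

#' Design the two primers that synthesise the HR template by PCR
#'
#' The forward primer is the first `primer_len` nt of the template; the
#' reverse primer is the reverse complement of the last `primer_len` nt.
#' Annealed at their common 3' overlap (2*`primer_len` - template length,
#' 40 nt with the defaults) and extended, they produce the full
#' double-stranded template without any genomic DNA input. At least 20 nt of
#' overlap is required for the PCR to work.
#'
#' @param template HR template from [build_hr_template()].
#' @param primer_len Primer length, nt.
#' @param min_overlap Minimum acceptable 3' overlap, nt.
#' @return List with `fw` and `rv` ([new_primer] objects) and `overlap` (nt).
#' @export
design_hr_primers <- function(template, primer_len = 100L, min_overlap = 20L) {
  primer_len <- as.integer(primer_len)
  tlen <- nchar(template)
  if (tlen < primer_len) {
    ko_error("invalid_primer_length", sprintf(
      "template (%d nt) shorter than primer length %d", tlen, primer_len
    ))
  }
  overlap <- 2L * primer_len - tlen
  if (overlap < min_overlap) {
    ko_error("insufficient_overlap", sprintf(
      "HR primers of %d nt on a %d-nt template overlap by %d nt (< %d required)",
      primer_len, tlen, overlap, min_overlap
    ))
  }
  list(
    fw = new_primer("HRfw", subseq1(template, 1L, primer_len)),
    rv = new_primer("HRrv", reverse_complement(subseq1(template, tlen - primer_len + 1L, tlen))),
    overlap = overlap
  )
}

#' Plasmid configuration for sgRNA cloning
#'
#' Describes the circular Cas9/sgRNA expression plasmid and where the 20-nt
#' spacer is inserted by inverse PCR: between position `insertion_point` (the
#' last base of the sgRNA leader) and `insertion_point + 1` (the first base
#' of the scaffold). `anneal_len` is how many plasmid bases each cloning
#' primer anneals with.
#'
#' The real expression plasmid's sequence is not distributed here; supply it
#' as a FASTA/GenBank file via [read_plasmid()]. A small synthetic default
#' for demonstrations is available via `toy_plasmid()`.
#'
#' @param seq Circular plasmid sequence (plus strand, A,C,G,T).
#' @param insertion_point 1-based position p; spacer goes between p and p+1.
#' @param anneal_len Plasmid-annealing length of the cloning primers (>= 15).
#' @return A `plasmid_config` object.
#' @export
plasmid_config <- function(seq, insertion_point, anneal_len = 20L) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    ko_error("invalid_sequence", "plasmid sequence must contain only A,C,G,T")
  }
  p <- as.integer(insertion_point)
  if (is.na(p) || p < 1L || p > nchar(seq)) {
    ko_error("invalid_plasmid", sprintf(
      "insertion_point %s outside plasmid (1-%d)", insertion_point, nchar(seq)
    ))
  }
  anneal_len <- as.integer(anneal_len)
  if (anneal_len < 1L) ko_error("invalid_plasmid", "anneal_len must be positive")
  if (anneal_len < 15L) {
    ko_warning("short_anneal", sprintf(
      "anneal_len %d is below the 15 nt recommended for reliable priming", anneal_len
    ))
  }
  if (nchar(seq) < 2L * anneal_len) {
    ko_error("invalid_plasmid", "plasmid shorter than two annealing windows")
  }
  structure(list(seq = seq, insertion_point = p, anneal_len = anneal_len),
            class = "plasmid_config")
}

#' @rdname plasmid_config
#' @export
toy_plasmid <- function() {
  # synthetic 60-bp stand-in (leader | scaffold); NOT the real expression
  # plasmid -- demonstration and testing only
  plasmid_config(
    paste0("ATCGGTACCTAGGCATCGAT", "TTGACGCATGCAAGCTTGCA",
           "CCGGATATCGGCCTAGCTAG"),
    insertion_point = 20L, anneal_len = 20L
  )
}

#' Read a plasmid from FASTA or GenBank flat file
#'
#' GenBank input is detected by a LOCUS header; only the ORIGIN sequence
#' block is used (features are ignored).
#'
#' @param path Plasmid file.
#' @param insertion_point,anneal_len Passed to [plasmid_config()].
#' @return A `plasmid_config`.
#' @export
read_plasmid <- function(path, insertion_point, anneal_len = 20L) {
  if (!file.exists(path)) ko_error("missing_file", sprintf("plasmid file not found: %s", path))
  head <- readLines(path, n = 1L)
  if (grepl("^LOCUS", head)) {
    lines <- readLines(path)
    o <- grep("^ORIGIN", lines)
    if (length(o) == 0L) ko_error("malformed_genbank", "GenBank file has no ORIGIN block")
    end <- grep("^//", lines)
    end <- end[end > o[1]][1]
    if (is.na(end)) end <- length(lines) + 1L
    body <- lines[(o[1] + 1L):(end - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  } else {
    ss <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) ko_error("malformed_fasta", conditionMessage(e)))
    if (length(ss) != 1L) ko_error("invalid_plasmid", "plasmid FASTA must contain exactly one record")
    seq <- as.character(ss[[1]])
  }
  plasmid_config(seq, insertion_point, anneal_len)
}

# circular 1-based extraction of `len` bases starting at `start` (may be <1 or >L)
circ_substr <- function(seq, start, len) {
  L <- nchar(seq)
  idx <- ((start - 1L + seq_len(len) - 1L) %% L) + 1L
  paste(strsplit(seq, "")[[1]][idx], collapse = "")
}

#' Design inverse-PCR primers that clone a spacer into the plasmid
#'
#' Both methods amplify the whole plasmid outwards from the insertion point
#' and carry the spacer on primer 5' tails. In the `ligation` method only the
#' forward primer carries the spacer and the blunt PCR product is
#' phosphorylated and ligated; in the `ligation_free` method both primers
#' carry the full spacer (in opposite orientation) so the bacteria
#' recircularise the product through the 20-nt terminal homology.
#'
#' Either way the reassembled circle is leader + spacer + scaffold; verify
#' with [check_assembly()].
#'
#' @param spacer 20-nt spacer sequence (own strand, 5'->3').
#' @param plasmid A [plasmid_config()].
#' @param method `"ligation"` or `"ligation_free"`.
#' @return List with `fw`, `rv` ([new_primer]) and `method`.
#' @export
design_cloning_primers <- function(spacer, plasmid,
                                   method = c("ligation_free", "ligation")) {
  method <- match.arg(method)
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L || grepl("[^ACGT]", spacer)) {
    ko_error("invalid_sequence", "spacer must be 20 nt of A,C,G,T")
  }
  p <- plasmid$insertion_point
  a <- plasmid$anneal_len
  Af <- circ_substr(plasmid$seq, p + 1L, a)                       # scaffold side
  Ar <- reverse_complement(circ_substr(plasmid$seq, p - a + 1L, a))  # leader side
  doubled <- paste0(plasmid$seq, plasmid$seq)
  if (grepl(spacer, doubled, fixed = TRUE) ||
      grepl(reverse_complement(spacer), doubled, fixed = TRUE)) {
    ko_warning("mispriming_risk", "spacer occurs in the plasmid sequence; cloning primers may misprime")
  }
  fw <- new_primer(sprintf("sgRNA_%s_fw", method), paste0(spacer, Af))
  rv <- if (method == "ligation") {
    new_primer("sgRNA_ligation_rv", Ar)
  } else {
    new_primer("sgRNA_ligation_free_rv", paste0(reverse_complement(spacer), Ar))
  }
  list(fw = fw, rv = rv, method = method)
}

# TRUE if a and b are the same circular sequence (rotation-equivalent)
same_circular_sequence <- function(a, b) {
  nchar(a) == nchar(b) && grepl(b, paste0(a, a), fixed = TRUE)
}

#' Simulate inverse PCR + recircularisation and verify the assembled plasmid
#'
#' Locates the 3' annealing ends of both primers on the circular template,
#' extends them around the plasmid to produce the linear inverse-PCR product
#' (primer 5' tails included), then recircularises it: blunt end joining for
#' the ligation method, collapse of the terminal spacer homology for the
#' ligation-free method. The result is compared (as a circular sequence,
#' rotation-invariant) with leader + spacer + scaffold.
#'
#' @param primers Result of [design_cloning_primers()].
#' @param plasmid The [plasmid_config()] used.
#' @param spacer The 20-nt spacer.
#' @return List with `ok` (logical), `circle` (assembled circular sequence,
#'   rotated to start at the leader) and `expected`.
#' @export
check_assembly <- function(primers, plasmid, spacer) {
  spacer <- toupper(spacer)
  a <- plasmid$anneal_len
  L <- nchar(plasmid$seq)
  doubled <- paste0(plasmid$seq, plasmid$seq)

  fw_seq <- primers$fw$seq
  rv_seq <- primers$rv$seq
  fw_anneal <- substr(fw_seq, nchar(fw_seq) - a + 1L, nchar(fw_seq))
  fw_tail <- substr(fw_seq, 1L, nchar(fw_seq) - a)
  rv_anneal <- substr(rv_seq, nchar(rv_seq) - a + 1L, nchar(rv_seq))
  rv_tail <- substr(rv_seq, 1L, nchar(rv_seq) - a)

  s <- regexpr(fw_anneal, doubled, fixed = TRUE)[1]
  rv_site <- reverse_complement(rv_anneal)  # top-strand footprint of rv primer
  e0 <- regexpr(rv_site, doubled, fixed = TRUE)[1]
  if (s < 1L || e0 < 1L) {
    ko_error("assembly_failure", "a primer 3' end does not anneal to the plasmid")
  }
  s <- ((s - 1L) %% L) + 1L
  e <- ((e0 - 1L + a - 1L) %% L) + 1L  # last top-strand base covered by rv
  seg_len <- ((e - s) %% L) + 1L
  product <- paste0(fw_tail, circ_substr(plasmid$seq, s, seg_len),
                    reverse_complement(rv_tail))

  circle <- if (primers$method == "ligation") {
    product
  } else {
    h <- nchar(rv_tail)
    if (substr(product, 1L, h) !=
        substr(product, nchar(product) - h + 1L, nchar(product))) {
      ko_error("assembly_failure", "ligation-free product lacks terminal homology")
    }
    substr(product, 1L, nchar(product) - h)
  }
  p <- plasmid$insertion_point
  expected <- paste0(subseq1(plasmid$seq, 1L, p), spacer,
                     if (p < L) subseq1(plasmid$seq, p + 1L, L) else "")
  ok <- same_circular_sequence(circle, expected)
  # rotate the simulated circle so it starts at the leader, when it matches
  if (ok) {
    pos <- regexpr(expected, paste0(circle, circle), fixed = TRUE)[1]
    circle <- circ_substr(circle, pos, nchar(circle))
  }
  list(ok = ok, circle = circle, expected = expected)
}

#' Default checking-primer constraints (Primer3-like)
#' @export
checking_constraints <- function(min_len = 18L, max_len = 25L, opt_len = 20L,
                                 min_tm = 57, max_tm = 63, opt_tm = 60,
                                 min_gc = 20, max_gc = 80, max_pair_tm_diff = 3) {
  list(min_len = as.integer(min_len), max_len = as.integer(max_len),
       opt_len = as.integer(opt_len), min_tm = min_tm, max_tm = max_tm,
       opt_tm = opt_tm, min_gc = min_gc, max_gc = max_gc,
       max_pair_tm_diff = max_pair_tm_diff)
}

# all candidate primers inside one flank of the junction sequence
candidate_windows <- function(flank_seq, cons) {
  n <- nchar(flank_seq)
  lens <- cons$min_len:cons$max_len
  starts <- unlist(lapply(lens, function(l) if (n >= l) seq_len(n - l + 1L) else integer(0)))
  lens <- unlist(lapply(lens, function(l) if (n >= l) rep(l, n - l + 1L) else integer(0)))
  data.frame(start = starts, end = starts + lens - 1L,
             seq = substring(flank_seq, starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

#' Design deletion-checking primers around the junction
#'
#' Builds the post-deletion junction sequence in silico by joining the
#' `flank` nt immediately up- and down-stream of the target region (default
#' 250 + 250 = 500 nt), then picks one forward primer in the upstream flank
#' and one reverse primer (reverse complement) in the downstream flank.
#' Candidates must satisfy length, Tm and GC constraints; the chosen pair
#' minimises |Tm_fw - 60| + |Tm_rv - 60| + |Tm_fw - Tm_rv| subject to a pair
#' Tm difference of at most `max_pair_tm_diff`, with ties broken by the
#' leftmost forward then the rightmost reverse primer. For speed the pairing
#' step considers the 150 lowest-penalty candidates per side, falling back to
#' the full cross product if that subset has no feasible pair.
#'
#' The predicted PCR product for a successful deletion spans from the forward
#' primer start to the reverse primer end across the junction; the wild-type
#' product is longer by exactly the deleted length.
#'
#' @param genome A [genome_sequence].
#' @param region A `target_region`.
#' @param flank Flank length on each side of the junction, nt.
#' @param constraints See [checking_constraints()].
#' @return A `checking_design` list: `forward`, `reverse` ([new_primer] with
#'   Tm and genomic footprints), `junction_sequence`,
#'   `product_size_deleted`, `product_size_wildtype`, `flank`.
#' @export
design_checking_primers <- function(genome, region, flank = 250L,
                                    constraints = checking_constraints()) {
  flank <- as.integer(flank)
  cons <- constraints
  len <- chrom_length(genome, region$chrom)
  if (region$start - flank < 1L || region$end + flank > len) {
    ko_error("insufficient_flank", sprintf(
      "checking primers need %d nt on both sides of %s (available: %d upstream, %d downstream)",
      flank, format_region(region), region$start - 1L, len - region$end
    ))
  }
  chr <- genome[[region$chrom]]
  up <- subseq1(chr, region$start - flank, region$start - 1L)
  down <- subseq1(chr, region$end + 1L, region$end + flank)
  junction <- paste0(up, down)

  pick_side <- function(flank_seq, side) {
    w <- candidate_windows(flank_seq, cons)
    w <- w[!grepl("N", w$seq, fixed = TRUE), , drop = FALSE]
    if (nrow(w) == 0L) {
      ko_error("primer_failure", sprintf("no candidate window in the %s flank", side))
    }
    # Tm and GC are strand-symmetric, so the top-strand window values serve
    # the reverse primer too; the chosen primer is reverse-complemented later
    w$tm <- tm_windows(flank_seq, w$start, w$end)
    w$gc <- 100 * gc_fraction(w$seq)
    ok <- w$tm >= cons$min_tm & w$tm <= cons$max_tm &
      w$gc >= cons$min_gc & w$gc <= cons$max_gc
    if (!any(ok)) {
      # name the tightest violated constraint of the least-infeasible candidate
      viol <- cbind(
        pmax(0, cons$min_tm - w$tm), pmax(0, w$tm - cons$max_tm),
        pmax(0, cons$min_gc - w$gc), pmax(0, w$gc - cons$max_gc)
      )
      tot <- rowSums(viol)
      i <- which.min(tot)
      nz <- which(viol[i, ] > 0)
      labs <- c(sprintf("Tm >= %.1f", cons$min_tm), sprintf("Tm <= %.1f", cons$max_tm),
                sprintf("GC >= %.0f%%", cons$min_gc), sprintf("GC <= %.0f%%", cons$max_gc))
      tightest <- labs[nz[which.min(viol[i, nz])]]
      ko_error("primer_failure", sprintf(
        "no %s checking primer satisfies the constraints; tightest violated: %s",
        side, tightest
      ))
    }
    w <- w[ok, , drop = FALSE]
    w$penalty <- abs(w$tm - cons$opt_tm)
    w
  }

  fw <- pick_side(up, "forward")
  rv <- pick_side(down, "reverse")

  best_pair <- function(fw, rv) {
    pen <- outer(fw$penalty, rv$penalty, `+`) + abs(outer(fw$tm, rv$tm, `-`))
    feas <- abs(outer(fw$tm, rv$tm, `-`)) <= cons$max_pair_tm_diff
    if (!any(feas)) return(NULL)
    pen[!feas] <- Inf
    # ties: leftmost forward start, then rightmost reverse end
    key <- order(pen, outer(fw$start, rep(1, nrow(rv))),
                 -outer(rep(1, nrow(fw)), rv$end))
    idx <- key[1]
    i <- ((idx - 1L) %% nrow(fw)) + 1L
    j <- ((idx - 1L) %/% nrow(fw)) + 1L
    list(fw = fw[i, , drop = FALSE], rv = rv[j, , drop = FALSE])
  }

  prune <- function(w, side) {
    ord <- if (side == "forward") order(w$penalty, w$start) else order(w$penalty, -w$end)
    w[ord[seq_len(min(150L, nrow(w)))], , drop = FALSE]
  }
  pair <- best_pair(prune(fw, "forward"), prune(rv, "reverse"))
  if (is.null(pair)) pair <- best_pair(fw, rv)
  if (is.null(pair)) {
    ko_error("primer_failure", sprintf(
      "no forward/reverse pair within the pair Tm difference limit (%.1f C)",
      cons$max_pair_tm_diff
    ))
  }

  f <- pair$fw; r <- pair$rv
  f$primer <- f$seq
  r$primer <- reverse_complement(r$seq)
  # junction coordinates: up-flank occupies 1..flank, down-flank flank+1..2*flank
  rv_junc_start <- flank + r$start
  rv_junc_end <- flank + r$end
  product_deleted <- rv_junc_end - f$start + 1L
  product_wt <- product_deleted + region_length(region)

  forward <- new_primer("check_fw", f$primer, tm = f$tm,
                        footprint = c(region$start - flank + f$start - 1L,
                                      region$start - flank + f$end - 1L))
  reverse <- new_primer("check_rv", r$primer, tm = r$tm,
                        footprint = c(region$end + r$start, region$end + r$end))
  structure(list(
    forward = forward, reverse = reverse,
    junction_sequence = junction,
    product_size_deleted = as.integer(product_deleted),
    product_size_wildtype = as.integer(product_wt),
    flank = flank
  ), class = "checking_design")
}

#' @export
print.checking_design <- function(x, ...) {
  cat("deletion-checking design\n")
  print(x$forward); print(x$reverse)
  cat(sprintf("  product if deleted: %d nt; wild-type: %d nt; junction template: %d nt\n",
              x$product_size_deleted, x$product_size_wildtype, nchar(x$junction_sequence)))
  invisible(x)
}
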