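test_that("HR template joins the 80-nt flanks into a 160-nt repair template", {
  gA <- genome_sequence(c(c1 = strrep("A", 300)))
  reg <- parse_region("c1", 101, 200, gA)
  tpl <- build_hr_template(gA, reg)
  expect_identical(tpl, strrep("A", 160))
  expect_identical(nchar(tpl), 160L)

  # pad + P(80) + D(100) + Q(80) + pad, region = D  ->  template == P + Q
  set.seed(5)
  P <- random_dna(80); D <- random_dna(100); Q <- random_dna(80)
  g <- genome_sequence(c(c1 = paste0(strrep("T", 20), P, D, Q, strrep("T", 20))))
  regD <- parse_region("c1", 101, 200, g)
  expect_identical(build_hr_template(g, regD), paste0(P, Q))

  err <- expect_error(build_hr_template(gA, parse_region("c1", 50, 200, gA)),
                      class = "crisprko_insufficient_flank")
  expect_match(conditionMessage(err), "49")

  # round trip: deleting the region and reading across the new junction
  # reproduces the template exactly
  deleted <- paste0(substr(g[["c1"]], 1, 100), substr(g[["c1"]], 201, nchar(g[["c1"]])))
  expect_identical(substr(deleted, 101 - 80, 100 + 80), build_hr_template(g, regD))
})

test_that("HR primers are template ends with a shared 40-nt overlap", {
  set.seed(6)
  tpl <- random_dna(160)
  hr <- design_hr_primers(tpl)
  expect_identical(nchar(hr$fw$seq), 100L)
  expect_identical(nchar(hr$rv$seq), 100L)
  expect_identical(hr$overlap, 40L)
  expect_identical(hr$fw$seq, substr(tpl, 1, 100))
  expect_identical(hr$rv$seq, reverse_complement(substr(tpl, 61, 160)))
  # the overlap region is the same physical sequence in both primers
  expect_identical(substr(hr$fw$seq, 61, 100),
                   substr(reverse_complement(hr$rv$seq), 1, 40))

  expect_identical(design_hr_primers(strrep("A", 160))$rv$seq, strrep("T", 100))

  expect_error(design_hr_primers(tpl, primer_len = 80),
               class = "crisprko_insufficient_overlap")
  expect_error(design_hr_primers(random_dna(50), primer_len = 100),
               class = "crisprko_invalid_primer_length")
})

test_that("cloning primers carry the spacer on their 5' tails as specified", {
  toy <- suppressWarnings(plasmid_config(paste0("GGGGG", "TTTTT"),
                                         insertion_point = 5, anneal_len = 5))
  spacer <- strrep("A", 20)

  lf <- suppressWarnings(design_cloning_primers(spacer, toy, "ligation_free"))
  expect_identical(lf$fw$seq, paste0(spacer, "TTTTT"))
  expect_identical(lf$rv$seq, paste0(strrep("T", 20), "CCCCC"))

  lig <- suppressWarnings(design_cloning_primers(spacer, toy, "ligation"))
  expect_identical(lig$fw$seq, paste0(spacer, "TTTTT"))
  expect_identical(lig$rv$seq, "CCCCC")

  # both methods reassemble to leader + spacer + scaffold
  for (pr in list(lf, lig)) {
    chk <- check_assembly(pr, toy, spacer)
    expect_true(chk$ok)
    expect_identical(chk$circle, paste0("GGGGG", spacer, "TTTTT"))
  }

  expect_warning(plasmid_config("GGGGGTTTTT", 5, anneal_len = 5),
                 class = "crisprko_short_anneal")
  expect_error(suppressWarnings(design_cloning_primers("ACGT", toy)),
               class = "crisprko_invalid_sequence")
})

test_that("a spacer already present in the plasmid triggers a mispriming warning", {
  set.seed(41)
  pl <- plasmid_config(random_dna(80), insertion_point = 40)
  inside <- substr(pl$seq, 11, 30)
  expect_warning(design_cloning_primers(inside, pl, "ligation_free"),
                 class = "crisprko_mispriming_risk")
})

test_that("assembly holds for random spacers and plasmids, and wraps the origin", {
  set.seed(42)
  for (i in 1:25) {
    pl <- plasmid_config(random_dna(sample(60:200, 1), gc = 0.5),
                         insertion_point = sample(40:50, 1))
    sp <- random_dna(20, gc = 0.5)
    for (m in c("ligation", "ligation_free")) {
      pr <- suppressWarnings(design_cloning_primers(sp, pl, m))
      chk <- suppressWarnings(check_assembly(pr, pl, sp))
      expect_true(chk$ok)
      expect_identical(chk$circle, chk$expected)
    }
  }
  # anneal windows crossing the circular origin are taken with wraparound
  set.seed(43)
  s <- random_dna(100, gc = 0.5)
  edge <- plasmid_config(s, insertion_point = 100)  # scaffold anneal wraps to base 1
  pr <- suppressWarnings(design_cloning_primers(random_dna(20, gc = 0.5), edge))
  expect_identical(substr(pr$fw$seq, 21, 40), substr(s, 1, 20))
  edge2 <- plasmid_config(s, insertion_point = 10)  # leader anneal wraps backwards
  pr2 <- suppressWarnings(design_cloning_primers(random_dna(20, gc = 0.5), edge2))
  expect_identical(substr(pr2$rv$seq, 21, 40),
                   reverse_complement(paste0(substr(s, 91, 100), substr(s, 1, 10))))
})

test_that("melting temperatures reproduce independent reference values", {
  # frozen values from an independent implementation of the same unified
  # nearest-neighbor tables (50 mM Na+, 50 nM oligo), computed before this
  # implementation was written; first sequence is the M13F sequencing primer
  ref <- c(
    TGTAAAACGACGGCCAGT = 51.143144,
    ACGTACGTACGTACGTACGT = 53.096666,
    GCGCGCGCGCGCGCGCGCGC = 77.164352,
    ATATATATATATATATATAT = 24.192808,
    AGCTTTTCATTCTGACTGCAACG = 54.507107
  )
  for (s in names(ref)) {
    expect_equal(melting_temperature(s), unname(ref[s]), tolerance = 1e-6)
  }

  # duplex symmetry and GC monotonicity
  set.seed(8)
  for (i in 1:20) {
    s <- random_dna(sample(8:30, 1), gc = 0.5)
    expect_equal(melting_temperature(s), melting_temperature(reverse_complement(s)))
  }
  expect_gt(melting_temperature("GCGCGCGCGCGCGCGCGCGC"),
            melting_temperature("ATATATATATATATATATAT"))

  expect_error(melting_temperature("ACGTACGN"), class = "crisprko_invalid_sequence")
  expect_error(melting_temperature("ACGT"), class = "crisprko_invalid_sequence")
})

test_that("windowed Tm fast path agrees exactly with the scalar model", {
  set.seed(9)
  parent <- random_dna(400)
  starts <- sample(1:350, 40)
  ends <- pmin(starts + sample(17:24, 40, replace = TRUE), 400)
  fast <- crisprko:::tm_windows(parent, starts, ends)
  slow <- melting_temperature(substring(parent, starts, ends))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("checking primers frame the junction and predict product sizes", {
  sg <- synth_genome(c(cA = 2000L), seed = 77, gc = 0.5)
  g <- sg$genome
  reg <- parse_region("cA", 901, 1100, g)
  chk <- design_checking_primers(g, reg)

  expect_identical(nchar(chk$junction_sequence), 500L)
  expect_identical(chk$product_size_wildtype - chk$product_size_deleted,
                   region_length(reg))
  expect_lte(chk$product_size_deleted, 500L)

  # both primers are exact genomic substrings outside the deleted interval
  fw <- chk$forward; rv <- chk$reverse
  expect_identical(substring(g[["cA"]], fw$footprint[1], fw$footprint[2]), fw$seq)
  expect_identical(reverse_complement(
    substring(g[["cA"]], rv$footprint[1], rv$footprint[2])), rv$seq)
  expect_lt(fw$footprint[2], reg$start)
  expect_gt(rv$footprint[1], reg$end)

  # constraints honoured
  for (p in list(fw, rv)) {
    expect_gte(p$tm, 57); expect_lte(p$tm, 63)
    expect_gte(nchar(p$seq), 18L); expect_lte(nchar(p$seq), 25L)
  }
  expect_lte(abs(fw$tm - rv$tm), 3)

  # junction sequence is exactly up-flank + down-flank
  expect_identical(chk$junction_sequence,
                   paste0(substring(g[["cA"]], 651, 900), substring(g[["cA"]], 1101, 1350)))

  # infeasible side is named along with the tightest violated constraint
  gBad <- genome_sequence(c(c1 = strrep("A", 2000)))
  err <- expect_error(design_checking_primers(gBad, parse_region("c1", 901, 1100, gBad)),
                      class = "crisprko_primer_failure")
  expect_match(conditionMessage(err), "forward")
  expect_match(conditionMessage(err), "Tm")

  err2 <- expect_error(
    design_checking_primers(g, parse_region("cA", 100, 1900, g)),
    class = "crisprko_insufficient_flank"
  )
  expect_match(conditionMessage(err2), "99")
})

test_that("plasmid files are read from FASTA and GenBank", {
  set.seed(12)
  s <- random_dna(120, gc = 0.5)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">pl", s), fa)
  expect_identical(read_plasmid(fa, 60)$seq, s)

  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       pl_demo       120 bp    DNA     circular SYN",
    "DEFINITION  synthetic test plasmid.",
    "FEATURES             Location/Qualifiers",
    "ORIGIN",
    paste("        1", tolower(paste(substring(s, seq(1, 60, 10), seq(10, 60, 10)), collapse = " "))),
    paste("       61", tolower(paste(substring(s, seq(61, 120, 10), seq(70, 120, 10)), collapse = " "))),
    "//"
  ), gb)
  expect_identical(read_plasmid(gb, 60)$seq, s)
  expect_error(read_plasmid(tempfile(), 1), class = "crisprko_missing_file")
})
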