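test_that("gene-name and coordinate input paths produce the same design", {
  g <- read_genome(demo_file("genome.fa"))
  ann <- read_annotation(demo_file("annotation.gff3"))
  idx <- build_index(scan_pams(g), g)

  by_gene <- suppressWarnings(
    design_deletion(g, resolve_gene("SPNCRNA.01", ann, g), index = idx))
  by_coord <- suppressWarnings(
    design_deletion(g, parse_region("II", 901, 1500, g), index = idx))

  a <- as_design_list(by_gene); b <- as_design_list(by_coord)
  a$target$label <- b$target$label  # labels differ by construction
  expect_identical(a, b)
})

test_that("the design report is internally consistent", {
  g <- read_genome(demo_file("genome.fa"))
  idx <- build_index(scan_pams(g), g)
  reg <- parse_region("I", 601, 1400, g)
  d <- suppressWarnings(design_deletion(g, reg, index = idx))

  expect_identical(nchar(d$hr_template), 160L)
  expect_identical(d$checking$product_size_wildtype - d$checking$product_size_deleted,
                   region_length(reg))
  # HR round trip across the deletion junction
  chr <- g[["I"]]
  deleted <- paste0(substr(chr, 1, 600), substr(chr, 1401, nchar(chr)))
  expect_identical(substr(deleted, 601 - 80, 600 + 80), d$hr_template)

  # cloning primer sets exist for both methods and reassemble correctly
  for (cl in d$cloning) {
    expect_setequal(names(cl$primer_sets), c("ligation", "ligation_free"))
    for (m in names(cl$primer_sets)) {
      chk <- check_assembly(cl$primer_sets[[m]], toy_plasmid(), cl$spacer)
      expect_true(chk$ok)
    }
  }

  # all sequences in the JSON document round-trip byte-identically
  doc <- as_design_list(d)
  path <- tempfile(fileext = ".json")
  write_design_json(d, path)
  back <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(back$hr$template, d$hr_template)
  expect_identical(back$checking$junction_sequence, d$checking$junction_sequence)
  expect_identical(back$sgrnas[[1]]$spacer, doc$sgrnas[[1]]$spacer)
})

test_that("JSON output is byte-identical across runs and agrees with the TSVs", {
  g <- read_genome(demo_file("genome.fa"))
  idx <- build_index(scan_pams(g), g)
  reg <- parse_region("II", 901, 1500, g)

  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  d1 <- suppressWarnings(design_deletion(g, reg, index = idx))
  d2 <- suppressWarnings(design_deletion(g, reg, index = idx))
  write_design_json(d1, p1); write_design_json(d2, p2)
  expect_identical(readLines(p1), readLines(p2))

  prefix <- tempfile()
  write_design_tsv(d1, prefix)
  sg_tab <- utils::read.table(paste0(prefix, "_sgrnas.tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  doc <- jsonlite::fromJSON(p1, simplifyVector = FALSE)
  expect_identical(sg_tab$spacer,
                   vapply(doc$sgrnas, function(x) x$spacer, character(1)))
  expect_identical(sg_tab$cut_position,
                   vapply(doc$sgrnas, function(x) as.integer(x$cut_position), integer(1)))

  primers <- utils::read.table(paste0(prefix, "_primers.tsv"), sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  expect_identical(primers$sequence[primers$name == "check_fw"], doc$checking$fw$seq)
  expect_identical(primers$sequence[primers$name == "HRfw"], doc$hr$fw$seq)

  # order sheet renders the same primers in lowercase
  sheet <- utils::read.table(paste0(prefix, "_order_sheet.tsv"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  expect_identical(sheet$sequence, tolower(primers$sequence))
})

test_that("cli_main maps error families to distinct exit codes", {
  expect_identical(cli_main(character(0)), 2L)
  expect_identical(cli_main(c("design", "--genome", demo_file("genome.fa"))), 2L)
  expect_identical(cli_main(c("design", "--genome", tempfile(),
                              "--chrom", "I", "--start", "601", "--end", "1400")), 3L)
  expect_identical(cli_main(c("design", "--genome", demo_file("genome.fa"),
                              "--gff", demo_file("annotation.gff3"),
                              "--gene", "nosuchgene")), 6L)
  expect_identical(cli_main(c("design", "--genome", demo_file("genome.fa"),
                              "--chrom", "IV", "--start", "1", "--end", "100")), 5L)
  expect_identical(cli_main(c("frobnicate")), 2L)
})

test_that("cli design/sgrna/index/primers subcommands run end to end", {
  genome_fa <- demo_file("genome.fa")
  out <- tempfile()
  code <- cli_main(c("design", "--genome", genome_fa,
                     "--chrom", "II", "--start", "901", "--end", "1500",
                     "--out", out, "--format", "both"))
  expect_identical(code, 0L)
  expect_true(file.exists(paste0(out, ".json")))
  expect_true(file.exists(paste0(out, "_sgrnas.tsv")))
  doc <- jsonlite::fromJSON(paste0(out, ".json"), simplifyVector = FALSE)
  expect_identical(doc$target$chrom, "II")
  expect_identical(doc$hr$template_length, 160L)

  # same invocation twice: byte-identical report
  out2 <- tempfile()
  cli_main(c("design", "--genome", genome_fa, "--chrom", "II",
             "--start", "901", "--end", "1500", "--out", out2, "--format", "json"))
  expect_identical(readLines(paste0(out, ".json")), readLines(paste0(out2, ".json")))

  # gene path through the CLI equals the coordinate path
  out3 <- tempfile()
  code3 <- cli_main(c("design", "--genome", genome_fa,
                      "--gff", demo_file("annotation.gff3"),
                      "--gene", "SPNCRNA.01", "--out", out3, "--format", "json"))
  expect_identical(code3, 0L)
  j1 <- jsonlite::fromJSON(paste0(out, ".json"), simplifyVector = FALSE)
  j3 <- jsonlite::fromJSON(paste0(out3, ".json"), simplifyVector = FALSE)
  j3$target$label <- j1$target$label
  expect_identical(j1, j3)

  # index build + reuse, and stale-cache refusal
  cache <- tempfile(fileext = ".jsonl")
  expect_identical(cli_main(c("index", "build", "--genome", genome_fa,
                              "--index-cache", cache)), 0L)
  expect_true(file.exists(cache))
  g <- read_genome(genome_fa)
  expect_s3_class(load_index(cache, g), "sgrna_index")
  other <- genome_sequence(c(I = strrep("ACGT", 100)))
  expect_error(load_index(cache, other), class = "crisprko_stale_index")

  out4 <- tempfile()
  expect_identical(cli_main(c("sgrna", "--genome", genome_fa,
                              "--chrom", "II", "--start", "901", "--end", "1500",
                              "--index-cache", cache,
                              "--out", out4, "--format", "tsv")), 0L)
  tab <- utils::read.table(paste0(out4, ".tsv"), sep = "\t", header = TRUE)
  expect_true(all(tab$k20 == 1L))

  out5 <- tempfile()
  expect_identical(cli_main(c("primers", "check", "--genome", genome_fa,
                              "--chrom", "II", "--start", "901", "--end", "1500",
                              "--out", out5)), 0L)
  chk <- jsonlite::fromJSON(paste0(out5, ".json"), simplifyVector = FALSE)
  expect_identical(chk$checking$product_size_wildtype - chk$checking$product_size_deleted,
                   600L)
})

test_that("config files supply defaults that explicit flags override", {
  genome_fa <- demo_file("genome.fa")
  cfg <- tempfile(fileext = ".conf")
  writeLines(c("chrom=II", "start=901", "end=1500", "check-flank=200"), cfg)
  out <- tempfile()
  expect_identical(cli_main(c("primers", "check", "--genome", genome_fa,
                              "--config", cfg, "--out", out)), 0L)
  doc <- jsonlite::fromJSON(paste0(out, ".json"), simplifyVector = FALSE)
  expect_identical(nchar(doc$checking$junction_sequence), 400L)

  # flag on the command line wins over the config value
  out2 <- tempfile()
  expect_identical(cli_main(c("primers", "check", "--genome", genome_fa,
                              "--config", cfg, "--check-flank", "250",
                              "--out", out2)), 0L)
  doc2 <- jsonlite::fromJSON(paste0(out2, ".json"), simplifyVector = FALSE)
  expect_identical(nchar(doc2$checking$junction_sequence), 500L)

  # YAML config equivalent
  ycfg <- tempfile(fileext = ".yaml")
  writeLines(c("chrom: II", "start: 901", "end: 1500", "check-flank: 200"), ycfg)
  out3 <- tempfile()
  expect_identical(cli_main(c("primers", "check", "--genome", genome_fa,
                              "--config", ycfg, "--out", out3)), 0L)
  doc3 <- jsonlite::fromJSON(paste0(out3, ".json"), simplifyVector = FALSE)
  expect_identical(doc3$checking, doc$checking)
})
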