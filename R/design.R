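#' Full seamless-deletion design for a target region
#'
#' Runs the whole pipeline: enumerate and rank genome-unique sgRNAs in the
#' region, design plasmid cloning primers for the top candidates (both
#' cloning methods), build the HR template and its two synthesis primers,
#' and pick junction-checking primers with predicted product sizes. The
#' pipeline is fully deterministic: the same inputs always give the same
#' design.
#'
#' Fewer than two usable sgRNAs triggers a warning (two independent guides
#' per deletion are recommended) but not an error.
#'
#' @param genome A [genome_sequence].
#' @param region A `target_region`.
#' @param index `sgrna_index` for this genome; built on the fly when NULL.
#' @param plasmid A [plasmid_config()] (default: the synthetic demo plasmid).
#' @param hr_flank HR-template flank, nt per side.
#' @param hr_primer_len HR synthesis primer length, nt.
#' @param check_flank Checking-primer flank, nt per side.
#' @param mode sgRNA containment mode (see [enumerate_candidates()]).
#' @param methods Cloning method(s) to design primers for.
#' @param top_n How many top-ranked sgRNAs get cloning primers.
#' @param constraints Checking-primer constraints ([checking_constraints()]).
#' @return A `deletion_design` object.
#' @export
design_deletion <- function(genome, region, index = NULL,
                            plasmid = toy_plasmid(),
                            hr_flank = 80L, hr_primer_len = 100L,
                            check_flank = 250L,
                            mode = c("contain", "overhang"),
                            methods = c("ligation", "ligation_free"),
                            top_n = 2L,
                            constraints = checking_constraints()) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, c("ligation", "ligation_free"), several.ok = TRUE)
  if (is.null(index)) index <- build_index(scan_pams(genome), genome)

  candidates <- enumerate_candidates(region, genome, index, mode = mode)
  if (nrow(candidates) < 2L) {
    ko_warning("few_candidates", sprintf(
      "only %d usable sgRNA(s) in %s; at least two independent guides per deletion are recommended",
      nrow(candidates), format_region(region)
    ))
  }
  top <- candidates[seq_len(min(top_n, nrow(candidates))), , drop = FALSE]
  cloning <- lapply(seq_len(nrow(top)), function(i) {
    sets <- lapply(methods, function(m) {
      design_cloning_primers(top$spacer[i], plasmid, method = m)
    })
    names(sets) <- methods
    list(rank = top$rank[i], spacer = top$spacer[i], primer_sets = sets)
  })

  template <- build_hr_template(genome, region, flank = hr_flank)
  hr <- design_hr_primers(template, primer_len = hr_primer_len)
  checking <- design_checking_primers(genome, region, flank = check_flank,
                                      constraints = constraints)

  structure(list(
    target = region,
    candidates = candidates,
    top_n = as.integer(top_n),
    cloning = cloning,
    hr_template = template,
    hr_primers = hr,
    checking = checking,
    parameters = list(hr_flank = as.integer(hr_flank),
                      hr_primer_len = as.integer(hr_primer_len),
                      check_flank = as.integer(check_flank),
                      mode = mode, methods = methods)
  ), class = "deletion_design")
}

#' @export
print.deletion_design <- function(x, ...) {
  cat(sprintf("deletion design for %s (%d nt)\n", x$target$label, region_length(x$target)))
  cat(sprintf("  %d genome-unique sgRNA candidate(s); top %d with cloning primers\n",
              nrow(x$candidates), length(x$cloning)))
  if (nrow(x$candidates) > 0) {
    show <- utils::head(x$candidates[, c("rank", "strand", "spacer", "pam",
                                         "spacer_start", "cut_position", "seed_unique",
                                         paste0("k", SIMILARITY_KS))], length(x$cloning))
    print.data.frame(show, row.names = FALSE)
  }
  cat(sprintf("  HR template: %d nt; HR primers %d nt each, %d nt overlap\n",
              nchar(x$hr_template), nchar(x$hr_primers$fw$seq), x$hr_primers$overlap))
  print(x$checking)
  invisible(x)
}

primer_to_list <- function(p) {
  out <- list(name = p$name, seq = p$seq, length = nchar(p$seq))
  if (!is.na(p$tm)) out$tm_celsius <- p$tm
  if (!is.null(p$footprint)) out$footprint <- list(start = p$footprint[1], end = p$footprint[2])
  out
}

#' Convert a deletion design to a plain list (the JSON document)
#' @param design A `deletion_design`.
#' @return A nested list mirroring the JSON report, coordinates 1-based inclusive.
#' @export
as_design_list <- function(design) {
  cand <- design$candidates
  list(
    target = list(chrom = design$target$chrom, start = design$target$start,
                  end = design$target$end, label = design$target$label,
                  length = region_length(design$target)),
    parameters = design$parameters,
    sgrnas = lapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, ]
      list(rank = r$rank, chrom = r$chrom, strand = r$strand,
           spacer = r$spacer, pam = r$pam,
           spacer_start = r$spacer_start, spacer_end = r$spacer_end,
           pam_start = r$pam_start, pam_end = r$pam_end,
           cut_position = r$cut_position,
           mutable_window = list(start = r$mut_start, end = r$mut_end),
           seed_unique = r$seed_unique,
           similarity = as.list(stats::setNames(
             as.integer(unlist(r[paste0("k", SIMILARITY_KS)])),
             paste0("k", SIMILARITY_KS)
           )))
    }),
    cloning = lapply(design$cloning, function(cl) {
      list(rank = cl$rank, spacer = cl$spacer,
           methods = lapply(cl$primer_sets, function(ps) {
             list(fw = primer_to_list(ps$fw), rv = primer_to_list(ps$rv))
           }))
    }),
    hr = list(template = design$hr_template,
              template_length = nchar(design$hr_template),
              fw = primer_to_list(design$hr_primers$fw),
              rv = primer_to_list(design$hr_primers$rv),
              overlap = design$hr_primers$overlap),
    checking = list(
      fw = primer_to_list(design$checking$forward),
      rv = primer_to_list(design$checking$reverse),
      junction_sequence = design$checking$junction_sequence,
      product_size_deleted = design$checking$product_size_deleted,
      product_size_wildtype = design$checking$product_size_wildtype
    )
  )
}

#' Write the design report
#'
#' `write_design_json()` writes one JSON document (byte-stable across runs).
#' `write_design_tsv()` writes three TSVs sharing the prefix:
#' `<prefix>_sgrnas.tsv` (the ranked candidate table),
#' `<prefix>_primers.tsv` (every primer with length/Tm/product sizes) and
#' `<prefix>_order_sheet.tsv` (IDT-style name + lowercase sequence).
#'
#' @param design A `deletion_design`.
#' @param path,prefix Output location.
#' @return The path(s) written, invisibly.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(as_design_list(design), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design_json
#' @export
write_design_tsv <- function(design, prefix) {
  cand <- design$candidates
  keep <- c("rank", "chrom", "strand", "spacer", "pam", "spacer_start",
            "spacer_end", "pam_start", "pam_end", "cut_position",
            "seed_unique", paste0("k", SIMILARITY_KS), "mut_start", "mut_end")
  p_sg <- paste0(prefix, "_sgrnas.tsv")
  utils::write.table(cand[, keep, drop = FALSE], p_sg, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  primer_rows <- design_primer_table(design)
  p_pr <- paste0(prefix, "_primers.tsv")
  utils::write.table(primer_rows, p_pr, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")

  order_sheet <- data.frame(name = primer_rows$name,
                            sequence = tolower(primer_rows$sequence),
                            stringsAsFactors = FALSE)
  p_os <- paste0(prefix, "_order_sheet.tsv")
  utils::write.table(order_sheet, p_os, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p_sg, p_pr, p_os))
}

# one row per primer in the design, shared by the TSV writer and tests
design_primer_table <- function(design) {
  rows <- list()
  add <- function(name, seq, tm = NA_real_, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, sequence = seq, length = nchar(seq), tm_celsius = tm,
      note = note, stringsAsFactors = FALSE
    )
  }
  for (cl in design$cloning) {
    for (m in names(cl$primer_sets)) {
      ps <- cl$primer_sets[[m]]
      add(sprintf("sg%d_%s", cl$rank, ps$fw$name), ps$fw$seq,
          note = sprintf("sgRNA rank %d, %s", cl$rank, m))
      add(sprintf("sg%d_%s", cl$rank, ps$rv$name), ps$rv$seq,
          note = sprintf("sgRNA rank %d, %s", cl$rank, m))
    }
  }
  add("HRfw", design$hr_primers$fw$seq,
      note = sprintf("HR synthesis, %d nt overlap", design$hr_primers$overlap))
  add("HRrv", design$hr_primers$rv$seq,
      note = sprintf("HR synthesis, %d nt overlap", design$hr_primers$overlap))
  add("check_fw", design$checking$forward$seq, tm = design$checking$forward$tm,
      note = sprintf("deletion product %d nt, wild-type %d nt",
                     design$checking$product_size_deleted,
                     design$checking$product_size_wildtype))
  add("check_rv", design$checking$reverse$seq, tm = design$checking$reverse$tm,
      note = sprintf("deletion product %d nt, wild-type %d nt",
                     design$checking$product_size_deleted,
                     design$checking$product_size_wildtype))
  do.call(rbind, rows)
}
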