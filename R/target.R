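#' Target region to delete
#'
#' Validates a chromosome + 1-based inclusive interval against the genome.
#' If `start > end` the bounds are swapped with a warning (class
#' `crisprko_swapped_coordinates`). Regions are always expressed on the plus
#' strand regardless of any gene's orientation.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @param genome A [genome_sequence].
#' @param label Free-text label; defaults to `"chrom:start-end"`.
#' @return A `target_region` list with fields `chrom`, `start`, `end`, `label`.
#' @examples
#' g <- genome_sequence(c(I = strrep("ACGT", 10)))
#' parse_region("I", 5, 20, g)
#' @export
parse_region <- function(chrom, start, end, genome, label = NULL) {
  if (!chrom %in% names(genome)) {
    ko_error("unknown_chromosome", sprintf(
      "unknown chromosome '%s'; genome has: %s",
      chrom, paste(names(genome), collapse = ", ")
    ))
  }
  start <- as.integer(start); end <- as.integer(end)
  if (anyNA(c(start, end))) {
    ko_error("invalid_region", "start and end must be integers")
  }
  if (start > end) {
    ko_warning("swapped_coordinates", sprintf(
      "start (%d) > end (%d); coordinates swapped", start, end
    ))
    tmp <- start; start <- end; end <- tmp
  }
  len <- chrom_length(genome, chrom)
  if (start < 1L || end > len) {
    ko_error("invalid_region", sprintf(
      "coordinates %d-%d outside chromosome '%s' (valid range 1-%d)",
      start, end, chrom, len
    ))
  }
  structure(list(
    chrom = chrom, start = start, end = end,
    label = label %||% sprintf("%s:%d-%d", chrom, start, end)
  ), class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("target_region %s (%s:%d-%d, %d nt)\n",
              x$label, x$chrom, x$start, x$end, region_length(x)))
  invisible(x)
}

#' @rdname parse_region
#' @param region A `target_region`.
#' @export
region_length <- function(region) region$end - region$start + 1L

#' Format / parse the "chrom:start-end" region string
#' @param region A `target_region`.
#' @return `format_region`: a string; `parse_region_string`: a `target_region`.
#' @export
format_region <- function(region) sprintf("%s:%d-%d", region$chrom, region$start, region$end)

#' @rdname format_region
#' @param s Region string like `"II:1500340-1501528"`.
#' @param genome A [genome_sequence].
#' @export
parse_region_string <- function(s, genome) {
  m <- regmatches(s, regexec("^(.+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4L) {
    ko_error("invalid_region", sprintf("cannot parse region string '%s' (expected chrom:start-end)", s))
  }
  parse_region(m[2], as.integer(m[3]), as.integer(m[4]), genome)
}

#' Read gene annotation for gene-name target lookup
#'
#' Reads a GFF3 file (via [rtracklayer::import]) and reduces it to one record
#' per gene: chromosome, span, strand and the searchable identifiers (ID,
#' Name, comma-split synonyms). For coding genes the span is the union CDS
#' span across all transcripts (CDS features linked to the gene through
#' Parent attributes); genes without CDS keep their gene-feature span.
#'
#' A two-column TSV fallback (`id<TAB>chrom:start-end`, no header) is also
#' accepted and detected by file content.
#'
#' @param path GFF3 (or two-column TSV) annotation file.
#' @return A `gene_annotation` data frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `names` (list column of searchable aliases).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) ko_error("missing_file", sprintf("annotation file not found: %s", path))
  first <- readLines(path, n = 50L)
  first <- first[nzchar(first)]
  if (!any(grepl("^##gff", first)) && all(!grepl("\t.*\t", first[!grepl("^#", first)]))) {
    return(read_annotation_tsv(path))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) ko_error("malformed_gff3", conditionMessage(e))
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  genes <- df[df$type %in% c("gene", "ncRNA_gene", "pseudogene"), , drop = FALSE]
  if (nrow(genes) == 0L) ko_error("malformed_gff3", "annotation contains no gene features")

  # map CDS -> gene through Parent chains (CDS -> mRNA -> gene, or CDS -> gene)
  parent_of <- function(p) vapply(p, function(v) if (length(v)) v[[1]] else NA_character_, character(1))
  df$parent1 <- if ("Parent" %in% names(df)) parent_of(df$Parent) else NA_character_
  id_of <- df$ID
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_gene <- stats::setNames(tx$parent1, tx$ID)
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) > 0L) {
    gene_hit <- ifelse(cds$parent1 %in% genes$ID, cds$parent1,
                       unname(tx_gene[cds$parent1]))
    cds$gene <- gene_hit
    cds <- cds[!is.na(cds$gene), , drop = FALSE]
  }
  span <- function(g) {
    if (nrow(cds) > 0L) {
      hit <- cds[cds$gene == g$ID, , drop = FALSE]
      if (nrow(hit) > 0L) return(c(min(hit$start), max(hit$end)))
    }
    c(g$start, g$end)
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    sp <- span(g)
    aliases <- g$ID
    if ("Name" %in% names(g) && !is.na(g$Name)) aliases <- c(aliases, g$Name)
    for (col in c("synonyms", "Synonyms", "synonym", "Alias")) {
      if (col %in% names(genes)) {
        v <- genes[[col]][i]
        v <- if (is.list(v)) unlist(v) else v
        if (length(v) && !all(is.na(v))) {
          aliases <- c(aliases, unlist(strsplit(stats::na.omit(v), ",", fixed = TRUE)))
        }
      }
    }
    data.frame(
      gene_id = g$ID, chrom = as.character(g$seqnames),
      start = sp[1], end = sp[2], strand = as.character(g$strand),
      names = I(list(unique(trimws(aliases)))), stringsAsFactors = FALSE
    )
  })
  ann <- do.call(rbind, rows)
  validate_annotation(ann)
}

read_annotation_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene_id", "span"),
                           stringsAsFactors = FALSE, comment.char = "#")
  m <- regmatches(tab$span, regexec("^(.+):([0-9]+)-([0-9]+)$", tab$span))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    ko_error("malformed_annotation", sprintf(
      "TSV line %d: span '%s' is not chrom:start-end", which(bad)[1], tab$span[which(bad)[1]]
    ))
  }
  ann <- data.frame(
    gene_id = tab$gene_id,
    chrom = vapply(m, `[`, character(1), 2),
    start = as.integer(vapply(m, `[`, character(1), 3)),
    end = as.integer(vapply(m, `[`, character(1), 4)),
    strand = "*",
    names = I(as.list(tab$gene_id)), stringsAsFactors = FALSE
  )
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  keys <- tolower(ann$gene_id)
  if (anyDuplicated(keys)) {
    ko_error("malformed_annotation", sprintf(
      "duplicate gene identifier(s) after case-folding: %s",
      paste(unique(ann$gene_id[duplicated(keys)]), collapse = ", ")
    ))
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Resolve a gene name to the region it spans
#'
#' Case-insensitive match against each gene's ID, Name and synonyms. For
#' coding genes the region is the union CDS span; non-coding genes use the
#' gene-feature span (both precomputed by [read_annotation()]). An unknown
#' name fails with the closest identifiers (edit distance) in the message.
#'
#' @param name Gene identifier or primary name (e.g. a systematic ID).
#' @param annotation A `gene_annotation` from [read_annotation()].
#' @param genome A [genome_sequence].
#' @return A `target_region` labelled with the gene name.
#' @export
resolve_gene <- function(name, annotation, genome) {
  key <- tolower(trimws(name))
  hit <- which(vapply(annotation$names, function(al) key %in% tolower(al), logical(1)))
  if (length(hit) == 0L) {
    all_names <- unique(unlist(annotation$names))
    d <- utils::adist(key, tolower(all_names))[1, ]
    near <- all_names[order(d)][seq_len(min(3L, length(all_names)))]
    ko_error("unknown_gene", sprintf(
      "unknown gene '%s'; closest identifiers: %s", name, paste(near, collapse = ", ")
    ))
  }
  if (length(hit) > 1L) {
    ko_error("ambiguous_gene", sprintf(
      "name '%s' matches multiple genes: %s", name,
      paste(annotation$gene_id[hit], collapse = ", ")
    ))
  }
  rec <- annotation[hit, , drop = FALSE]
  parse_region(rec$chrom, rec$start, rec$end, genome, label = name)
}
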