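#' Read an ortholog count matrix and its sample sheet
#'
#' The count table is a TSV with columns `gene_id`, `length_bp`, then one
#' integer column per sample; the sample sheet is a TSV with columns
#' `sample_id`, `species`, `tissue` (and optionally `role`). Sample columns are
#' validated against, and reordered to, the sample sheet.
#'
#' @param path path to the count TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return list with `counts` (tibble) and `samples` (tibble).
#' @export
read_counts <- function(path, sample_sheet_path) {
  samples <- read_sample_sheet(sample_sheet_path)
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(counts))) {
    abort(paste0(path, ": count table must start with gene_id and length_bp columns"))
  }
  have <- value_cols(counts)
  missing_samples <- setdiff(samples$sample_id, have)
  if (length(missing_samples) > 0) {
    abort(paste0(path, ": sample(s) in sheet absent from count table: ",
                 paste(missing_samples, collapse = ", ")))
  }
  unknown <- setdiff(have, samples$sample_id)
  if (length(unknown) > 0) {
    abort(paste0(path, ": count column(s) not in sample sheet: ",
                 paste(unknown, collapse = ", ")))
  }
  dup <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup) > 0) {
    abort(paste0(path, ": duplicated gene_id: ", paste(unique(dup), collapse = ", ")))
  }
  m <- as_gene_matrix(counts)
  bad <- which(m < 0 | m != round(m) | is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("%s: negative or non-integer count at line %d (gene %s, sample %s)",
                  path, bad[1, 1] + 1L, counts$gene_id[bad[1, 1]],
                  colnames(m)[bad[1, 2]]))
  }
  counts <- counts[c("gene_id", "length_bp", samples$sample_id)]
  assert_counts_tbl(counts)
  list(counts = counts, samples = samples)
}

#' @rdname read_counts
#' @param counts count tibble as produced by [simulate_expression()] or
#'   [read_counts()].
#' @export
write_counts <- function(counts, path) {
  assert_counts_tbl(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname read_counts
#' @export
read_sample_sheet <- function(sample_sheet_path) {
  samples <- readr::read_tsv(sample_sheet_path, show_col_types = FALSE, progress = FALSE)
  assert_sample_sheet(samples)
  samples
}

#' Read a gene annotation from GFF3 or BED12
#'
#' GFF3 input must carry a gene/mRNA/exon (or gene/transcript/exon) hierarchy;
#' BED12 input uses blocks as exons. External 1-based closed (GFF3) or 0-based
#' (BED) coordinates are converted to the package-wide internal convention:
#' 0-based half-open for every interval. The strand-aware promoter (the 1000 bp
#' immediately upstream of the TSS) and intron intervals are derived.
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @param promoter_size promoter length in bp upstream of the TSS.
#' @return annotation tibble: gene_id, chrom, strand, start, end, tss,
#'   promoter_start, promoter_end, and an `exons` list-column of tibbles with
#'   0-based half-open `start`, `end`.
#' @export
read_annotation <- function(path, promoter_size = 1000L) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("gff3", "gff")) {
    gr <- rtracklayer::import(path, format = "gff3")
    parse_gff3_genes(gr)
  } else if (ext %in% c("bed", "bed12")) {
    gr <- rtracklayer::import(path, format = "bed")
    parse_bed12_genes(gr)
  } else {
    abort(paste0(path, ": unsupported annotation format '", ext, "'"))
  }
  finalize_annotation(raw, promoter_size)
}

parse_gff3_genes <- function(gr) {
  type <- as.character(gr$type)
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    id = as.character(gr$ID),
    parent = vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  )
  genes <- df[df$type == "gene", ]
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  exons <- df[df$type == "exon", ]
  if (nrow(genes) == 0) abort("GFF3 contains no gene features")
  tx_gene <- setNames(tx$parent, tx$id)
  exons$gene <- tx_gene[exons$parent]
  exons$gene[is.na(exons$gene)] <- exons$parent[is.na(exons$gene)]
  purrr::pmap(
    list(genes$id, genes$chrom, genes$strand, genes$start, genes$end),
    function(id, chrom, strand, start, end) {
      ex <- exons[!is.na(exons$gene) & exons$gene == id, c("start", "end")]
      if (nrow(ex) == 0) ex <- tibble(start = start, end = end)
      list(gene_id = id, chrom = chrom, strand = strand, start = start,
           end = end, exons = as_tibble(ex))
    }
  )
}

parse_bed12_genes <- function(gr) {
  purrr::map(seq_along(gr), function(i) {
    x <- gr[i]
    start <- GenomicRanges::start(x) - 1L
    blocks <- x$blocks[[1]]
    ex_start <- start + GenomicRanges::start(blocks) - 1L
    ex_end <- start + GenomicRanges::end(blocks)
    ex <- tibble(start = ex_start, end = ex_end)
    list(gene_id = as.character(x$name), chrom = as.character(GenomicRanges::seqnames(x)),
         strand = as.character(GenomicRanges::strand(x)),
         start = start, end = GenomicRanges::end(x), exons = ex)
  })
}

finalize_annotation <- function(records, promoter_size) {
  rows <- purrr::map(records, function(r) {
    if (!r$strand %in% c("+", "-")) {
      abort(paste0("gene ", r$gene_id, ": unknown strand '", r$strand, "'"))
    }
    ex <- arrange(r$exons, .data$start)
    if (any(ex$start < r$start | ex$end > r$end)) {
      abort(paste0("gene ", r$gene_id, ": exon outside gene span"))
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(paste0("gene ", r$gene_id, ": overlapping exons"))
    }
    tss <- if (r$strand == "+") r$start else r$end - 1L
    prom <- promoter_interval(tss, r$strand, promoter_size)
    tibble(gene_id = r$gene_id, chrom = r$chrom, strand = r$strand,
           start = as.integer(r$start), end = as.integer(r$end),
           tss = as.integer(tss),
           promoter_start = as.integer(prom[1]), promoter_end = as.integer(prom[2]),
           exons = list(mutate(ex, across(c("start", "end"), as.integer))))
  })
  bind_rows(rows) |> arrange(.data$chrom, .data$start)
}

#' Derived element intervals of an annotation
#'
#' @param annotation tibble from [read_annotation()].
#' @return tibble of 0-based half-open intervals with columns gene_id, element
#'   (promoter/gene/exon/intron), chrom, start, end. Single-exon genes
#'   contribute no introns; promoters running past the chromosome start are
#'   truncated at 0.
#' @export
annotation_elements <- function(annotation) {
  per_gene <- purrr::pmap(
    annotation[c("gene_id", "chrom", "start", "end",
                 "promoter_start", "promoter_end", "exons")],
    function(gene_id, chrom, start, end, promoter_start, promoter_end, exons) {
      ex <- arrange(exons, .data$start)
      introns <- tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
      introns <- introns[introns$end > introns$start, , drop = FALSE]
      bind_rows(
        tibble(element = "promoter", start = max(0L, promoter_start), end = promoter_end),
        tibble(element = "gene", start = start, end = end),
        tibble(element = "exon", start = ex$start, end = ex$end),
        if (nrow(introns) > 0) tibble(element = "intron", start = introns$start,
                                      end = introns$end)
      ) |> mutate(gene_id = gene_id, chrom = chrom)
    }
  )
  bind_rows(per_gene) |> select("gene_id", "element", "chrom", "start", "end")
}

#' @rdname read_annotation
#' @param annotation annotation tibble.
#' @param format `"gff3"` or `"bed12"`.
#' @export
write_annotation <- function(annotation, path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "gff3") {
    lines <- "##gff-version 3"
    for (i in seq_len(nrow(annotation))) {
      g <- annotation[i, ]
      ex <- g$exons[[1]]
      # internal 0-based half-open -> GFF3 1-based closed
      lines <- c(
        lines,
        sprintf("%s\tconvergeomics\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
        sprintf("%s\tconvergeomics\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_id),
        sprintf("%s\tconvergeomics\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                g$chrom, ex$start + 1L, ex$end, g$strand, g$gene_id,
                seq_len(nrow(ex)), g$gene_id)
      )
    }
    readr::write_lines(lines, path)
  } else {
    lines <- vapply(seq_len(nrow(annotation)), function(i) {
      g <- annotation[i, ]
      ex <- g$exons[[1]]
      paste(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand, g$start, g$end,
            "0", nrow(ex),
            paste0(paste(ex$end - ex$start, collapse = ","), ","),
            paste0(paste(ex$start - g$start, collapse = ","), ","),
            sep = "\t")
    }, "")
    readr::write_lines(lines, path)
  }
  invisible(path)
}

#' @rdname read_annotation
#' @param genome named character vector of chromosome sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname read_annotation
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a per-cytosine bisulfite report
#'
#' Accepts the 6-column Bismark-coverage dialect (chrom, start 1-based, end,
#' methylation percent, methylated count, unmethylated count) or the 7-column
#' context dialect written by [write_cytosine_report()] (chrom, pos 0-based,
#' strand, context, methylated count, unmethylated count, percent). Records
#' with zero total coverage are dropped (count reported via a message). When a
#' genome is supplied and context/strand are absent they are inferred with
#' [classify_context()]; coverage-dialect positions without a C on either
#' strand are rejected.
#'
#' @param path report TSV (no header).
#' @param genome optional named character vector (see [read_genome_fasta()]).
#' @return cytosine report tibble: chrom, pos (0-based), strand, context
#'   (CG/CHG/CHH or NA), mc, uc.
#' @export
read_cytosine_report <- function(path, genome = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (ncol(x) == 6) {
    rep <- tibble(
      chrom = x[[1]], pos = as.integer(x[[2]]) - 1L, strand = NA_character_,
      context = NA_character_, mc = as.integer(x[[5]]), uc = as.integer(x[[6]]),
      pct = as.numeric(x[[4]])
    )
  } else if (ncol(x) == 7) {
    rep <- tibble(
      chrom = x[[1]], pos = as.integer(x[[2]]), strand = x[[3]],
      context = x[[4]], mc = as.integer(x[[5]]), uc = as.integer(x[[6]]),
      pct = as.numeric(x[[7]])
    )
  } else {
    abort(paste0(path, ": expected 6-column coverage or 7-column context dialect, got ",
                 ncol(x), " columns"))
  }
  if (anyNA(rep$mc) || anyNA(rep$uc) || any(rep$mc < 0) || any(rep$uc < 0)) {
    bad <- which(is.na(rep$mc) | is.na(rep$uc) | rep$mc < 0 | rep$uc < 0)[1]
    abort(sprintf("%s: malformed counts at line %d", path, bad))
  }
  zero <- rep$mc + rep$uc == 0
  if (any(zero)) {
    inform(sprintf("%s: dropped %d record(s) with zero coverage", path, sum(zero)))
    rep <- rep[!zero, , drop = FALSE]
  }
  stated <- rep$pct
  actual <- 100 * rep$mc / (rep$mc + rep$uc)
  off <- !is.na(stated) & abs(stated - actual) > 0.5
  if (any(off)) {
    warn(sprintf("%s: %d record(s) with methylation percent inconsistent with counts by > 0.5 points",
                 path, sum(off)))
  }
  rep$pct <- NULL
  if (!is.null(genome) && anyNA(rep$strand)) {
    rep <- infer_strand_context(rep, genome)
  } else if (!is.null(genome) && anyNA(rep$context)) {
    rep$context <- classify_context(genome, rep$chrom, rep$pos, rep$strand)
  }
  rep
}

# coverage-dialect records carry no strand: decide it from the reference base
infer_strand_context <- function(rep, genome) {
  base <- genome_base(genome, rep$chrom, rep$pos)
  if (any(!base %in% c("C", "G"))) {
    bad <- which(!base %in% c("C", "G"))[1]
    abort(sprintf("record %d (%s:%d): reference base %s is not a cytosine on either strand",
                  bad, rep$chrom[bad], rep$pos[bad], base[bad]))
  }
  rep$strand <- ifelse(base == "C", "+", "-")
  rep$context <- classify_context(genome, rep$chrom, rep$pos, rep$strand)
  rep
}

genome_base <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    if (is.null(genome[[ch]])) abort(paste0("chromosome ", ch, " absent from genome"))
    out[i] <- substring(genome[[ch]], pos[i] + 1L, pos[i] + 1L)
  }
  out
}

#' @rdname read_cytosine_report
#' @param report cytosine report tibble.
#' @param format `"coverage"` (6-column Bismark-coverage dialect) or
#'   `"context"` (7-column dialect with strand and context).
#' @export
write_cytosine_report <- function(report, path, format = c("coverage", "context")) {
  format <- match.arg(format)
  pct <- round(100 * report$mc / (report$mc + report$uc), 6)
  out <- if (format == "coverage") {
    tibble(chrom = report$chrom, start = report$pos + 1L, end = report$pos + 1L,
           pct = pct, mc = report$mc, uc = report$uc)
  } else {
    tibble(chrom = report$chrom, pos = report$pos, strand = report$strand,
           context = report$context, mc = report$mc, uc = report$uc, pct = pct)
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated name, description, members.
#' Duplicate members are collapsed; memberless sets are skipped with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (file.size(path) == 0) {
    warn(paste0(path, ": empty GMT file"))
    return(setNames(list(), character()))
  }
  sets <- fgsea::gmtPathways(path)
  sets <- purrr::map(sets, unique)
  empty <- lengths(sets) < 1
  if (any(empty)) {
    warn(paste0("skipping memberless set(s): ", paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  sets
}
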