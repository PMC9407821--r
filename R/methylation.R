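#' Classify the trinucleotide context of cytosines
#'
#' Reads the strandwise triplet starting at each cytosine: CG when the next
#' base is G; CHG when the next base is H (A, C or T) and the following base
#' is G; CHH otherwise. On the minus strand the triplet is read from the
#' reverse complement. Sites too close to a chromosome end for a complete
#' triplet are classed CHH by convention (reported via a message).
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom,pos,strand vectors describing the sites; `pos` is 0-based and
#'   must hold a cytosine on `strand`.
#' @return character vector in `{"CG", "CHG", "CHH"}`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  out <- character(n)
  incomplete <- 0L
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    s <- genome[[ch]]
    if (is.null(s) || is.na(s)) abort(paste0("chromosome ", ch, " absent from genome"))
    len <- nchar(s)
    p <- pos[i]
    st <- strand[i]
    base <- substring(s, p + 1L, p + 1L)
    expected <- ifelse(st == "+", "C", "G")
    if (any(base != expected)) {
      bad <- which(base != expected)[1]
      abort(sprintf("site %s:%d(%s) is not a cytosine on that strand (reference base %s)",
                    ch, p[bad], st[bad], base[bad]))
    }
    b1 <- ifelse(st == "+", substring(s, p + 2L, p + 2L),
                 comp_base(substring(s, p, p)))
    b2 <- ifelse(st == "+", substring(s, p + 3L, p + 3L),
                 comp_base(substring(s, p - 1L, p - 1L)))
    short <- b1 == "" | (b2 == "" & b1 != "G")
    ctx <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
    ctx[short] <- "CHH"
    incomplete <- incomplete + sum(short)
    out[i] <- ctx
  }
  if (incomplete > 0) {
    inform(sprintf("%d site(s) within 2 bp of a chromosome end classed CHH by convention",
                   incomplete))
  }
  out
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Methylation level of a single cytosine
#'
#' @param mc,uc methylated and unmethylated read counts; `mc + uc >= 1`.
#' @return `mc / (mc + uc)` in `[0, 1]`.
#' @export
site_level <- function(mc, uc) {
  if (any(mc + uc < 1)) abort("site level is undefined at zero coverage")
  mc / (mc + uc)
}

#' Pooled methylation levels in fixed-width genomic bins
#'
#' Bins are `[k * bin_size, (k + 1) * bin_size)` per chromosome; the level of
#' a bin pools reads over its member sites, `sum(mc) / sum(mc + uc)` (not the
#' mean of site levels). Bins without covered sites are omitted.
#'
#' @param report cytosine report tibble.
#' @param bin_size bin width in bp.
#' @param context context class to include; NULL pools all contexts.
#' @return tibble chrom, bin_start, bin_end, n_sites, level.
#' @export
bin_levels <- function(report, bin_size = 10000, context = "CG") {
  if (!is.null(context)) report <- report[report$context %in% context, , drop = FALSE]
  report |>
    mutate(bin_start = (.data$pos %/% bin_size) * bin_size) |>
    group_by(.data$chrom, .data$bin_start) |>
    summarise(n_sites = dplyr::n(),
              level = sum(.data$mc) / sum(.data$mc + .data$uc), .groups = "drop") |>
    mutate(bin_end = .data$bin_start + bin_size) |>
    select("chrom", "bin_start", "bin_end", "n_sites", "level") |>
    arrange(.data$chrom, .data$bin_start)
}

#' Per-context coverage summary
#'
#' Counts sites covered by at least one and at least five reads per context,
#' and among the >= 5-covered sites, the fraction with methylation level above
#' 0.5.
#'
#' @param report cytosine report tibble.
#' @return tibble context, n_cov1, n_cov5, frac_high_cov5.
#' @export
coverage_summary <- function(report) {
  report |>
    mutate(cov = .data$mc + .data$uc) |>
    group_by(.data$context) |>
    summarise(
      n_cov1 = sum(.data$cov >= 1),
      n_cov5 = sum(.data$cov >= 5),
      frac_high_cov5 = ifelse(sum(.data$cov >= 5) == 0, NA_real_,
                              mean((.data$mc / .data$cov)[.data$cov >= 5] > 0.5)),
      .groups = "drop"
    )
}

# overlap join of sites to 0-based half-open intervals; returns site row,
# interval row pairs
site_interval_overlaps <- function(report, intervals) {
  hits <- vector("list", length(unique(intervals$chrom)))
  out <- list()
  for (ch in unique(intervals$chrom)) {
    si <- which(report$chrom == ch)
    ii <- which(intervals$chrom == ch)
    if (length(si) == 0 || length(ii) == 0) next
    q <- IRanges::IRanges(start = report$pos[si] + 1L, width = 1L)
    s <- IRanges::IRanges(start = intervals$start[ii] + 1L,
                          end = intervals$end[ii])
    ov <- IRanges::findOverlaps(q, s)
    out[[ch]] <- tibble(site = si[S4Vectors::queryHits(ov)],
                        interval = ii[S4Vectors::subjectHits(ov)])
  }
  bind_rows(out)
}

#' Pooled methylation level of gene elements
#'
#' Pools reads of the requested context over all CpG sites falling inside any
#' promoter, gene, exon or intron interval (both strands' cytosines inside the
#' interval; sites inside several genes' intervals count toward each, as no
#' overlap resolution is attempted).
#'
#' @param report cytosine report tibble.
#' @param annotation annotation tibble from [read_annotation()].
#' @param context context class to include.
#' @return tibble element, n_sites, level.
#' @export
element_levels <- function(report, annotation, context = "CG") {
  report <- report[report$context %in% context, , drop = FALSE]
  elements <- annotation_elements(annotation)
  ov <- site_interval_overlaps(report, elements)
  if (nrow(ov) == 0) return(tibble(element = character(), n_sites = integer(),
                                   level = double()))
  tibble(
    element = elements$element[ov$interval],
    mc = report$mc[ov$site],
    uc = report$uc[ov$site]
  ) |>
    group_by(.data$element) |>
    summarise(n_sites = dplyr::n(),
              level = sum(.data$mc) / sum(.data$mc + .data$uc), .groups = "drop") |>
    arrange(factor(.data$element, levels = c("promoter", "gene", "exon", "intron")))
}

#' Metagene methylation profile over flanks and length-normalized gene bodies
#'
#' Each gene contributes a 3 x `n_bins` vector: the upstream 2 kb flank split
#' into `n_bins` equal bins, the gene body into `n_bins` equal-length bins
#' (fractional boundaries), and the downstream 2 kb flank likewise. Bin levels
#' pool reads within a gene; the profile is the unweighted mean over genes of
#' the per-gene bin levels (bins a gene leaves empty do not contribute), so
#' long genes do not dominate. Minus-strand genes are flipped so position 1 is
#' always the 5' end. Genes shorter than `n_bins` bp are excluded.
#'
#' @param report cytosine report tibble.
#' @param annotation annotation tibble.
#' @param n_bins bins per region.
#' @param flank flank width in bp.
#' @param context context class to include.
#' @return tibble bin (1..3*n_bins), region (upstream/body/downstream),
#'   n_genes, level.
#' @export
metagene_profile <- function(report, annotation, n_bins = 20, flank = 2000,
                             context = "CG") {
  report <- report[report$context %in% context, , drop = FALSE]
  short <- annotation$end - annotation$start < n_bins
  if (any(short)) {
    inform(sprintf("%d gene(s) shorter than %d bp excluded from the metagene profile",
                   sum(short), n_bins))
    annotation <- annotation[!short, , drop = FALSE]
  }
  if (nrow(annotation) == 0) abort("no gene qualifies for the metagene profile")
  windows <- tibble(
    gene = seq_len(nrow(annotation)),
    chrom = annotation$chrom,
    start = pmax(0L, annotation$start - as.integer(flank)),
    end = annotation$end + as.integer(flank)
  )
  ov <- site_interval_overlaps(report, windows)
  g <- windows$gene[ov$interval]
  pos <- report$pos[ov$site]
  gs <- annotation$start[g]
  ge <- annotation$end[g]
  strand <- annotation$strand[g]
  len <- ge - gs

  # signed position in units of bins from the gene 5' end
  upstream <- ifelse(strand == "+", pos < gs, pos >= ge)
  downstream <- ifelse(strand == "+", pos >= ge, pos < gs)
  body <- !upstream & !downstream
  bin <- integer(length(pos))
  d5 <- ifelse(strand == "+", gs - 1L - pos, pos - ge)      # 0-based dist into upstream
  bin[upstream] <- n_bins - floor(d5[upstream] / (flank / n_bins))
  frac <- ifelse(strand == "+", (pos - gs) / len, (ge - 1L - pos) / len)
  bin[body] <- n_bins + pmin(n_bins, floor(frac[body] * n_bins) + 1L)
  d3 <- ifelse(strand == "+", pos - ge, gs - 1L - pos)
  bin[downstream] <- 2L * n_bins + floor(d3[downstream] / (flank / n_bins)) + 1L
  ok <- bin >= 1 & bin <= 3 * n_bins
  per_gene <- tibble(gene = g[ok], bin = bin[ok],
                     mc = report$mc[ov$site][ok], uc = report$uc[ov$site][ok]) |>
    group_by(.data$gene, .data$bin) |>
    summarise(level = sum(.data$mc) / sum(.data$mc + .data$uc), .groups = "drop")
  prof <- per_gene |>
    group_by(.data$bin) |>
    summarise(n_genes = dplyr::n(), level = mean(.data$level), .groups = "drop")
  full <- tibble(bin = seq_len(3L * n_bins)) |>
    left_join(prof, by = "bin") |>
    mutate(
      n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes),
      region = rep(c("upstream", "body", "downstream"), each = n_bins)
    ) |>
    select("bin", "region", "n_genes", "level")
  class(full) <- c("metagene_profile", class(full))
  full
}
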