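# Independent oracle implementations used to cross-check the package's own
# routines. Each is a literal, unoptimized transcription of the underlying
# definition, kept deliberately separate from the package code paths.

# trimmed mean of M-values, transcribed step by step from the definition
oracle_tmm <- function(mat, trim_m = 0.30, trim_a = 0.05) {
  libs <- colSums(mat)
  ratio_uq <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    ratio_uq[j] <- quantile(mat[, j] / libs[j], probs = 0.75, names = FALSE)
  }
  ref <- which.min(abs(ratio_uq - mean(ratio_uq)))
  factors <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]; r <- mat[, ref]
    use <- x > 0 & r > 0
    x <- x[use]; r <- r[use]
    m_val <- log2((x / libs[j]) / (r / libs[ref]))
    a_val <- 0.5 * log2((x / libs[j]) * (r / libs[ref]))
    w_val <- (libs[j] - x) / (libs[j] * x) + (libs[ref] - r) / (libs[ref] * r)
    if (max(abs(m_val)) < 1e-6) { factors[j] <- 1; next }
    n <- length(m_val)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep <- which(rank(m_val) >= lo_m & rank(m_val) <= hi_m &
                    rank(a_val) >= lo_a & rank(a_val) <= hi_a)
    factors[j] <- 2^(sum(m_val[keep] / w_val[keep]) / sum(1 / w_val[keep]))
  }
  factors / exp(mean(log(factors)))
}

# exact conditional NB test by direct summation of the joint NB mass; the
# conditional law is free of the common mean, so any mu must give the same
# answer as the package's negative-hypergeometric route
oracle_nb_exact <- function(sa, sb, na, nb, phi, mu = 10) {
  t <- sa + sb
  if (t == 0) return(1)
  k <- 0:t
  if (phi == 0) {
    pk <- dbinom(k, t, na / (na + nb))
  } else {
    pk <- dnbinom(k, size = na / phi, mu = na * mu) *
      dnbinom(t - k, size = nb / phi, mu = nb * mu)
    pk <- pk / sum(pk)
  }
  min(1, sum(pk[pk <= pk[sa + 1] * (1 + 1e-10)]))
}

# one-tailed rank-sum p by enumeration of all group assignments (midranks)
oracle_wilcoxon <- function(x, y, direction) {
  r <- rank(c(x, y))
  n <- length(x) + length(y)
  w_obs <- sum(r[seq_along(x)])
  assignments <- utils::combn(n, length(x))
  ws <- apply(assignments, 2, function(i) sum(r[i]))
  if (direction == "less") mean(ws <= w_obs) else mean(ws >= w_obs)
}

# context of a cytosine from its strandwise triplet, via explicit reverse
# complement of the plus-strand text
oracle_context <- function(triplet) {
  b <- strsplit(triplet, "")[[1]]
  stopifnot(b[1] == "C")
  if (length(b) >= 2 && b[2] == "G") return("CG")
  if (length(b) >= 3 && b[3] == "G") return("CHG")
  "CHH"
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# hypergeometric upper tail by explicit mass summation
oracle_hyper_upper <- function(overlap, set_size, bg_size, query_size) {
  k <- overlap:min(set_size, query_size)
  sum(choose(set_size, k) * choose(bg_size - set_size, query_size - k)) /
    choose(bg_size, query_size)
}

# --- small fixture builders -------------------------------------------------

toy_counts <- function(counts_mat, lengths = NULL) {
  lengths <- lengths %||% rep(1000L, nrow(counts_mat))
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(nrow(counts_mat))),
    length_bp = lengths
  ) |> dplyr::bind_cols(tibble::as_tibble(counts_mat))
}

toy_samples <- function(sample_ids, species, tissue = "stomach") {
  tibble::tibble(sample_id = sample_ids, species = species, tissue = tissue)
}

toy_annotation <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    strand <- r$strand %||% "+"
    tss <- if (strand == "+") r$start else r$end - 1L
    prom <- if (strand == "+") c(tss - 1000L, tss) else c(tss + 1L, tss + 1001L)
    tibble::tibble(
      gene_id = r$gene_id, chrom = r$chrom %||% "chr1", strand = strand,
      start = as.integer(r$start), end = as.integer(r$end), tss = as.integer(tss),
      promoter_start = as.integer(prom[1]), promoter_end = as.integer(prom[2]),
      exons = list(r$exons %||% tibble::tibble(start = as.integer(r$start),
                                               end = as.integer(r$end)))
    )
  }))
}

toy_report <- function(pos, mc, uc, chrom = "chr1", strand = "+", context = "CG") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 context = context, mc = as.integer(mc), uc = as.integer(uc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_config <- function(...) {
  args <- utils::modifyList(list(
    n_genes = 300, n_convergent_up = 15, n_convergent_down = 15,
    n_hypo_promoters = 15, n_hyper_promoters = 15,
    library_size_range = c(2e5, 3e5), seed = 11
  ), list(...))
  do.call(sim_config, args)
}
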