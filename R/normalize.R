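#' Low-expression filter for cross-species count matrices
#'
#' Retains genes whose counts are greater than zero in every sample of every
#' species present in the matrix (`rule = "all_species"`), or in every sample
#' of at least one species (`rule = "any_species"`). The number of removed
#' genes is reported via a message.
#'
#' @param counts count tibble (gene_id, length_bp, one column per sample).
#' @param samples sample sheet tibble.
#' @param rule filtering rule, see above.
#' @return filtered count tibble.
#' @export
filter_low_expression <- function(counts, samples,
                                  rule = c("all_species", "any_species")) {
  rule <- match.arg(rule)
  assert_counts_tbl(counts)
  assert_sample_sheet(samples)
  m <- as_gene_matrix(counts)[, samples$sample_id, drop = FALSE]
  by_species <- vapply(split(samples$sample_id, samples$species), function(ids) {
    rowSums(m[, ids, drop = FALSE] > 0) == length(ids)
  }, logical(nrow(m)))
  keep <- if (rule == "all_species") rowSums(!by_species) == 0 else rowSums(by_species) > 0
  if (!any(keep)) {
    abort("low-expression filter removed every gene; review the filtering rule or inputs")
  }
  inform(sprintf("low-expression filter removed %d of %d genes", sum(!keep), nrow(m)))
  counts[keep, , drop = FALSE]
}

#' Reads per kilobase: within-sample gene-length correction
#'
#' @param counts count tibble.
#' @return tibble gene_id plus one numeric column per sample with
#'   `count / (length_bp / 1000)`.
#' @export
rpk <- function(counts) {
  assert_counts_tbl(counts)
  m <- as_gene_matrix(counts) / (counts$length_bp / 1000)
  gene_matrix_tbl(m, counts$gene_id)
}

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample scaling factors from the published TMM definition: the
#' reference is the sample whose upper-quartile/library-size ratio is closest
#' to the mean such ratio; for each sample, log ratios M and average log
#' abundances A are formed against the reference over genes positive in both;
#' the top and bottom `trim_m` of M and `trim_a` of A are trimmed (by rank);
#' the factor is 2 to the precision-weighted mean of the surviving M values
#' (inverse delta-method variances as weights). Factors are rescaled to
#' geometric mean 1.
#'
#' @param rpk_tbl length-corrected table from [rpk()] (raw counts also work;
#'   TMM is scale-aware through library sizes).
#' @param trim_m,trim_a two-sided trim fractions for M and A.
#' @return tibble (sample_id, tmm_factor) with the reference sample id in
#'   attribute `reference`.
#' @export
tmm_factors <- function(rpk_tbl, trim_m = 0.30, trim_a = 0.05) {
  m <- as_gene_matrix(rpk_tbl)
  if (ncol(m) < 2) abort("TMM needs at least two samples")
  if (any(colSums(m) <= 0)) abort("every sample needs at least one positive value")
  lib <- colSums(m)
  f75 <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair_factor(m[, j], m[, ref], trim_m, trim_a)
  }, 0)
  f <- f / geometric_mean(f)
  structure(tibble(sample_id = colnames(m), tmm_factor = f),
            reference = colnames(m)[ref])
}

# single-sample TMM factor against a reference column
tmm_pair_factor <- function(obs, ref, trim_m, trim_a) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  m_g <- log2((obs / n_obs) / (ref / n_ref))
  a_g <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w_g <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(m_g) & is.finite(a_g) & (a_g > -1e10)
  m_g <- m_g[fin]; a_g <- a_g[fin]; w_g <- w_g[fin]
  if (length(m_g) == 0 || max(abs(m_g)) < 1e-6) return(1)
  n <- length(m_g)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m_g) >= lo_m & rank(m_g) <= hi_m &
    rank(a_g) >= lo_a & rank(a_g) <= hi_a
  if (sum(keep) < 10) {
    warn("fewer than 10 genes survive the TMM trim; using the untrimmed weighted mean")
    keep <- rep(TRUE, n)
  }
  2^(sum(m_g[keep] / w_g[keep], na.rm = TRUE) / sum(1 / w_g[keep], na.rm = TRUE))
}

#' GeTMM normalization
#'
#' Gene-length-corrected TMM: RPK values are rescaled per sample to a
#' per-million scale using the TMM-scaled library size,
#' `value[g, s] = rpk[g, s] * 1e6 / (sum_g rpk[g, s] * factor_s)`, giving
#' expression values comparable across species with different gene lengths and
#' sequencing depths.
#'
#' @param counts count tibble, already low-expression filtered.
#' @inheritParams tmm_factors
#' @return tibble gene_id plus one normalized column per sample, with the TMM
#'   factor tibble in attribute `tmm` and class `getmm_tbl`.
#' @export
getmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  rpk_tbl <- rpk(counts)
  factors <- tmm_factors(rpk_tbl, trim_m, trim_a)
  m <- as_gene_matrix(rpk_tbl)
  eff <- colSums(m) * factors$tmm_factor[match(colnames(m), factors$sample_id)]
  if (any(eff <= 0)) abort("zero effective library size")
  norm <- sweep(m, 2, eff, "/") * 1e6
  out <- gene_matrix_tbl(norm, rpk_tbl$gene_id)
  attr(out, "tmm") <- factors
  class(out) <- c("getmm_tbl", class(out))
  out
}

#' log2(x + 1) transform of a normalized table
#'
#' @param norm_tbl tibble gene_id plus numeric sample columns.
#' @return same shape, values `log2(x + 1)`.
#' @export
log_transform <- function(norm_tbl) {
  m <- as_gene_matrix(norm_tbl)
  if (any(m < 0)) abort("log transform expects non-negative values")
  gene_matrix_tbl(log2(m + 1), norm_tbl$gene_id)
}

#' Variance filter
#'
#' Drops the fraction `quantile` of genes with the lowest cross-sample
#' variance; genes tied with the cutoff variance are retained, so slightly
#' more than `1 - quantile` of genes can survive.
#'
#' @param log_tbl tibble gene_id plus numeric sample columns (any scale).
#' @param quantile fraction in `[0, 1)` of lowest-variance genes to drop.
#' @return filtered tibble.
#' @export
variance_filter <- function(log_tbl, quantile = 0.5) {
  if (quantile < 0 || quantile >= 1) abort("quantile must lie in [0, 1)")
  if (quantile == 0) return(log_tbl)
  m <- as_gene_matrix(log_tbl)
  if (ncol(m) < 2) abort("variance filter needs at least two samples")
  v <- apply(m, 1, var, na.rm = TRUE)
  n_drop <- floor(nrow(m) * quantile)
  if (n_drop == 0) return(log_tbl)
  # smallest retained variance; genes tied with it survive
  threshold <- sort(v)[min(nrow(m), n_drop + 1)]
  log_tbl[v >= threshold, , drop = FALSE]
}
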