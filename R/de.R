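#' Common negative-binomial dispersion by method of moments
#'
#' Counts are scaled to a common effective library size (the geometric mean of
#' `library size x TMM factor`). For each gene, the within-species pooled
#' variance `s^2` and grand mean `mu` over species with at least two
#' replicates give `phi_g = max(0, (s^2 - mu) / mu^2)`; the common dispersion
#' is the median of `phi_g` over genes with `mu > 5`. When no gene passes the
#' mean filter the default 0.1 is returned with a warning.
#'
#' @param counts count tibble.
#' @param samples sample sheet restricted to the samples to use.
#' @param factors optional TMM factor tibble from [tmm_factors()]; ones when
#'   NULL.
#' @return non-negative scalar dispersion.
#' @export
estimate_common_dispersion <- function(counts, samples, factors = NULL) {
  m <- as_gene_matrix(counts)[, samples$sample_id, drop = FALSE]
  f <- rep(1, ncol(m))
  if (!is.null(factors)) {
    f <- factors$tmm_factor[match(colnames(m), factors$sample_id)]
  }
  eff <- colSums(m) * f
  scaled <- sweep(m, 2, geometric_mean(eff) / eff, "*")
  groups <- split(seq_len(ncol(scaled)), samples$species)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) abort("dispersion estimation needs >= 2 replicates in some species")
  use <- unlist(groups)
  mu <- rowMeans(scaled[, use, drop = FALSE])
  ss <- 0
  df <- 0
  for (idx in groups) {
    sub <- scaled[, idx, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(idx) - 1
  }
  s2 <- ss / df
  phi_g <- pmax(0, (s2 - mu) / mu^2)
  ok <- mu > 5
  if (!any(ok)) {
    warn("no gene with mean > 5; returning default dispersion 0.1")
    return(0.1)
  }
  median(phi_g[ok])
}

#' Exact negative-binomial test for a two-group count comparison
#'
#' Replicate counts are equalized to a common effective library size (the
#' geometric mean), rounded to pseudo-counts and summed within groups; under
#' the null of equal means the conditional distribution of the group-A sum
#' given the total is free of the mean, and the p-value is the probability of
#' outcomes at most as likely as the one observed (two-sided by probability
#' mass). With zero dispersion the conditional law is binomial.
#'
#' @param y_a,y_b integer replicate counts for one gene in each group.
#' @param lib_a,lib_b effective library sizes per replicate.
#' @param phi common negative-binomial dispersion.
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(y_a, y_b, lib_a, lib_b, phi) {
  common <- geometric_mean(c(lib_a, lib_b))
  sa <- sum(round(y_a * common / lib_a))
  sb <- sum(round(y_b * common / lib_b))
  nb_exact_pvalue(sa, sb, length(y_a), length(y_b), phi)
}

# conditional exact p-value for group sums sa, sb from na, nb replicates
nb_exact_pvalue <- function(sa, sb, na, nb, phi) {
  t <- sa + sb
  if (t == 0) return(1)
  k <- 0:t
  if (phi < 1e-10) {
    logp <- stats::dbinom(k, t, na / (na + nb), log = TRUE)
  } else {
    r_a <- na / phi
    r_b <- nb / phi
    # negative hypergeometric mass, unnormalized:
    # C(k + r_a - 1, k) * C(t - k + r_b - 1, t - k)
    logp <- lgamma(k + r_a) - lgamma(k + 1) + lgamma(t - k + r_b) - lgamma(t - k + 1)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  obs <- logp[sa + 1]
  p <- sum(exp(logp[logp <= obs + 1e-10]))
  min(1, max(p, exp(obs)))
}

#' Shrunken log2 fold change between normalized group means
#'
#' @param norm_a,norm_b normalized (GeTMM) values of one gene in the focal and
#'   outgroup samples.
#' @param prior pseudo-expression added to both means; stabilizes ratios of
#'   lowly expressed genes.
#' @return `log2((mean(norm_a) + prior) / (mean(norm_b) + prior))`; positive
#'   means higher in the focal group.
#' @export
log2_fold_change <- function(norm_a, norm_b, prior = 1) {
  log2((mean(norm_a) + prior) / (mean(norm_b) + prior))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential expression for one focal-vs-outgroup contrast
#'
#' Runs the exact negative-binomial test per gene on raw counts with
#' TMM-effective library sizes, adjusts p-values within the contrast
#' (Benjamini-Hochberg), computes GeTMM-scale log2 fold changes, and applies
#' the DEG thresholds `padj < alpha` and `|log2fc| > lfc_threshold`.
#'
#' @param counts count tibble (the DE gene universe).
#' @param samples sample sheet covering the samples of both species.
#' @param norm GeTMM table from [getmm()] on the same universe; computed when
#'   NULL.
#' @param focal,outgroup species labels to contrast (focal minus outgroup).
#' @param tissue optional tissue restriction.
#' @param dispersion common NB dispersion; estimated from the two species'
#'   samples when NULL.
#' @param alpha,lfc_threshold DEG thresholds.
#' @param prior prior expression for [log2_fold_change()].
#' @return `de_result` tibble: gene_id, log2fc, p, padj, is_deg, direction
#'   (up/down/none), with contrast metadata in attributes.
#' @export
call_contrast <- function(counts, samples, focal, outgroup, tissue = NULL,
                          norm = NULL, dispersion = NULL, alpha = 0.05,
                          lfc_threshold = 1, prior = 1) {
  assert_sample_sheet(samples)
  if (!is.null(tissue)) samples <- samples[samples$tissue == tissue, , drop = FALSE]
  sub <- samples[samples$species %in% c(focal, outgroup), , drop = FALSE]
  if (!all(c(focal, outgroup) %in% sub$species)) {
    abort(paste0("both species must be present: ", focal, " vs ", outgroup))
  }
  ids_a <- sub$sample_id[sub$species == focal]
  ids_b <- sub$sample_id[sub$species == outgroup]
  if (length(ids_a) + length(ids_b) < 4 || length(ids_a) < 2 || length(ids_b) < 2) {
    abort("each group needs at least two replicates")
  }
  if (is.null(norm)) norm <- getmm(counts)
  factors <- attr(norm, "tmm")
  if (is.null(factors)) {
    factors <- tmm_factors(rpk(counts))
  }
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, sub, factors)
  }

  m <- as_gene_matrix(counts)
  nm <- as_gene_matrix(norm)
  if (!identical(rownames(m), rownames(nm))) {
    nm <- nm[rownames(m), , drop = FALSE]
  }
  lib <- colSums(m) * factors$tmm_factor[match(colnames(m), factors$sample_id)]
  names(lib) <- colnames(m)

  # equalize once: pseudo-counts at the common effective library size
  common <- geometric_mean(lib[c(ids_a, ids_b)])
  pseudo <- round(sweep(m[, c(ids_a, ids_b), drop = FALSE], 2,
                        common / lib[c(ids_a, ids_b)], "*"))
  sa <- rowSums(pseudo[, ids_a, drop = FALSE])
  sb <- rowSums(pseudo[, ids_b, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(g) {
    nb_exact_pvalue(sa[g], sb[g], length(ids_a), length(ids_b), dispersion)
  }, 0)
  padj <- bh_adjust(p)
  lfc <- log2((rowMeans(nm[, ids_a, drop = FALSE]) + prior) /
                (rowMeans(nm[, ids_b, drop = FALSE]) + prior))
  is_deg <- padj < alpha & abs(lfc) > lfc_threshold
  out <- tibble(
    gene_id = counts$gene_id,
    log2fc = lfc, p = p, padj = padj, is_deg = is_deg,
    direction = ifelse(!is_deg, "none", ifelse(lfc > 0, "up", "down"))
  )
  attr(out, "contrast") <- list(focal = focal, outgroup = outgroup,
                                tissue = tissue %||% NA_character_,
                                dispersion = dispersion, alpha = alpha,
                                lfc_threshold = lfc_threshold)
  class(out) <- c("de_result", class(out))
  out
}

#' Convergent differentially expressed genes
#'
#' For each focal species, a gene is called up (down) only if it is an
#' up-regulated (down-regulated) DEG in every contrast against every outgroup
#' species; genes with conflicting directions across a focal species'
#' contrasts are excluded from that species' set. Convergent up/down genes are
#' the intersections of the two focal species' directional sets.
#'
#' @param results list of `de_result` objects covering every focal x outgroup
#'   contrast of one tissue.
#' @return `convergent_deg_set`: list with `up`, `down` (gene id vectors),
#'   `per_focal` (named list of each focal species' intersected directional
#'   sets, kept for audit), and `tissue`.
#' @export
convergent_degs <- function(results) {
  info <- purrr::map(results, attr, "contrast")
  focals <- unique(purrr::map_chr(info, "focal"))
  if (length(focals) != 2) abort("expected contrasts for exactly two focal species")
  universe <- results[[1]]$gene_id
  if (!all(purrr::map_lgl(results, ~ identical(.x$gene_id, universe)))) {
    abort("all contrasts must share one gene universe")
  }
  per_focal <- purrr::map(setNames(focals, focals), function(f) {
    rs <- results[purrr::map_chr(info, "focal") == f]
    dir_mat <- vapply(rs, function(r) r$direction, character(length(universe)))
    consistent <- function(d) rowSums(dir_mat == d) == ncol(dir_mat)
    list(up = universe[consistent("up")], down = universe[consistent("down")])
  })
  structure(list(
    up = intersect(per_focal[[1]]$up, per_focal[[2]]$up),
    down = intersect(per_focal[[1]]$down, per_focal[[2]]$down),
    per_focal = per_focal,
    tissue = info[[1]]$tissue
  ), class = "convergent_deg_set")
}
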