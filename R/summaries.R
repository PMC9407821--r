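#' Sample-level PCA of a log expression table
#'
#' Genes are centred, samples are the observations, and the decomposition is a
#' singular value decomposition (via [stats::prcomp()]); explained-variance
#' fractions come from the squared singular values. For reproducible signs,
#' each component is flipped so its largest-magnitude gene loading is positive.
#'
#' @param log_tbl tibble gene_id plus numeric sample columns.
#' @param samples optional sample sheet joined onto the scores.
#' @return `expr_pca` object: list with `scores` (tibble sample_id, PC1, ...),
#'   `loadings` (tibble gene_id, PC1, ...), and `explained` (tibble component,
#'   fraction).
#' @export
pca_samples <- function(log_tbl, samples = NULL) {
  m <- as_gene_matrix(log_tbl)
  if (nrow(m) < 2 || ncol(m) < 2) abort("PCA needs at least 2 genes and 2 samples")
  if (all(apply(m, 1, var) == 0)) abort("all genes are constant; PCA is degenerate")
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  flip <- apply(fit$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2, flip, "*")
  loadings <- sweep(fit$rotation, 2, flip, "*")
  scores_tbl <- bind_cols(tibble(sample_id = colnames(m)), as_tibble(scores))
  if (!is.null(samples)) scores_tbl <- left_join(scores_tbl, samples, by = "sample_id")
  out <- list(
    scores = scores_tbl,
    loadings = bind_cols(tibble(gene_id = log_tbl$gene_id), as_tibble(loadings)),
    explained = tibble(component = colnames(fit$x),
                       fraction = fit$sdev^2 / sum(fit$sdev^2))
  )
  structure(out, class = "expr_pca")
}

#' Spearman correlation and hierarchical clustering of samples
#'
#' Spearman's rank correlation (midranks for ties) between samples; distance
#' `1 - rho`; agglomerative clustering with complete linkage by default.
#'
#' @param log_tbl tibble gene_id plus numeric sample columns.
#' @param method linkage passed to [stats::hclust()].
#' @return `expr_clust` object: list with `correlation` (tibble, wide),
#'   `distance` (dist), and `tree` (hclust).
#' @export
spearman_cluster <- function(log_tbl, method = "complete") {
  m <- as_gene_matrix(log_tbl)
  if (ncol(m) < 3) abort("clustering needs at least 3 samples")
  rho <- cor(m, method = "spearman")
  d <- as.dist(1 - rho)
  tree <- hclust(d, method = method)
  structure(list(
    correlation = bind_cols(tibble(sample_id = colnames(rho)), as_tibble(rho)),
    distance = d,
    tree = tree
  ), class = "expr_clust")
}

#' Newick serialization of a sample dendrogram
#'
#' @param clust `expr_clust` from [spearman_cluster()].
#' @param path optional file; when NULL the newick string is returned.
#' @return newick string, invisibly when written to file.
#' @export
cluster_newick <- function(clust, path = NULL) {
  phy <- ape::as.phylo(clust$tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
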