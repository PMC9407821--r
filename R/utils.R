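#' @importFrom rlang %||% abort warn inform .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols rename pull distinct n across
#' @importFrom tibble tibble as_tibble new_tibble
#' @importFrom stats median quantile rnbinom rbeta rbinom rpois runif rlnorm
#'   var prcomp cor hclust as.dist p.adjust wilcox.test phyper qpois ppois
#'   setNames sd
#' @importFrom utils head
NULL

# sample (value) columns of a gene x sample tibble
value_cols <- function(tbl) {
  setdiff(names(tbl), c("gene_id", "length_bp"))
}

# numeric matrix with gene_id rownames from a wide gene x sample tibble
as_gene_matrix <- function(tbl) {
  cols <- value_cols(tbl)
  m <- as.matrix(tbl[cols])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$gene_id
  m
}

gene_matrix_tbl <- function(m, gene_id, length_bp = NULL) {
  out <- tibble(gene_id = gene_id)
  if (!is.null(length_bp)) out$length_bp <- length_bp
  bind_cols(out, as_tibble(m))
}

assert_sample_sheet <- function(samples) {
  need <- c("sample_id", "species", "tissue")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("sample sheet has duplicated sample_id values")
  }
  invisible(samples)
}

assert_counts_tbl <- function(counts) {
  if (!all(c("gene_id", "length_bp") %in% names(counts))) {
    abort("count table must have gene_id and length_bp columns")
  }
  if (anyDuplicated(counts$gene_id)) abort("duplicated gene_id in count table")
  if (any(counts$length_bp <= 0)) abort("gene lengths must be positive")
  m <- as_gene_matrix(counts)
  if (anyNA(m)) abort("count table contains missing cells")
  if (any(m < 0)) abort("counts must be non-negative")
  invisible(counts)
}

geometric_mean <- function(x) exp(mean(log(x)))

# deterministic child seed, kept well below .Machine$integer.max
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 9973 * as.numeric(offset)) %% 2000000011)
}
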