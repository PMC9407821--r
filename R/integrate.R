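#' Join convergent DEGs with convergent promoters
#'
#' One record per gene present in both the convergent DEG set and the
#' convergent promoter set of a tissue. A record is inverse-consistent when
#' expression and promoter methylation moved in opposite directions
#' (up & hypo, or down & hyper) — the pattern expected when promoter
#' methylation represses transcription.
#'
#' @param degs `convergent_deg_set` from [convergent_degs()], or a tibble with
#'   columns gene_id, direction (up/down).
#' @param promoters `convergent_promoter_set` from [convergent_promoters()],
#'   or a tibble with columns gene_id, direction (hypo/hyper).
#' @param tissue optional tissue label stamped on the records.
#' @return tibble: gene_id, tissue, expression_direction,
#'   methylation_direction, inverse_consistent; summary counts in attribute
#'   `summary`.
#' @export
integrate_inverse <- function(degs, promoters, tissue = NULL) {
  de_tbl <- if (is.data.frame(degs)) {
    tibble(gene_id = degs$gene_id, expression_direction = degs$direction)
  } else {
    bind_rows(tibble(gene_id = degs$up, expression_direction = "up"),
              tibble(gene_id = degs$down, expression_direction = "down"))
  }
  pm_tbl <- if (is.data.frame(promoters)) {
    tibble(gene_id = promoters$gene_id, methylation_direction = promoters$direction)
  } else {
    bind_rows(tibble(gene_id = promoters$hypo, methylation_direction = "hypo"),
              tibble(gene_id = promoters$hyper, methylation_direction = "hyper"))
  }
  out <- inner_join(de_tbl, pm_tbl, by = "gene_id") |>
    mutate(
      tissue = tissue %||% (if (is.data.frame(degs)) NA_character_ else degs$tissue),
      inverse_consistent =
        (.data$expression_direction == "up" & .data$methylation_direction == "hypo") |
        (.data$expression_direction == "down" & .data$methylation_direction == "hyper")
    ) |>
    select("gene_id", "tissue", "expression_direction", "methylation_direction",
           "inverse_consistent") |>
    arrange(.data$gene_id)
  attr(out, "summary") <- list(
    up_hypo = sum(out$expression_direction == "up" & out$methylation_direction == "hypo"),
    down_hyper = sum(out$expression_direction == "down" & out$methylation_direction == "hyper"),
    non_inverse = sum(!out$inverse_consistent)
  )
  out
}

#' Hypergeometric over-representation analysis on user gene sets
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each set of a GMT collection, against a background universe (the
#' expressed genes of the focal species, typically); Benjamini-Hochberg
#' adjustment across sets.
#'
#' @param query character vector of gene ids; must be a subset of `background`.
#' @param sets named list of gene-id vectors (see [read_gmt()]).
#' @param background character vector: the gene universe.
#' @param min_overlap sets overlapping the query in fewer genes are dropped
#'   from the output (0 keeps all).
#' @return tibble: set_name, overlap, set_size, query_size, background_size,
#'   p, padj.
#' @export
ora <- function(query, sets, background, min_overlap = 0) {
  background <- unique(background)
  if (length(background) == 0) abort("background gene universe is empty")
  query <- unique(query)
  if (!all(query %in% background)) {
    abort("query genes must all belong to the background universe")
  }
  rows <- purrr::imap(sets, function(members, name) {
    members <- intersect(unique(members), background)
    k <- length(intersect(members, query))
    tibble(
      set_name = name,
      overlap = k,
      set_size = length(members),
      query_size = length(query),
      background_size = length(background),
      p = phyper(k - 1, length(members), length(background) - length(members),
                 length(query), lower.tail = FALSE)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(set_name = character(), overlap = integer(), set_size = integer(),
                  query_size = integer(), background_size = integer(),
                  p = double(), padj = double()))
  }
  out$padj <- bh_adjust(out$p)
  out[out$overlap >= min_overlap, , drop = FALSE] |> arrange(.data$p)
}
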