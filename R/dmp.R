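# per-sample, per-gene promoter CpG observations: one row per (site, sample)
promoter_site_levels <- function(reports, annotation, min_coverage = 1) {
  prom <- tibble(gene_id = annotation$gene_id, chrom = annotation$chrom,
                 start = pmax(0L, annotation$promoter_start),
                 end = annotation$promoter_end)
  purrr::imap(reports, function(rep, id) {
    cg <- rep[rep$context %in% "CG", , drop = FALSE]
    cg <- cg[cg$mc + cg$uc >= min_coverage, , drop = FALSE]
    ov <- site_interval_overlaps(cg, prom)
    tibble(
      sample_id = id,
      gene_id = prom$gene_id[ov$interval],
      pos = cg$pos[ov$site],
      strand = cg$strand[ov$site],
      mc = cg$mc[ov$site],
      uc = cg$uc[ov$site]
    )
  }) |> bind_rows()
}

#' Promoter methylation matrix across samples
#'
#' One row per ortholog, one column per sample; each cell pools reads over the
#' promoter's CpG sites, `sum(mc) / sum(mc + uc)`. Cells with no covered site
#' are missing. The variance filter of the expression stage is applied to the
#' level matrix (quantile 0.5 by default).
#'
#' @param reports named list of cytosine report tibbles (names = sample ids).
#' @param annotation annotation tibble of the assembly the reports map to; for
#'   several assemblies, supply a named list keyed by species together with
#'   `samples`.
#' @param samples sample sheet; required when `annotation` is a list.
#' @param ortholog_map optional tibble (species, gene_id, ortholog_id) mapping
#'   species gene ids to a common ortholog id; identity when NULL. Orthologs
#'   missing an annotation in some species are dropped (reported).
#' @param var_quantile variance-filter quantile; 0 disables.
#' @param min_coverage minimum reads for a site to contribute.
#' @return `promoter_matrix` tibble: gene_id plus one level column per sample;
#'   per-cell supporting read counts in attribute `support`.
#' @export
promoter_matrix <- function(reports, annotation, samples = NULL,
                            ortholog_map = NULL, var_quantile = 0.5,
                            min_coverage = 1) {
  if (is.data.frame(annotation)) {
    obs <- promoter_site_levels(reports, annotation, min_coverage)
    if (!is.null(ortholog_map)) {
      obs <- inner_join(obs, distinct(ortholog_map[c("gene_id", "ortholog_id")]),
                        by = "gene_id") |>
        select(-"gene_id") |> rename(gene_id = "ortholog_id")
    }
  } else {
    if (is.null(samples) || is.null(ortholog_map)) {
      abort("per-species annotations need `samples` and `ortholog_map`")
    }
    shared <- ortholog_map |>
      group_by(.data$ortholog_id) |>
      summarise(n_sp = dplyr::n_distinct(.data$species), .groups = "drop")
    full <- shared$ortholog_id[shared$n_sp == length(annotation)]
    dropped <- sum(shared$n_sp < length(annotation))
    if (dropped > 0) {
      inform(sprintf("%d ortholog(s) missing an annotation in some species; dropped", dropped))
    }
    obs <- purrr::imap(annotation, function(ann, sp) {
      ids <- samples$sample_id[samples$species == sp]
      map_sp <- ortholog_map[ortholog_map$species == sp, ]
      promoter_site_levels(reports[intersect(names(reports), ids)], ann, min_coverage) |>
        inner_join(map_sp[c("gene_id", "ortholog_id")], by = "gene_id") |>
        select(-"gene_id") |> rename(gene_id = "ortholog_id")
    }) |> bind_rows()
    obs <- obs[obs$gene_id %in% full, , drop = FALSE]
  }

  cells <- obs |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(total = sum(.data$mc + .data$uc), mc = sum(.data$mc), .groups = "drop")
  lvl <- cells |>
    mutate(level = .data$mc / .data$total) |>
    select("gene_id", "sample_id", "level") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "level") |>
    arrange(.data$gene_id)
  if (var_quantile > 0) lvl <- variance_filter(lvl, var_quantile)
  attr(lvl, "support") <- cells
  class(lvl) <- c("promoter_matrix", class(lvl))
  lvl
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Midranks for ties; exact enumeration of the rank-sum null for tie-free
#' samples (up to the standard size limit), otherwise the normal approximation
#' with tie-corrected variance and continuity correction — the behaviour of
#' [stats::wilcox.test()], which backs this operation.
#'
#' @param x,y numeric observations for the two groups.
#' @param direction `"less"` (x tends lower than y) or `"greater"`.
#' @return p-value in (0, 1].
#' @export
wilcoxon_one_tailed <- function(x, y, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(x) < 2 || length(y) < 2) abort("each group needs at least two observations")
  if (length(unique(c(x, y))) == 1) return(1)
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = direction, correct = TRUE)$p.value
  )
  min(1, max(p, .Machine$double.xmin))
}

#' Differential promoter methylation for one focal-vs-outgroup comparison
#'
#' For each gene, observations are the per-(CpG site, sample) promoter
#' methylation levels at coverage `>= min_coverage`, grouped by species (the
#' `"sample"` unit instead uses one pooled promoter level per sample). Both
#' one-tailed Wilcoxon tests are run; p-values are Benjamini-Hochberg adjusted
#' across genes within each direction family; a gene is labeled `hypo` when
#' the less-direction `padj < alpha` (lower in the focal species), `hyper` for
#' the greater direction; in the pathological event both families fire, the
#' gene is left unlabeled (reported).
#'
#' @param reports named list of cytosine report tibbles.
#' @param annotation annotation tibble (one shared assembly).
#' @param samples sample sheet covering the reports.
#' @param focal,outgroup species labels.
#' @param genes optional gene universe (e.g. the variance-filtered rows of
#'   [promoter_matrix()]); all annotated genes when NULL.
#' @param min_coverage per-site coverage floor for an observation.
#' @param unit observation unit, `"site"` or `"sample"`.
#' @param alpha significance threshold on adjusted p-values.
#' @return `dmp_result` tibble: gene_id, n_obs_focal, n_obs_outgroup,
#'   level_focal, level_outgroup (pooled), p_less, p_greater, padj_less,
#'   padj_greater, direction (hypo/hyper/none).
#' @export
call_dmp <- function(reports, annotation, samples, focal, outgroup,
                     genes = NULL, min_coverage = 5,
                     unit = c("site", "sample"), alpha = 0.05) {
  unit <- match.arg(unit)
  assert_sample_sheet(samples)
  ids_a <- samples$sample_id[samples$species == focal]
  ids_b <- samples$sample_id[samples$species == outgroup]
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    abort(paste0("both species must be present: ", focal, " vs ", outgroup))
  }
  obs <- promoter_site_levels(reports[c(ids_a, ids_b)], annotation, min_coverage)
  if (!is.null(genes)) obs <- obs[obs$gene_id %in% genes, , drop = FALSE]
  if (unit == "sample") {
    obs <- obs |>
      group_by(.data$gene_id, .data$sample_id) |>
      summarise(mc = sum(.data$mc), uc = sum(.data$uc), .groups = "drop")
  }
  obs$group <- ifelse(obs$sample_id %in% ids_a, "focal", "outgroup")
  obs$level <- obs$mc / (obs$mc + obs$uc)

  per_gene <- split(obs, obs$gene_id)
  skipped <- 0L
  rows <- purrr::map(per_gene, function(d) {
    x <- d$level[d$group == "focal"]
    y <- d$level[d$group == "outgroup"]
    if (length(x) < 2 || length(y) < 2) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    tibble(
      gene_id = d$gene_id[1],
      n_obs_focal = length(x), n_obs_outgroup = length(y),
      level_focal = sum(d$mc[d$group == "focal"]) /
        sum((d$mc + d$uc)[d$group == "focal"]),
      level_outgroup = sum(d$mc[d$group == "outgroup"]) /
        sum((d$mc + d$uc)[d$group == "outgroup"]),
      p_less = wilcoxon_one_tailed(x, y, "less"),
      p_greater = wilcoxon_one_tailed(x, y, "greater")
    )
  })
  if (skipped > 0) {
    inform(sprintf("%d gene(s) skipped with fewer than two qualifying observations in a group",
                   skipped))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("no gene has enough promoter observations")
  out$padj_less <- bh_adjust(out$p_less)
  out$padj_greater <- bh_adjust(out$p_greater)
  hypo <- out$padj_less < alpha
  hyper <- out$padj_greater < alpha
  both <- hypo & hyper
  if (any(both)) {
    inform(sprintf("%d gene(s) significant in both directions left unlabeled", sum(both)))
  }
  out$direction <- ifelse(both, "none", ifelse(hypo, "hypo",
                                               ifelse(hyper, "hyper", "none")))
  attr(out, "comparison") <- list(focal = focal, outgroup = outgroup,
                                  unit = unit, min_coverage = min_coverage,
                                  alpha = alpha)
  class(out) <- c("dmp_result", class(out))
  out
}

#' Convergent differentially methylated promoters
#'
#' Convergent hypo (hyper) promoters are genes called hypo (hyper) in both
#' focal species against the outgroup; genes with conflicting directions are
#' excluded.
#'
#' @param calls list of two `dmp_result` objects, one per focal species.
#' @return `convergent_promoter_set`: list with `hypo`, `hyper`, `per_focal`
#'   audit sets.
#' @export
convergent_promoters <- function(calls) {
  info <- purrr::map(calls, attr, "comparison")
  focals <- purrr::map_chr(info, "focal")
  if (length(calls) != 2 || anyDuplicated(focals)) {
    abort("expected one call set per focal species")
  }
  per_focal <- purrr::map(setNames(calls, focals), function(r) {
    list(hypo = r$gene_id[r$direction == "hypo"],
         hyper = r$gene_id[r$direction == "hyper"])
  })
  structure(list(
    hypo = intersect(per_focal[[1]]$hypo, per_focal[[2]]$hypo),
    hyper = intersect(per_focal[[1]]$hyper, per_focal[[2]]$hyper),
    per_focal = per_focal
  ), class = "convergent_promoter_set")
}
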