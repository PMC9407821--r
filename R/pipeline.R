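#' Run the full convergence pipeline on simulated data
#'
#' Drives every stage end to end for each tissue: simulate counts ->
#' low-expression filter -> GeTMM -> log transform -> variance filter ->
#' per-contrast exact NB tests -> convergent DEGs; simulate genome and
#' methylomes -> promoter matrix -> one-tailed Wilcoxon differential promoter
#' methylation -> convergent promoters; then the inverse
#' methylation-expression join. Planted-truth recovery statistics are attached
#' per tissue.
#'
#' @param config a [sim_config()] or the path to a YAML file of its fields.
#' @param tissues tissue labels; each is simulated as an independent run.
#' @param var_quantile variance-filter quantile defining the DE gene universe.
#' @param run_methylation set FALSE to skip the methylation arm.
#' @return `convergence_run` object: list with one entry per tissue (`norm`,
#'   `contrasts`, `degs`, `dmp`, `promoters`, `integration`, `truth`,
#'   `recovery`) plus `config` and a `manifest`.
#' @export
run_convergence_pipeline <- function(config, tissues = c("stomach", "small_intestine"),
                                     var_quantile = 0.5, run_methylation = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "sim_config"))
  genome_ann <- if (run_methylation) simulate_genome_annotation(config) else NULL

  per_tissue <- purrr::imap(setNames(tissues, tissues), function(tissue, nm) {
    t_i <- match(tissue, tissues)
    sim <- simulate_expression(config, tissue, seed_offset = 10L * t_i)
    filtered <- filter_low_expression(sim$counts, sim$samples)
    norm <- getmm(filtered)
    logt <- log_transform(norm)
    kept <- variance_filter(logt, var_quantile)$gene_id
    universe <- filtered[filtered$gene_id %in% kept, , drop = FALSE]
    norm_u <- norm[norm$gene_id %in% kept, , drop = FALSE]
    attr(norm_u, "tmm") <- attr(norm, "tmm")

    dispersion <- estimate_common_dispersion(universe, sim$samples, attr(norm, "tmm"))
    contrasts <- list()
    for (f in config$focal_species) {
      for (o in config$outgroup_species) {
        contrasts[[paste(f, o, sep = ".vs.")]] <- call_contrast(
          universe, sim$samples, focal = f, outgroup = o, tissue = tissue,
          norm = norm_u, dispersion = dispersion
        )
      }
    }
    degs <- convergent_degs(contrasts)

    dmp <- NULL; promoters <- NULL; integration <- NULL; meth_truth <- NULL
    if (run_methylation) {
      meth <- simulate_methylome(config, genome_ann$genome, genome_ann$annotation,
                                 expression_truth = sim$truth, tissue = tissue,
                                 seed_offset = 10L * t_i + 5L)
      pm <- promoter_matrix(meth$reports, genome_ann$annotation,
                            var_quantile = var_quantile)
      dmp <- purrr::map(setNames(nm = config$focal_species), function(f) {
        call_dmp(meth$reports, genome_ann$annotation, meth$samples,
                 focal = f, outgroup = config$outgroup_species[1],
                 genes = pm$gene_id)
      })
      promoters <- convergent_promoters(dmp)
      integration <- integrate_inverse(degs, promoters, tissue)
      meth_truth <- meth$truth
    }

    truth <- sim$truth
    if (!is.null(meth_truth)) {
      truth <- left_join(truth, meth_truth[c("gene_id", "meth_status")], by = "gene_id")
    }
    recovery <- pipeline_recovery(degs, promoters, integration, truth)

    list(samples = sim$samples, norm = norm, universe = universe$gene_id,
         dispersion = dispersion, contrasts = contrasts, degs = degs,
         dmp = dmp, promoters = promoters, integration = integration,
         truth = truth, recovery = recovery)
  })

  structure(list(
    tissues = per_tissue,
    config = config,
    manifest = list(
      package_version = as.character(utils::packageVersion("convergeomics")),
      r_version = R.version.string,
      seed = config$seed,
      tissues = tissues,
      timestamp = format(Sys.time(), tz = "UTC")
    )
  ), class = "convergence_run")
}

#' Sensitivity and false-discovery proportion of a called set
#'
#' @param called character vector of called gene ids.
#' @param truth_set character vector of genes planted with the matching
#'   status.
#' @return tibble n_called, n_true, sensitivity, fdr (NA when nothing is
#'   called).
#' @export
recovery_stats <- function(called, truth_set) {
  tp <- length(intersect(called, truth_set))
  tibble(
    n_called = length(called),
    n_true = length(truth_set),
    sensitivity = if (length(truth_set) == 0) NA_real_ else tp / length(truth_set),
    fdr = if (length(called) == 0) NA_real_ else 1 - tp / length(called)
  )
}

pipeline_recovery <- function(degs, promoters, integration, truth) {
  out <- list(
    deg = bind_rows(
      mutate(recovery_stats(degs$up, truth$gene_id[truth$expression_status == "up"]),
             set = "convergent_up"),
      mutate(recovery_stats(degs$down, truth$gene_id[truth$expression_status == "down"]),
             set = "convergent_down")
    )
  )
  if (!is.null(promoters)) {
    out$promoter <- bind_rows(
      mutate(recovery_stats(promoters$hypo, truth$gene_id[truth$meth_status == "hypo"]),
             set = "convergent_hypo"),
      mutate(recovery_stats(promoters$hyper, truth$gene_id[truth$meth_status == "hyper"]),
             set = "convergent_hyper")
    )
  }
  if (!is.null(integration)) {
    planted_inverse <- truth$gene_id[
      (truth$expression_status == "up" & truth$meth_status == "hypo") |
        (truth$expression_status == "down" & truth$meth_status == "hyper")
    ]
    called <- integration$gene_id[integration$inverse_consistent]
    out$integration <- mutate(recovery_stats(called, planted_inverse),
                              set = "inverse_consistent")
  }
  out
}

#' Read a pipeline configuration from YAML
#'
#' The YAML fields mirror the arguments of [sim_config()]; unknown fields are
#' rejected.
#'
#' @param path YAML file.
#' @return validated `sim_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0(path, ": unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, raw)
}

#' Write the run manifest of a pipeline result as JSON
#'
#' @param run `convergence_run` object.
#' @param path output JSON path.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
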