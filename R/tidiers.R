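#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn call_contrast per-gene tibble of the contrast.
#' @param x,... broom-interface arguments.
#' @exportS3Method generics::tidy
tidy.de_result <- function(x, ...) {
  as_tibble(x)
}

#' @describeIn call_contrast one-row summary: contrast, dispersion, DEG counts.
#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  info <- attr(x, "contrast")
  tibble(
    focal = info$focal, outgroup = info$outgroup, tissue = info$tissue,
    dispersion = info$dispersion, n_genes = nrow(x),
    n_deg = sum(x$is_deg), n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down")
  )
}

#' @describeIn convergent_degs long tibble (gene_id, direction) of the
#'   convergent sets.
#' @param x,... broom-interface arguments.
#' @exportS3Method generics::tidy
tidy.convergent_deg_set <- function(x, ...) {
  bind_rows(tibble(gene_id = x$up, direction = "up"),
            tibble(gene_id = x$down, direction = "down"))
}

#' @describeIn convergent_degs one-row summary of set sizes.
#' @exportS3Method generics::glance
glance.convergent_deg_set <- function(x, ...) {
  tibble(
    tissue = x$tissue, n_up = length(x$up), n_down = length(x$down),
    n_convergent = length(x$up) + length(x$down)
  )
}

#' @describeIn call_dmp per-gene tibble of the comparison.
#' @exportS3Method generics::tidy
tidy.dmp_result <- function(x, ...) {
  as_tibble(x)
}

#' @describeIn call_dmp one-row summary: comparison, hypo/hyper counts.
#' @exportS3Method generics::glance
glance.dmp_result <- function(x, ...) {
  info <- attr(x, "comparison")
  tibble(
    focal = info$focal, outgroup = info$outgroup, unit = info$unit,
    n_genes = nrow(x), n_hypo = sum(x$direction == "hypo"),
    n_hyper = sum(x$direction == "hyper")
  )
}

#' @describeIn convergent_promoters long tibble (gene_id, direction).
#' @param x,... broom-interface arguments.
#' @exportS3Method generics::tidy
tidy.convergent_promoter_set <- function(x, ...) {
  bind_rows(tibble(gene_id = x$hypo, direction = "hypo"),
            tibble(gene_id = x$hyper, direction = "hyper"))
}

#' @describeIn convergent_promoters one-row summary of set sizes.
#' @exportS3Method generics::glance
glance.convergent_promoter_set <- function(x, ...) {
  tibble(n_hypo = length(x$hypo), n_hyper = length(x$hyper))
}

#' @describeIn pca_samples long tibble of scores with explained-variance
#'   fractions.
#' @param x,... broom-interface arguments.
#' @exportS3Method generics::tidy
tidy.expr_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                        values_to = "score") |>
    left_join(x$explained, by = "component")
}

#' @describeIn run_convergence_pipeline per-tissue summary of convergent
#'   calls and planted-truth recovery.
#' @param x,... broom-interface arguments.
#' @exportS3Method generics::glance
glance.convergence_run <- function(x, ...) {
  purrr::imap(x$tissues, function(tt, tissue) {
    rec <- bind_rows(tt$recovery)
    mutate(rec, tissue = tissue, .before = 1)
  }) |> bind_rows()
}

#' @exportS3Method base::print
print.convergence_run <- function(x, ...) {
  cat("<convergence_run> seed", x$config$seed, "\n")
  print(glance(x))
  invisible(x)
}
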