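test_that("promoter matrix pools promoter CpGs per sample", {
  ann <- toy_annotation(list(gene_id = "g1", start = 2000L, end = 3000L),
                        list(gene_id = "g2", start = 6000L, end = 7000L))
  # promoter of g1 is [1000, 2000); g2's is [5000, 6000)
  r1 <- dplyr::bind_rows(
    toy_report(pos = c(1100L, 1200L), mc = c(1L, 0L), uc = c(9L, 10L)),
    toy_report(pos = 5500L, mc = 4L, uc = 0L)
  )
  r2 <- toy_report(pos = c(1100L, 1200L), mc = c(5L, 5L), uc = c(5L, 5L))
  pm <- promoter_matrix(list(s1 = r1, s2 = r2), ann, var_quantile = 0)
  expect_equal(pm$s1[pm$gene_id == "g1"], 1 / 20)
  expect_equal(pm$s2[pm$gene_id == "g1"], 0.5)
  # no covered promoter site in s2 for g2: missing cell
  expect_true(is.na(pm$s2[pm$gene_id == "g2"]))
  expect_equal(pm$s1[pm$gene_id == "g2"], 1)
})

test_that("promoter matrix maps species gene ids onto orthologs", {
  ann_a <- toy_annotation(list(gene_id = "a_1", start = 2000L, end = 3000L))
  ann_b <- toy_annotation(list(gene_id = "b_1", start = 2000L, end = 3000L),
                          list(gene_id = "b_2", start = 6000L, end = 7000L))
  map <- tibble::tibble(
    species = c("spA", "spB", "spB"),
    gene_id = c("a_1", "b_1", "b_2"),
    ortholog_id = c("OG1", "OG1", "OG2")
  )
  samples <- toy_samples(c("sa", "sb"), c("spA", "spB"))
  rep_a <- toy_report(pos = 1500L, mc = 2L, uc = 2L)
  rep_b <- toy_report(pos = c(1500L, 5500L), mc = c(3L, 1L), uc = c(1L, 1L))
  expect_message(
    pm <- promoter_matrix(list(sa = rep_a, sb = rep_b),
                          list(spA = ann_a, spB = ann_b),
                          samples = samples, ortholog_map = map,
                          var_quantile = 0),
    "missing an annotation"
  )
  # OG2 has no spA annotation and is dropped; OG1 keeps both samples
  expect_equal(pm$gene_id, "OG1")
  expect_equal(pm$sa, 0.5)
  expect_equal(pm$sb, 0.75)
})

test_that("one-tailed Wilcoxon matches enumeration on the worked example", {
  a <- c(0.1, 0.2, 0.3); b <- c(0.4, 0.5, 0.6)
  expect_equal(wilcoxon_one_tailed(a, b, "less"), 0.05)
  expect_equal(wilcoxon_one_tailed(a, b, "greater"), 1)
  # symmetric input: both directions at least one half
  x <- c(0.2, 0.4, 0.6)
  expect_gte(wilcoxon_one_tailed(x, x + 1e-9 * 0, "less"), 0.5)
  expect_gte(wilcoxon_one_tailed(x, x, "greater"), 0.5)
  expect_equal(wilcoxon_one_tailed(c(1, 1), c(1, 1), "less"), 1)
  expect_error(wilcoxon_one_tailed(1, c(1, 2), "less"), "two observations")
})

test_that("exact Wilcoxon equals full permutation enumeration for small groups", {
  set.seed(13)
  for (i in 1:40) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- round(runif(na), 6); y <- round(runif(nb), 6)  # ties have measure ~0
    for (dir in c("less", "greater")) {
      expect_equal(wilcoxon_one_tailed(x, y, dir), oracle_wilcoxon(x, y, dir),
                   tolerance = 1e-12)
    }
  }
})

test_that("differential promoter calls recover planted shifts and stay quiet under the null", {
  cfg <- small_config(n_genes = 200, n_hypo_promoters = 20, n_hyper_promoters = 20,
                      seed = 31)
  ga <- simulate_genome_annotation(cfg)
  me <- suppressWarnings(simulate_methylome(cfg, ga$genome, ga$annotation))
  calls <- purrr::map(setNames(nm = cfg$focal_species), function(f) {
    suppressMessages(call_dmp(me$reports, ga$annotation, me$samples,
                              focal = f, outgroup = cfg$outgroup_species[1]))
  })
  conv <- convergent_promoters(calls)
  truth_hypo <- me$truth$gene_id[me$truth$meth_status == "hypo"]
  truth_hyper <- me$truth$gene_id[me$truth$meth_status == "hyper"]
  expect_gte(length(intersect(conv$hypo, truth_hypo)) / length(truth_hypo), 0.8)
  expect_gte(length(intersect(conv$hyper, truth_hyper)) / length(truth_hyper), 0.8)
  fp <- length(setdiff(c(conv$hypo, conv$hyper), c(truth_hypo, truth_hyper)))
  expect_lte(fp / max(1, length(conv$hypo) + length(conv$hyper)), 0.1)

  # null configuration: essentially nothing is labeled
  cfg0 <- small_config(n_genes = 200, n_hypo_promoters = 0, n_hyper_promoters = 0,
                       seed = 32)
  me0 <- simulate_methylome(cfg0, ga$genome, ga$annotation)
  call0 <- suppressMessages(call_dmp(me0$reports, ga$annotation, me0$samples,
                                     focal = cfg0$focal_species[1],
                                     outgroup = cfg0$outgroup_species[1]))
  expect_lte(sum(call0$direction != "none"), 1)
})

test_that("swapping focal and outgroup swaps hypo and hyper exactly", {
  cfg <- small_config(n_genes = 120, n_hypo_promoters = 15, n_hyper_promoters = 15,
                      seed = 33)
  ga <- simulate_genome_annotation(cfg)
  me <- suppressWarnings(simulate_methylome(cfg, ga$genome, ga$annotation))
  fwd <- suppressMessages(call_dmp(me$reports, ga$annotation, me$samples,
                                   focal = cfg$focal_species[1],
                                   outgroup = cfg$outgroup_species[1]))
  rev <- suppressMessages(call_dmp(me$reports, ga$annotation, me$samples,
                                   focal = cfg$outgroup_species[1],
                                   outgroup = cfg$focal_species[1]))
  expect_equal(fwd$gene_id, rev$gene_id)
  expect_equal(fwd$p_less, rev$p_greater, tolerance = 1e-12)
  expect_setequal(fwd$gene_id[fwd$direction == "hypo"],
                  rev$gene_id[rev$direction == "hyper"])
  expect_setequal(fwd$gene_id[fwd$direction == "hyper"],
                  rev$gene_id[rev$direction == "hypo"])
})

test_that("convergent promoter intersection matches a brute-force check", {
  mk <- function(focal, genes, dirs) {
    out <- tibble::tibble(gene_id = genes, n_obs_focal = 10L, n_obs_outgroup = 10L,
                          level_focal = 0.2, level_outgroup = 0.5,
                          p_less = 0.01, p_greater = 0.9,
                          padj_less = 0.02, padj_greater = 0.95,
                          direction = dirs)
    attr(out, "comparison") <- list(focal = focal, outgroup = "ferret",
                                    unit = "site", min_coverage = 5, alpha = 0.05)
    class(out) <- c("dmp_result", class(out))
    out
  }
  genes <- sprintf("g%02d", 1:10)
  set.seed(14)
  d1 <- sample(c("hypo", "hyper", "none"), 10, TRUE)
  d2 <- sample(c("hypo", "hyper", "none"), 10, TRUE)
  d1[1] <- d2[1] <- "hypo"; d1[2] <- "hypo"; d2[2] <- "none"
  conv <- convergent_promoters(list(mk("p1", genes, d1), mk("p2", genes, d2)))
  expect_setequal(conv$hypo, genes[d1 == "hypo" & d2 == "hypo"])
  expect_setequal(conv$hyper, genes[d1 == "hyper" & d2 == "hyper"])
  expect_true("g01" %in% conv$hypo)
  expect_false("g02" %in% conv$hypo)
  expect_length(intersect(conv$hypo, conv$hyper), 0)
})
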