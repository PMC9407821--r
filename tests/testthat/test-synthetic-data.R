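test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_genes = 10, n_convergent_up = 8, n_convergent_down = 8),
               "exceed")
  expect_error(sim_config(focal_species = "only_one"), "two focal")
  expect_error(sim_config(meth_delta = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 0), "positive")
})

test_that("expression simulation is seed-deterministic and truth-consistent", {
  cfg <- small_config()
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$expression_status == "up"), cfg$n_convergent_up)
  expect_equal(sum(a$truth$expression_status == "down"), cfg$n_convergent_down)
  expect_equal(nrow(a$counts), cfg$n_genes)
  expect_equal(length(value_cols <- setdiff(names(a$counts), c("gene_id", "length_bp"))),
               sum(cfg$replicates_per_species))
  # different tissue offset gives different draws
  c2 <- simulate_expression(cfg, seed_offset = 3L)
  expect_false(identical(a$counts, c2$counts))
})

test_that("null expression configuration plants nothing", {
  cfg <- small_config(n_convergent_up = 0, n_convergent_down = 0, effect_log2fc = 0)
  sim <- simulate_expression(cfg)
  expect_true(all(sim$truth$expression_status == "null"))
  mean_cols <- grep("^mean_", names(sim$truth), value = TRUE)
  # expected expression identical across species when nothing is planted
  for (col in mean_cols[-1]) expect_equal(sim$truth[[col]], sim$truth[[mean_cols[1]]])
})

test_that("planted fold change is recovered empirically from the count matrix", {
  cfg <- sim_config(n_genes = 2000, n_convergent_up = 100, n_convergent_down = 100,
                    effect_log2fc = 2, nb_dispersion = 0.1,
                    replicates_per_species = 4, seed = 41)
  sim <- simulate_expression(cfg)
  m <- as.matrix(sim$counts[setdiff(names(sim$counts), c("gene_id", "length_bp"))])
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  focal <- sim$samples$sample_id[sim$samples$role == "focal"]
  outg <- sim$samples$sample_id[sim$samples$role == "outgroup"]
  up <- sim$truth$expression_status == "up"
  ratio <- log2(rowMeans(cpm[up, focal]) / rowMeans(cpm[up, outg]))
  expect_equal(mean(ratio), 2.0, tolerance = 0.2 / 2.0)
})

test_that("simulated genome leaves 2 kb margins and sane composition", {
  cfg <- small_config(n_genes = 120)
  ga <- simulate_genome_annotation(cfg)
  chrom_len <- nchar(ga$genome)
  ann <- ga$annotation
  expect_true(all(ann$start - 2000 >= 0))
  expect_true(all(ann$end + 2000 <= chrom_len[ann$chrom]))
  gc <- sum(strsplit(paste(ga$genome, collapse = ""), "")[[1]] %in% c("G", "C")) /
    sum(chrom_len)
  expect_gt(gc, 0.3)
  expect_lt(gc, 0.7)
  expect_true(all(vapply(ann$exons, nrow, 1L) >= 2))
})

test_that("genome and annotation round-trip through FASTA and GFF3", {
  cfg <- small_config(n_genes = 30)
  ga <- simulate_genome_annotation(cfg)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome_fasta(ga$genome, fa)
  write_annotation(ga$annotation, gff)
  expect_identical(read_genome_fasta(fa), ga$genome)
  back <- read_annotation(gff)
  orig <- ga$annotation[order(ga$annotation$chrom, ga$annotation$start), ]
  expect_equal(back$gene_id, orig$gene_id)
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_equal(back$strand, orig$strand)
  expect_equal(back$tss, orig$tss)
  expect_equal(back$promoter_start, orig$promoter_start)
  purrr::walk2(back$exons, orig$exons, function(a, b) {
    expect_equal(as.data.frame(a), as.data.frame(b))
  })
  # BED12 mirror carries the same structure
  bed <- tempfile(fileext = ".bed")
  write_annotation(ga$annotation, bed, format = "bed12")
  back_bed <- read_annotation(bed)
  expect_equal(back_bed$start, orig$start)
  expect_equal(purrr::map_int(back_bed$exons, nrow), purrr::map_int(orig$exons, nrow))
})

test_that("methylome shows promoter troughs and seed determinism", {
  cfg <- small_config(n_genes = 60)
  ga <- simulate_genome_annotation(cfg)
  me <- suppressWarnings(simulate_methylome(cfg, ga$genome, ga$annotation))
  me2 <- suppressWarnings(simulate_methylome(cfg, ga$genome, ga$annotation))
  expect_identical(me$reports, me2$reports)
  prom <- tibble::tibble(gene_id = ga$annotation$gene_id, chrom = ga$annotation$chrom,
                         start = ga$annotation$promoter_start,
                         end = ga$annotation$promoter_end)
  for (rep in me$reports[1:3]) {
    cg <- rep[rep$context == "CG", ]
    in_prom <- rep(FALSE, nrow(cg))
    for (i in seq_len(nrow(prom))) {
      in_prom <- in_prom | (cg$chrom == prom$chrom[i] & cg$pos >= prom$start[i] &
                              cg$pos < prom$end[i])
    }
    gene_lvl <- sum(cg$mc[!in_prom]) / sum((cg$mc + cg$uc)[!in_prom])
    prom_lvl <- sum(cg$mc[in_prom]) / sum((cg$mc + cg$uc)[in_prom])
    expect_lt(prom_lvl, gene_lvl)
  }
  # every record covered at least once
  all_cov <- purrr::map_lgl(me$reports, ~ all(.x$mc + .x$uc >= 1))
  expect_true(all(all_cov))
})

test_that("null methylome plants no promoter differences", {
  cfg <- small_config(n_genes = 40, n_hypo_promoters = 0, n_hyper_promoters = 0)
  ga <- simulate_genome_annotation(cfg)
  me <- simulate_methylome(cfg, ga$genome, ga$annotation)
  expect_true(all(me$truth$meth_status == "null"))
  sp <- grep("^prom_", names(me$truth), value = TRUE)
  for (col in sp[-1]) expect_equal(me$truth[[col]], me$truth[[sp[1]]])
})

test_that("planted hypo promoters shift pooled levels by the configured delta", {
  cfg <- sim_config(n_genes = 150, n_convergent_up = 0, n_convergent_down = 0,
                    n_hypo_promoters = 30, n_hyper_promoters = 0,
                    meth_delta = 0.3, read_depth_mean = 10, seed = 5)
  ga <- simulate_genome_annotation(cfg)
  me <- simulate_methylome(cfg, ga$genome, ga$annotation)
  hypo <- me$truth$gene_id[me$truth$meth_status == "hypo"]
  ann <- ga$annotation[ga$annotation$gene_id %in% hypo, ]
  pooled <- function(ids) {
    tot_mc <- 0; tot <- 0
    for (id in ids) {
      rep <- me$reports[[id]]
      cg <- rep[rep$context == "CG", ]
      keep <- rep(FALSE, nrow(cg))
      for (i in seq_len(nrow(ann))) {
        keep <- keep | (cg$chrom == ann$chrom[i] & cg$pos >= ann$promoter_start[i] &
                          cg$pos < ann$promoter_end[i])
      }
      tot_mc <- tot_mc + sum(cg$mc[keep]); tot <- tot + sum((cg$mc + cg$uc)[keep])
    }
    tot_mc / tot
  }
  focal_ids <- me$samples$sample_id[me$samples$role == "focal"]
  out_ids <- me$samples$sample_id[me$samples$role == "outgroup"]
  expect_equal(pooled(out_ids) - pooled(focal_ids), 0.3, tolerance = 0.05 / 0.3)
})

test_that("methylation truth aligns with expression truth when linked", {
  cfg <- small_config()
  sim <- simulate_expression(cfg)
  ga <- simulate_genome_annotation(cfg)
  me <- suppressWarnings(simulate_methylome(cfg, ga$genome, ga$annotation, sim$truth))
  up <- sim$truth$gene_id[sim$truth$expression_status == "up"]
  hypo <- me$truth$gene_id[me$truth$meth_status == "hypo"]
  expect_true(all(hypo %in% up))
  expect_equal(sum(me$truth$meth_status == "hypo"), cfg$n_hypo_promoters)
  expect_equal(sum(me$truth$meth_status == "hyper"), cfg$n_hyper_promoters)
})
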