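test_that("low-expression filter honours the species-wise rules", {
  m <- matrix(c(
    5L, 3L, 2L, 4L,   # expressed everywhere
    5L, 0L, 2L, 4L,   # one zero in species a
    0L, 0L, 3L, 3L,   # expressed only in species b
    0L, 0L, 0L, 0L    # silent
  ), nrow = 4, byrow = TRUE, dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  counts <- toy_counts(m)
  samples <- toy_samples(c("a1", "a2", "b1", "b2"), c("a", "a", "b", "b"))
  strict <- suppressMessages(filter_low_expression(counts, samples))
  expect_equal(strict$gene_id, "g001")
  loose <- suppressMessages(filter_low_expression(counts, samples, rule = "any_species"))
  expect_equal(loose$gene_id, c("g001", "g002", "g003"))
  # all-positive matrix unchanged
  allpos <- toy_counts(matrix(1L, 2, 4, dimnames = list(NULL, colnames(m))))
  expect_equal(nrow(suppressMessages(filter_low_expression(allpos, samples))), 2L)
})

test_that("rpk divides counts by kilobases", {
  counts <- toy_counts(matrix(c(100, 0, 7), 3, 1, dimnames = list(NULL, "s1")),
                       lengths = c(2000L, 1500L, 500L))
  out <- rpk(counts)
  expect_equal(out$s1, c(50, 0, 14))
})

test_that("TMM factors are 1 under symmetry and pure depth differences", {
  set.seed(1)
  x <- matrix(rpois(600, 50) + 1, 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  same <- toy_counts(cbind(a = x[, 1], b = x[, 1], c = x[, 1]))
  f <- tmm_factors(rpk(same))
  expect_equal(f$tmm_factor, rep(1, 3))
  # doubling a column is absorbed by the library size, not the factor
  depth <- toy_counts(cbind(a = x[, 1], b = 2L * x[, 1]))
  f2 <- tmm_factors(rpk(depth))
  expect_equal(f2$tmm_factor, rep(1, 2))
})

test_that("asymmetric expression shifts the TMM factor in the right direction", {
  set.seed(2)
  a <- rpois(200, 100) + 1
  b <- rpois(200, 100) + 1
  b[1:20] <- b[1:20] * 8L  # 10% of genes much higher in B
  counts <- toy_counts(cbind(A = a, B = b))
  f <- tmm_factors(rpk(counts))
  fb <- f$tmm_factor[f$sample_id == "B"]
  fa <- f$tmm_factor[f$sample_id == "A"]
  expect_lt(fb / fa, 1)
  # agrees with the independent literal transcription
  oracle <- oracle_tmm(as.matrix(rpk(counts)[c("A", "B")]))
  expect_equal(f$tmm_factor, oracle, tolerance = 1e-12)
})

test_that("TMM matches the reference edgeR implementation on random fixtures", {
  skip_if_not_installed("edgeR")
  set.seed(33)
  for (i in 1:5) {
    m <- matrix(rnbinom(200 * 6, mu = exp(runif(200, 1, 7)), size = 5), 200, 6)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    m <- m / runif(nrow(m), 0.5, 3)  # continuous, RPK-like values
    colnames(m) <- paste0("s", 1:6)
    tbl <- toy_counts(m)
    mine <- tmm_factors(rpk(tbl))$tmm_factor
    theirs <- unname(edgeR::calcNormFactors(as.matrix(rpk(tbl)[colnames(m)])))
    expect_equal(mine, theirs, tolerance = 1e-12)
  }
})

test_that("GeTMM satisfies its normalization identities", {
  set.seed(3)
  m <- matrix(rpois(150 * 4, 60) + 1, 150, 4, dimnames = list(NULL, paste0("s", 1:4)))
  counts <- toy_counts(m, lengths = sample(500:3000, 150))
  norm <- getmm(counts)
  factors <- attr(norm, "tmm")
  vals <- as.matrix(norm[paste0("s", 1:4)])
  # column sums equal 1e6 / factor
  expect_equal(unname(colSums(vals)), 1e6 / factors$tmm_factor, tolerance = 1e-9)
  # scaling all counts of one sample leaves its normalized column unchanged
  # up to the depth-dependence of the TMM precision weights
  counts2 <- counts
  counts2$s2 <- 2L * counts2$s2
  norm2 <- getmm(counts2)
  expect_equal(norm2$s2, norm$s2, tolerance = 1e-3)
  # worked 3-gene fixture: equal RPK gives equal thirds of a million
  worked <- toy_counts(matrix(c(10L, 20L, 70L, 10L, 20L, 70L), 3, 2,
                              dimnames = list(NULL, c("x", "y"))),
                       lengths = c(1000L, 2000L, 7000L))
  wn <- getmm(worked)
  expect_equal(wn$x, rep(1e6 / 3, 3), tolerance = 1e-9)
})

test_that("pipeline output is invariant to gene and sample order", {
  set.seed(4)
  m <- matrix(rpois(80 * 4, 40) + 1, 80, 4, dimnames = list(NULL, paste0("s", 1:4)))
  counts <- toy_counts(m, lengths = sample(800:2000, 80))
  norm <- getmm(counts)
  perm <- counts[sample(nrow(counts)), c("gene_id", "length_bp", "s3", "s1", "s4", "s2")]
  norm_perm <- getmm(perm)
  joined <- dplyr::left_join(as_tibble(norm_perm), as_tibble(norm),
                             by = "gene_id", suffix = c("_p", ""))
  for (s in paste0("s", 1:4)) {
    expect_equal(joined[[paste0(s, "_p")]], joined[[s]], tolerance = 1e-12)
  }
})

test_that("log transform and variance filter behave as documented", {
  tbl <- toy_counts(matrix(c(0, 1, 1023), 3, 1, dimnames = list(NULL, "s1")))
  lt <- log_transform(tbl[c("gene_id", "s1")])
  expect_equal(lt$s1, c(0, 1, 10))

  set.seed(5)
  m <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m[1, ] <- 5  # constant row, zero variance
  tbl2 <- tibble::tibble(gene_id = sprintf("g%02d", 1:10)) |>
    dplyr::bind_cols(tibble::as_tibble(m))
  expect_equal(variance_filter(tbl2, 0), tbl2)
  kept <- variance_filter(tbl2, 0.5)
  expect_equal(nrow(kept), 5L)
  v <- apply(m, 1, var)
  expect_setequal(kept$gene_id, tbl2$gene_id[rank(-v) <= 5])
  expect_false("g01" %in% kept$gene_id)
  expect_error(variance_filter(tbl2, 1), "\\[0, 1\\)")
})

test_that("PCA separates duplicated-column clusters and keeps SVD identities", {
  base1 <- rnorm(50); base2 <- rnorm(50)
  m <- cbind(a1 = base1, a2 = base1 + rnorm(50, sd = 1e-3),
             b1 = base2, b2 = base2 + rnorm(50, sd = 1e-3))
  tbl <- tibble::tibble(gene_id = sprintf("g%02d", 1:50)) |>
    dplyr::bind_cols(tibble::as_tibble(m))
  p <- pca_samples(tbl)
  expect_equal(sum(p$explained$fraction), 1, tolerance = 1e-9)
  expect_gt(p$explained$fraction[1], 0.99)
  s <- p$scores
  expect_true(sign(s$PC1[1]) == sign(s$PC1[2]) && sign(s$PC1[3]) == sign(s$PC1[4]))
  expect_true(sign(s$PC1[1]) != sign(s$PC1[3]))
  gram <- crossprod(as.matrix(s[paste0("PC", 1:4)]))
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  expect_error(pca_samples(tbl |> dplyr::mutate(dplyr::across(-gene_id, ~0))),
               "degenerate")
})

test_that("Spearman clustering is rank-invariant and merges the closest pair first", {
  set.seed(6)
  a <- rnorm(30)
  m <- cbind(A = a, B = a + rnorm(30, sd = 0.1), C = rnorm(30))
  tbl <- tibble::tibble(gene_id = sprintf("g%02d", 1:30)) |>
    dplyr::bind_cols(tibble::as_tibble(m))
  cl <- spearman_cluster(tbl)
  expect_equal(diag(as.matrix(cl$correlation[c("A", "B", "C")])), rep(1, 3),
               ignore_attr = TRUE)
  # monotone transform of a column leaves correlations unchanged
  tbl2 <- tbl |> dplyr::mutate(A = exp(A))
  cl2 <- spearman_cluster(tbl2)
  expect_equal(cl$correlation, cl2$correlation)
  # first merge joins the two correlated samples
  first <- cl$tree$merge[1, ]
  expect_setequal(cl$tree$labels[-first], c("A", "B"))
  # newick serialization carries all labels
  nwk <- cluster_newick(cl)
  expect_true(all(vapply(c("A", "B", "C"), grepl, TRUE, x = nwk)))
})
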