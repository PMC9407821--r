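#' Simulation configuration for the convergence study design
#'
#' Bundles every tunable of the synthetic multi-species study: a negative-
#' binomial ortholog count matrix with planted convergent expression shifts in
#' the two focal (bamboo-eating) species, and beta-binomial CpG methylomes with
#' promoter troughs and planted convergent promoter hypo-/hypermethylation.
#'
#' The defaults mirror the emulated study design: two focal species against
#' three non-herbivore outgroups for expression (methylomes use the focal pair
#' plus the first outgroup, the ferret analogue), four replicates per species
#' and tissue, 2000 orthologs with 100 convergent-up and 100 convergent-down
#' genes planted at |log2FC| = 2 under dispersion 0.1, and promoters carrying
#' 20 CpGs at mean coverage 10 with a planted methylation shift of 0.3.
#'
#' @param n_genes number of orthologs.
#' @param focal_species,outgroup_species character vectors of species labels;
#'   exactly two focal species are required.
#' @param replicates_per_species replicates per species per tissue; scalar or
#'   named vector over all species.
#' @param n_convergent_up,n_convergent_down planted convergent DEG counts.
#' @param effect_log2fc planted absolute log2 fold change (focal vs outgroup).
#' @param nb_dispersion common negative-binomial dispersion (variance
#'   \eqn{\mu + \phi \mu^2}).
#' @param library_size_range,gene_length_range integer pairs: per-sample library
#'   size and transcript length (bp) sampling ranges.
#' @param n_hypo_promoters,n_hyper_promoters planted convergent promoter counts.
#' @param meth_delta planted promoter methylation shift, in (0, 1).
#' @param baseline_promoter_meth,baseline_body_meth mean methylation level at
#'   the TSS trough bottom and in gene bodies / intergenic sequence.
#' @param beta_precision concentration of the per-site beta distribution of
#'   true methylation levels.
#' @param read_depth_mean mean per-cytosine coverage (Poisson, truncated at 1).
#' @param promoter_cpg,body_cpg CpG dinucleotides planted per promoter and per
#'   gene body.
#' @param non_cg_site_rate fraction of non-CpG cytosines emitted in reports
#'   (sparse sampling keeps reports compact; levels there are near zero).
#' @param seed integer seed; fully determines all generated data.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2000,
                       focal_species = c("giant_panda", "red_panda"),
                       outgroup_species = c("ferret", "dog", "mouse"),
                       replicates_per_species = 4,
                       n_convergent_up = 100,
                       n_convergent_down = 100,
                       effect_log2fc = 2,
                       nb_dispersion = 0.1,
                       library_size_range = c(8e5, 1.2e6),
                       gene_length_range = c(1000, 3000),
                       n_hypo_promoters = 100,
                       n_hyper_promoters = 100,
                       meth_delta = 0.3,
                       baseline_promoter_meth = 0.4,
                       baseline_body_meth = 0.7,
                       beta_precision = 30,
                       read_depth_mean = 10,
                       promoter_cpg = 20,
                       body_cpg = 20,
                       non_cg_site_rate = 0.02,
                       seed = 1L) {
  if (n_genes < 1) abort("n_genes must be a positive integer")
  if (length(focal_species) != 2) abort("exactly two focal species are required")
  if (length(outgroup_species) < 1) abort("at least one outgroup species is required")
  species <- c(focal_species, outgroup_species)
  if (anyDuplicated(species)) abort("species labels must be unique")
  reps <- replicates_per_species
  if (length(reps) == 1) reps <- setNames(rep(reps, length(species)), species)
  if (is.null(names(reps))) names(reps) <- species
  if (!all(species %in% names(reps))) abort("replicates_per_species must cover every species")
  if (any(reps < 1)) abort("replicates_per_species must be positive")
  if (n_convergent_up + n_convergent_down > n_genes) {
    abort("planted convergent DEG counts exceed n_genes")
  }
  if (n_hypo_promoters + n_hyper_promoters > n_genes) {
    abort("planted convergent promoter counts exceed n_genes")
  }
  probs <- c(meth_delta, baseline_promoter_meth, baseline_body_meth)
  if (any(probs < 0 | probs > 1)) abort("methylation levels/shifts must lie in [0, 1]")
  if (effect_log2fc < 0) abort("effect_log2fc must be non-negative")
  if (nb_dispersion < 0) abort("nb_dispersion must be non-negative")
  if (diff(library_size_range) < 0 || any(library_size_range <= 0)) {
    abort("library_size_range must be an increasing pair of positive numbers")
  }
  if (diff(gene_length_range) < 0 || any(gene_length_range <= 0)) {
    abort("gene_length_range must be an increasing pair of positive numbers")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    focal_species = focal_species,
    outgroup_species = outgroup_species,
    replicates_per_species = reps,
    n_convergent_up = as.integer(n_convergent_up),
    n_convergent_down = as.integer(n_convergent_down),
    effect_log2fc = effect_log2fc,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    gene_length_range = gene_length_range,
    n_hypo_promoters = as.integer(n_hypo_promoters),
    n_hyper_promoters = as.integer(n_hyper_promoters),
    meth_delta = meth_delta,
    baseline_promoter_meth = baseline_promoter_meth,
    baseline_body_meth = baseline_body_meth,
    beta_precision = beta_precision,
    read_depth_mean = read_depth_mean,
    promoter_cpg = as.integer(promoter_cpg),
    body_cpg = as.integer(body_cpg),
    non_cg_site_rate = non_cg_site_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

sim_species <- function(config) c(config$focal_species, config$outgroup_species)

sim_gene_ids <- function(config) {
  sprintf("g%05d", seq_len(config$n_genes))
}

# planted expression statuses: deterministic given the config seed
sim_expression_truth <- function(config) {
  gene_id <- sim_gene_ids(config)
  status <- rep("null", config$n_genes)
  n_up <- config$n_convergent_up
  n_down <- config$n_convergent_down
  if (n_up + n_down > 0) {
    idx <- sample.int(config$n_genes, n_up + n_down)
    status[idx[seq_len(n_up)]] <- "up"
    if (n_down > 0) status[idx[n_up + seq_len(n_down)]] <- "down"
  }
  tibble(gene_id = gene_id, expression_status = status)
}

#' Simulate a multi-species ortholog count matrix with planted convergence
#'
#' Draws negative-binomial counts for every sample of every species in the
#' panel. Gene means are proportional to a log-normal baseline expression times
#' transcript length (longer transcripts attract more reads), scaled to the
#' sample's library size. Planted "up" genes are shifted by
#' `+effect_log2fc` in both focal species relative to every outgroup ("down"
#' genes by the negative shift); all other genes share one cross-species mean,
#' so composition bias from the planted genes is the only systematic
#' between-species difference — exactly what TMM scaling is meant to absorb.
#'
#' @param config a [sim_config()].
#' @param tissue tissue label written into the sample sheet.
#' @param seed_offset added (scaled) to the config seed so tissues can be
#'   simulated as independent runs.
#' @return list with `counts` (tibble: gene_id, length_bp, one column per
#'   sample), `samples` (sample sheet tibble: sample_id, species, tissue,
#'   role), and `truth` (tibble: gene_id, expression_status, plus
#'   `mean_<species>` expected per-million expression).
#' @export
simulate_expression <- function(config, tissue = "stomach", seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, seed_offset))
  species <- sim_species(config)
  gene_id <- sim_gene_ids(config)

  length_bp <- round(runif(config$n_genes, config$gene_length_range[1],
                           config$gene_length_range[2]))
  baseline <- rlnorm(config$n_genes, meanlog = 3, sdlog = 1.2)
  truth <- sim_expression_truth(config)

  weight <- baseline * length_bp / 1000
  fc <- matrix(1, config$n_genes, length(species),
               dimnames = list(gene_id, species))
  fc[truth$expression_status == "up", config$focal_species] <- 2^config$effect_log2fc
  fc[truth$expression_status == "down", config$focal_species] <- 2^(-config$effect_log2fc)

  samples <- tidyr::expand_grid(species = species) |>
    mutate(n = config$replicates_per_species[.data$species]) |>
    tidyr::uncount(.data$n, .id = "rep") |>
    mutate(
      sample_id = paste(.data$species, tissue, .data$rep, sep = "_"),
      tissue = tissue,
      role = ifelse(.data$species %in% config$focal_species, "focal", "outgroup")
    ) |>
    select("sample_id", "species", "tissue", "role")

  counts <- matrix(0L, config$n_genes, nrow(samples),
                   dimnames = list(gene_id, samples$sample_id))
  libsize <- round(runif(nrow(samples), config$library_size_range[1],
                         config$library_size_range[2]))
  for (j in seq_len(nrow(samples))) {
    w <- weight * fc[, samples$species[j]]
    mu <- libsize[j] * w / sum(w)
    counts[, j] <- if (config$nb_dispersion > 0) {
      rnbinom(config$n_genes, mu = mu, size = 1 / config$nb_dispersion)
    } else {
      rpois(config$n_genes, mu)
    }
  }

  for (sp in species) {
    w <- weight * fc[, sp]
    truth[[paste0("mean_", sp)]] <- 1e6 * w / sum(w)
  }

  list(
    counts = gene_matrix_tbl(counts, gene_id, length_bp),
    samples = samples,
    truth = truth
  )
}

#' Simulate a genome and gene annotation with CpG-structured promoters
#'
#' Lays the configured genes on chromosomes of 100 genes each, one transcript
#' per gene with 2-4 exons and random strand, leaving >= 2 kb of flank around
#' every gene. The background sequence is CpG-depleted (as in vertebrate
#' genomes); CpG dinucleotides are then planted densely in promoters
#' (`promoter_cpg` per 1 kb promoter), at moderate density in gene bodies, and
#' sparsely in intergenic sequence, so promoter CpG islands stand out.
#'
#' @inheritParams simulate_expression
#' @param length_bp optional per-gene span lengths (bp); drawn from
#'   `gene_length_range` when NULL. Supply the lengths from
#'   [simulate_expression()] to keep the two data types consistent.
#' @return list with `genome` (named character vector of chromosome sequences)
#'   and `annotation` (tibble as returned by [read_annotation()]: gene_id,
#'   chrom, strand, start, end, tss, promoter_start, promoter_end, exons
#'   list-column; 0-based half-open coordinates).
#' @export
simulate_genome_annotation <- function(config, length_bp = NULL, seed_offset = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, seed_offset))
  n <- config$n_genes
  gene_id <- sim_gene_ids(config)
  if (is.null(length_bp)) {
    length_bp <- round(runif(n, config$gene_length_range[1], config$gene_length_range[2]))
  }
  length_bp <- pmax(length_bp, 200)
  flank <- 2000L
  spacer <- 1000L
  genes_per_chrom <- 100L
  chrom_of <- (seq_len(n) - 1L) %/% genes_per_chrom + 1L
  chroms <- sprintf("chr%02d", sort(unique(chrom_of)))

  ann <- vector("list", n)
  seqs <- list()
  for (ci in seq_along(chroms)) {
    idx <- which(chrom_of == ci)
    # gene k occupies [cursor + flank, cursor + flank + len)
    cursor <- 0L
    starts <- integer(length(idx))
    for (k in seq_along(idx)) {
      starts[k] <- cursor + flank
      cursor <- starts[k] + length_bp[idx[k]] + flank + spacer
    }
    chrom_len <- cursor + flank
    # CpG-depleted background: sample letters, then break accidental CG pairs
    s <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    cg <- which(s[-length(s)] == "C" & s[-1] == "G")
    if (length(cg) > 0) s[cg + 1L] <- "A"

    for (k in seq_along(idx)) {
      g <- idx[k]
      start <- starts[k]
      end <- start + length_bp[g]
      strand <- sample(c("+", "-"), 1)
      tss <- if (strand == "+") start else end - 1L
      # exon structure: 2-4 exons over the span
      n_exon <- sample(2:4, 1)
      cuts <- sort(sample(seq(start + 50L, end - 50L, by = 10L), 2L * (n_exon - 1L)))
      bounds <- c(start, cuts, end)
      exon_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
      exon_end <- bounds[seq(2, length(bounds), by = 2)]

      prom <- promoter_interval(tss, strand, size = 1000L)
      plant_cpg <- function(lo, hi, n_cpg) {
        if (n_cpg < 1 || hi - lo < 4) return(invisible(NULL))
        pos <- lo + sort(sample.int(hi - lo - 2L, min(n_cpg, (hi - lo) %/% 3L))) - 1L
        pos <- pos[c(TRUE, diff(pos) >= 2L)]
        s[pos + 1L] <<- "C"; s[pos + 2L] <<- "G"
      }
      plant_cpg(prom[1], prom[2], config$promoter_cpg)
      plant_cpg(start, end, config$body_cpg)

      ann[[g]] <- tibble(
        gene_id = gene_id[g], chrom = chroms[ci], strand = strand,
        start = start, end = end, tss = tss,
        promoter_start = prom[1], promoter_end = prom[2],
        exons = list(tibble(start = exon_start, end = exon_end))
      )
    }
    # sparse intergenic CpGs
    n_inter <- max(1L, round(chrom_len / 2000))
    pos <- sort(sample.int(chrom_len - 2L, n_inter))
    pos <- pos[c(TRUE, diff(pos) >= 2L)]
    s[pos] <- "C"; s[pos + 1L] <- "G"
    seqs[[chroms[ci]]] <- paste(s, collapse = "")
  }
  list(genome = unlist(seqs), annotation = bind_rows(ann))
}

# strand-aware promoter: the 1000 bp immediately upstream of the TSS,
# 0-based half-open
promoter_interval <- function(tss, strand, size = 1000L) {
  if (strand == "+") c(max(0L, tss - size), tss) else c(tss + 1L, tss + 1L + size)
}

# trough-shaped mean methylation level around the TSS: body baseline far from
# the TSS, promoter baseline at its bottom, linear taper over the promoter and
# the first 1000 bp of gene body
trough_mean <- function(dist_to_tss, promoter_mean, body_mean, width = 1000) {
  w <- pmax(0, 1 - abs(dist_to_tss) / width)
  body_mean + (promoter_mean - body_mean) * w
}

#' Simulate per-cytosine bisulfite reports with planted promoter shifts
#'
#' For every CpG in the genome (both strands) a true methylation level is drawn
#' from a beta distribution whose mean follows a TSS-centred trough
#' (`baseline_body_meth` far from genes, `baseline_promoter_meth` at the TSS);
#' coverage is Poisson truncated at 1 and methylated counts are binomial.
#' Planted hypo (hyper) promoters shift the promoter-region mean by
#' `-meth_delta` (`+meth_delta`) in both focal species; shifted means are
#' clipped to [0.01, 0.99] with a warning. Non-CpG cytosines are emitted for a
#' sparse subset of positions at mean level 0.01, reflecting the near-absence
#' of methylation outside the CpG context in mammals.
#'
#' @inheritParams simulate_expression
#' @param genome,annotation from [simulate_genome_annotation()].
#' @param expression_truth optional truth tibble from [simulate_expression()];
#'   when supplied, planted hypo promoters are assigned to convergent-up genes
#'   first and hyper promoters to convergent-down genes, so inverse
#'   methylation-expression pairs exist by construction.
#' @return list with `reports` (named list of per-sample cytosine report
#'   tibbles: chrom, pos, strand, context, mc, uc), `samples` (sample sheet),
#'   and `truth` (gene_id, meth_status, expected pooled promoter level per
#'   species as `prom_<species>`).
#' @export
simulate_methylome <- function(config, genome, annotation,
                               expression_truth = NULL,
                               tissue = "stomach", seed_offset = 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, seed_offset))
  species <- c(config$focal_species, config$outgroup_species[1])

  truth <- sim_methylation_truth(config, expression_truth)

  sites <- methylome_sites(config, genome, annotation, truth)

  samples <- tidyr::expand_grid(species = species) |>
    mutate(n = config$replicates_per_species[.data$species]) |>
    tidyr::uncount(.data$n, .id = "rep") |>
    mutate(
      sample_id = paste(.data$species, tissue, "bs", .data$rep, sep = "_"),
      tissue = tissue,
      role = ifelse(.data$species %in% config$focal_species, "focal", "outgroup")
    ) |>
    select("sample_id", "species", "tissue", "role")

  reports <- vector("list", nrow(samples))
  names(reports) <- samples$sample_id
  for (j in seq_len(nrow(samples))) {
    focal <- samples$role[j] == "focal"
    mean_level <- if (focal) sites$mean_focal else sites$mean_outgroup
    level <- rbeta(nrow(sites),
                   shape1 = mean_level * config$beta_precision,
                   shape2 = (1 - mean_level) * config$beta_precision)
    cov <- rpois_trunc1(nrow(sites), config$read_depth_mean)
    mc <- rbinom(nrow(sites), cov, level)
    reports[[j]] <- tibble(
      chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
      context = sites$context, mc = mc, uc = cov - mc
    )
  }

  for (sp in species) {
    focal <- sp %in% config$focal_species
    m <- if (focal) sites$mean_focal else sites$mean_outgroup
    prom <- tapply(m[!is.na(sites$promoter_gene)],
                   sites$promoter_gene[!is.na(sites$promoter_gene)], mean)
    truth[[paste0("prom_", sp)]] <- as.numeric(prom[truth$gene_id])
  }

  list(reports = reports, samples = samples, truth = truth)
}

sim_methylation_truth <- function(config, expression_truth = NULL) {
  gene_id <- sim_gene_ids(config)
  status <- rep("null", config$n_genes)
  n_hypo <- config$n_hypo_promoters
  n_hyper <- config$n_hyper_promoters
  pick <- function(pool, n, taken) {
    pool <- setdiff(pool, taken)
    pool[seq_len(min(n, length(pool)))]
  }
  if (!is.null(expression_truth)) {
    up <- expression_truth$gene_id[expression_truth$expression_status == "up"]
    down <- expression_truth$gene_id[expression_truth$expression_status == "down"]
    none <- expression_truth$gene_id[expression_truth$expression_status == "null"]
    hypo <- pick(c(up, none), n_hypo, character())
    hyper <- pick(c(down, none), n_hyper, hypo)
  } else {
    idx <- sample.int(config$n_genes, n_hypo + n_hyper)
    hypo <- gene_id[idx[seq_len(n_hypo)]]
    hyper <- gene_id[idx[n_hypo + seq_len(n_hyper)]]
  }
  status[gene_id %in% hypo] <- "hypo"
  status[gene_id %in% hyper] <- "hyper"
  tibble(gene_id = gene_id, meth_status = status)
}

# enumerate cytosine sites (both strands of every CpG plus a sparse sample of
# non-CpG cytosines) with their per-species mean methylation levels
methylome_sites <- function(config, genome, annotation, truth) {
  out <- vector("list", length(genome))
  shift <- setNames(
    ifelse(truth$meth_status == "hypo", -config$meth_delta,
           ifelse(truth$meth_status == "hyper", config$meth_delta, 0)),
    truth$gene_id
  )
  clipped <- FALSE
  for (chrom in names(genome)) {
    s <- strsplit(genome[[chrom]], "")[[1]]
    cg <- which(s[-length(s)] == "C" & s[-1] == "G")  # 1-based C of CG
    plus <- tibble(chrom = chrom, pos = cg - 1L, strand = "+", context = "CG")
    minus <- tibble(chrom = chrom, pos = cg, strand = "-", context = "CG")
    sites <- bind_rows(plus, minus)

    non_cg <- setdiff(which(s == "C" | s == "G"), c(cg, cg + 1L))
    n_take <- round(length(non_cg) * config$non_cg_site_rate)
    if (n_take > 0) {
      take <- sort(sample(non_cg, n_take))
      str <- ifelse(s[take] == "C", "+", "-")
      ctx <- classify_context(genome, rep(chrom, n_take), take - 1L, str)
      sites <- bind_rows(sites, tibble(chrom = chrom, pos = take - 1L,
                                       strand = str, context = ctx))
    }

    ann <- annotation[annotation$chrom == chrom, ]
    mean_base <- rep(config$baseline_body_meth, nrow(sites))
    mean_focal <- mean_base
    promoter_gene <- rep(NA_character_, nrow(sites))
    for (g in seq_len(nrow(ann))) {
      tss <- ann$tss[g]
      dist <- if (ann$strand[g] == "+") sites$pos - tss else tss - sites$pos
      near <- which(dist > -1000 & dist < 1000)
      if (length(near) > 0) {
        mean_base[near] <- trough_mean(dist[near], config$baseline_promoter_meth,
                                       config$baseline_body_meth)
        mean_focal[near] <- mean_base[near]
      }
      in_prom <- which(sites$pos >= ann$promoter_start[g] &
                         sites$pos < ann$promoter_end[g])
      if (length(in_prom) > 0) {
        promoter_gene[in_prom] <- ann$gene_id[g]
        d <- shift[[ann$gene_id[g]]]
        if (d != 0) {
          shifted <- mean_base[in_prom] + d
          if (any(shifted < 0.01 | shifted > 0.99)) clipped <- TRUE
          mean_focal[in_prom] <- pmin(0.99, pmax(0.01, shifted))
        }
      }
    }
    sites$mean_outgroup <- mean_base
    sites$mean_focal <- mean_focal
    sites$promoter_gene <- promoter_gene
    # non-CpG contexts are essentially unmethylated
    non <- sites$context != "CG"
    sites$mean_outgroup[non] <- 0.01
    sites$mean_focal[non] <- 0.01
    out[[chrom]] <- sites
  }
  if (clipped) {
    warn("planted methylation shift pushed some site means outside (0, 1); clipped to [0.01, 0.99]")
  }
  bind_rows(out) |> arrange(.data$chrom, .data$pos, .data$strand)
}

# Poisson truncated at >= 1, exact via inverse transform
rpois_trunc1 <- function(n, lambda) {
  p0 <- ppois(0, lambda)
  qpois(p0 + runif(n) * (1 - p0), lambda)
}

#' Write a simulated data set to disk in standard formats
#'
#' Serializes every artifact of a simulation: counts + sample sheet as TSV,
#' genome as FASTA, annotation as GFF3 and BED12, cytosine reports as
#' Bismark-coverage-style TSV plus the context-annotated dialect, and the
#' planted truth as TSV.
#'
#' @param dir output directory (created if missing).
#' @param expression result of [simulate_expression()].
#' @param genome,annotation result of [simulate_genome_annotation()].
#' @param methylome result of [simulate_methylome()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, expression = NULL, genome = NULL,
                             annotation = NULL, methylome = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(expression)) {
    write_counts(expression$counts, file.path(dir, "counts.tsv"))
    readr::write_tsv(expression$samples, file.path(dir, "samples.tsv"))
    readr::write_tsv(expression$truth, file.path(dir, "expression_truth.tsv"))
  }
  if (!is.null(genome)) write_genome_fasta(genome, file.path(dir, "genome.fa"))
  if (!is.null(annotation)) {
    write_annotation(annotation, file.path(dir, "annotation.gff3"))
    write_annotation(annotation, file.path(dir, "annotation.bed"), format = "bed12")
  }
  if (!is.null(methylome)) {
    readr::write_tsv(methylome$samples, file.path(dir, "bs_samples.tsv"))
    readr::write_tsv(methylome$truth, file.path(dir, "methylation_truth.tsv"))
    for (id in names(methylome$reports)) {
      write_cytosine_report(methylome$reports[[id]],
                            file.path(dir, paste0(id, ".cov.tsv")))
      write_cytosine_report(methylome$reports[[id]],
                            file.path(dir, paste0(id, ".context.tsv")),
                            format = "context")
    }
  }
  invisible(dir)
}
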