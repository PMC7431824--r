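#' Simulation configuration
#'
#' Bundles every knob of the synthetic methylome generator. The defaults
#' emulate the study design the package targets: two groups of six samples
#' (young donors aged 25-35 years, advanced-paternal-age donors aged 50-64),
#' sperm-like baseline methylation (CpG islands hypomethylated near 10%,
#' non-island background near 80%), beta-binomial inter-individual noise,
#' Poisson read depth with mean 20, and spiked differentially methylated
#' regions of absolute effect 30 percentage points.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_islands CpG islands per chromosome.
#' @param island_length Island width in bp.
#' @param cpgs_per_island CpG sites placed inside each island.
#' @param background_cpg_rate Background CpG density per bp outside islands.
#' @param island_baseline_meth,background_baseline_meth Baseline methylation
#'   percentages inside/outside islands.
#' @param dispersion Beta-binomial overdispersion rho in (0, 1); 0 means
#'   no inter-individual variance beyond sampling.
#' @param coverage_mean Mean Poisson read depth per CpG per sample.
#' @param n_young,n_apa Samples per group.
#' @param n_spiked_hyper,n_spiked_hypo Number of spiked hyper/hypomethylated
#'   regions (APA relative to young).
#' @param effect_sizes Absolute methylation differences (percentage points)
#'   cycled over the spiked regions; each must be >= 10.
#' @param age_range_young,age_range_apa Uniform age ranges (years).
#' @param age_slope_per_year Optional extra effect (percent per year beyond
#'   age 50) applied along the spiked direction in APA samples; default 0.
#' @param n_genes_per_chrom Genes tiled per chromosome (alternating strand).
#' @param gene_length Gene body width in bp.
#' @param n_bands_per_chrom Cytobands per chromosome (must be even; first
#'   half is the p arm).
#' @param nucleosome_gene_fraction Fraction of genes whose promoter is
#'   covered by a nucleosome-retention region.
#' @param gene_set_specs Named list describing synthetic gene lists; each
#'   element is `list(size =, frac =)` where `frac` is the fraction of the
#'   list drawn from spiked-DMR-associated genes (`NA` = proportional null).
#' @param seed Master seed; all generation is a pure function of the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2,
                       chrom_length = 1e6,
                       n_islands = 20,
                       island_length = 1000,
                       cpgs_per_island = 15,
                       background_cpg_rate = 5e-4,
                       island_baseline_meth = 10,
                       background_baseline_meth = 80,
                       dispersion = 0.05,
                       coverage_mean = 20,
                       n_young = 6,
                       n_apa = 6,
                       n_spiked_hyper = 8,
                       n_spiked_hypo = 8,
                       effect_sizes = 30,
                       age_range_young = c(25, 35),
                       age_range_apa = c(50, 64),
                       age_slope_per_year = 0,
                       n_genes_per_chrom = 50,
                       gene_length = 10000,
                       n_bands_per_chrom = 8,
                       nucleosome_gene_fraction = 0.2,
                       gene_set_specs = list(
                         planted = list(size = 20, frac = 0.5),
                         proportional_null = list(size = 20, frac = NA)),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_chroms >= 1, chrom_length > 0, n_islands >= 0,
            island_length > 0, cpgs_per_island >= 1,
            background_cpg_rate >= 0,
            island_baseline_meth >= 0, island_baseline_meth <= 100,
            background_baseline_meth >= 0, background_baseline_meth <= 100,
            dispersion >= 0, dispersion < 1,
            coverage_mean > 0, n_young >= 1, n_apa >= 1,
            n_spiked_hyper >= 0, n_spiked_hypo >= 0,
            all(abs(effect_sizes) >= 10),
            n_bands_per_chrom %% 2 == 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate genome-scale annotations and CpG positions
#'
#' Produces the structural half of a synthetic study: CpG islands, CpG site
#' positions (dense inside islands, sparse Poisson background outside),
#' gene models tiling each chromosome with alternating strands, cytobands
#' that exactly partition each chromosome into p/q arm bands, and
#' nucleosome-retention regions covering a configurable fraction of gene
#' promoters. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome` with elements `islands`, `cpg_sites`,
#'   `genes`, `cytobands`, `nucleosomes`, `chrom_lengths`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_islands * config$island_length > config$chrom_length) {
    stop("island total length exceeds chromosome length")
  }
  with_seed(derive_seed(config$seed, 1L), {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms),
                              chroms)
    islands <- list(); sites <- list(); genes <- list()
    bands <- list(); nucs <- list()
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      L <- config$chrom_length
      # islands on an even lattice with jitter; lattice keeps them disjoint
      if (config$n_islands > 0) {
        spacing <- L / config$n_islands
        jitter_max <- max(0, (spacing - config$island_length) / 2 - 1)
        anchors <- (seq_len(config$n_islands) - 0.5) * spacing -
          config$island_length / 2
        starts <- round(anchors + runif(config$n_islands,
                                        -jitter_max / 2, jitter_max / 2))
        starts <- pmax(0, pmin(starts, L - config$island_length))
        isl <- data.frame(chrom = ch, start = as.integer(starts),
                          end = as.integer(starts + config$island_length))
        isl$name <- sprintf("%s_island_%02d", ch, seq_len(nrow(isl)))
        islands[[ci]] <- isl
        isl_pos <- unlist(lapply(seq_len(nrow(isl)), function(i) {
          sort(sample(seq(isl$start[i], isl$end[i] - 1L),
                      config$cpgs_per_island))
        }))
      } else {
        islands[[ci]] <- data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), name = character(0))
        isl_pos <- integer(0)
      }
      n_bg <- rpois(1, config$background_cpg_rate * L)
      bg_pos <- sort(as.integer(floor(runif(n_bg, 0, L))))
      if (config$n_islands > 0 && length(bg_pos)) {
        isl <- islands[[ci]]
        in_isl <- vapply(bg_pos, function(p) {
          any(p >= isl$start & p < isl$end)
        }, logical(1))
        bg_pos <- bg_pos[!in_isl]
      }
      pos <- sort(unique(c(isl_pos, bg_pos)))
      sites[[ci]] <- data.frame(chrom = ch, pos = as.integer(pos))
      # genes: evenly tiled, alternating strand; bodies clamped so they
      # stay disjoint and inside the chromosome whatever the config says
      ng <- config$n_genes_per_chrom
      gspace <- L / ng
      glen <- max(100L, min(config$gene_length, floor(gspace * 0.8)))
      gstart <- as.integer(round((seq_len(ng) - 1) * gspace +
                                   (gspace - glen) / 2))
      genes[[ci]] <- data.frame(
        symbol = sprintf("G%d_%03d", ci, seq_len(ng)),
        chrom = ch,
        strand = rep(c("+", "-"), length.out = ng),
        start = gstart,
        end = as.integer(gstart + glen))
      # cytobands exactly partition [0, L)
      nb <- config$n_bands_per_chrom
      cuts <- round(seq(0, L, length.out = nb + 1))
      arm <- rep(c("p", "q"), each = nb / 2)
      idx <- c(rev(seq_len(nb / 2)), seq_len(nb / 2))  # count outward from centromere? pter->qter labels
      bands[[ci]] <- data.frame(chrom = ch,
                                start = as.integer(cuts[-(nb + 1)]),
                                end = as.integer(cuts[-1]),
                                band = paste0(arm, idx, ".1"),
                                stain = "gneg")
      # nucleosome-retention regions over a fraction of gene promoters
      gi <- genes[[ci]]
      n_nuc <- round(config$nucleosome_gene_fraction * nrow(gi))
      if (n_nuc > 0) {
        pick <- sort(sample(nrow(gi), n_nuc))
        tss <- ifelse(gi$strand == "+", gi$start, gi$end - 1L)[pick]
        nucs[[ci]] <- data.frame(chrom = ch,
                                 start = pmax(0L, as.integer(tss - 500L)),
                                 end = as.integer(tss + 500L))
      } else {
        nucs[[ci]] <- data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0))
      }
    }
    g <- list(islands = do.call(rbind, islands),
              cpg_sites = do.call(rbind, sites),
              genes = {
                gg <- do.call(rbind, genes)
                gg$tss <- ifelse(gg$strand == "+", gg$start, gg$end - 1L)
                gg
              },
              cytobands = {
                bb <- do.call(rbind, bands)
                bb$name <- paste0(sub("^chr", "", bb$chrom), bb$band)
                bb
              },
              nucleosomes = do.call(rbind, nucs),
              chrom_lengths = chrom_lengths)
    class(g) <- "sim_genome"
    g
  })
}

# mean methylation fraction -> one beta-binomial fraction draw per cell
rbeta_mean <- function(n, mu, dispersion) {
  mu <- pmin(pmax(mu, 0.005), 0.995)
  if (dispersion <= 0) return(mu + numeric(n))
  theta <- 1 / dispersion - 1
  rbeta(n, mu * theta, (1 - mu) * theta)
}

# pick spiked islands and build per-site baseline/effect vectors
plan_spikes <- function(genome, config) {
  isl <- genome$islands
  counts <- vapply(seq_len(nrow(isl)), function(i) {
    sum(genome$cpg_sites$chrom == isl$chrom[i] &
          genome$cpg_sites$pos >= isl$start[i] &
          genome$cpg_sites$pos < isl$end[i])
  }, integer(1))
  eligible <- which(counts >= 3)
  n_spike <- config$n_spiked_hyper + config$n_spiked_hypo
  if (n_spike > length(eligible)) {
    stop("requested more spiked DMRs than eligible regions")
  }
  pick <- eligible[sample.int(length(eligible), n_spike)]
  list(hyper = pick[seq_len(config$n_spiked_hyper)],
       hypo = pick[config$n_spiked_hyper + seq_len(config$n_spiked_hypo)],
       cpg_counts = counts)
}

#' Simulate bisulfite read counts with spiked ground truth
#'
#' Draws, for every CpG site and sample, a methylation fraction from a
#' beta distribution centred on the site's baseline (island vs background),
#' a read depth from Poisson(`coverage_mean`), and methylated reads from a
#' binomial. Spiked regions are CpG islands: islands chosen for
#' hypermethylation keep the hypomethylated island baseline and gain
#' `+effect` in the APA group; islands chosen for hypomethylation start from
#' the methylated background baseline (methylation must exist to be lost)
#' and lose `effect` in the APA group.
#'
#' @param genome A `sim_genome` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List with elements `dataset` (a `MethylationDataset`, unfiltered —
#'   apply [filter_coverage()] or the pipeline's merge step) and `truth`
#'   (class `SyntheticTruth`: spiked spans, directions, effects, planted
#'   gene sets).
#' @export
simulate_counts <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 2L), {
    sites <- genome$cpg_sites
    n_sites <- nrow(sites)
    isl <- genome$islands
    spikes <- plan_spikes(genome, config)

    # site-level island membership
    isl_gr <- as_granges(isl)
    hits <- GenomicRanges::findOverlaps(pos_granges(sites$chrom, sites$pos),
                                        isl_gr)
    island_of <- rep(NA_integer_, n_sites)
    island_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

    baseline <- ifelse(is.na(island_of),
                       config$background_baseline_meth,
                       config$island_baseline_meth)
    effect <- numeric(n_sites)
    direction <- rep(NA_character_, n_sites)
    eff_cycle <- rep(abs(config$effect_sizes),
                     length.out = length(spikes$hyper) + length(spikes$hypo))
    k <- 0
    for (i in spikes$hyper) {
      k <- k + 1
      m <- which(island_of == i)
      effect[m] <- eff_cycle[k]
      direction[m] <- "hyper"
    }
    for (i in spikes$hypo) {
      k <- k + 1
      m <- which(island_of == i)
      baseline[m] <- config$background_baseline_meth
      effect[m] <- -eff_cycle[k]
      direction[m] <- "hypo"
    }

    n_y <- config$n_young; n_a <- config$n_apa
    ids <- c(sprintf("young_%02d", seq_len(n_y)),
             sprintf("apa_%02d", seq_len(n_a)))
    grp <- c(rep("young", n_y), rep("APA", n_a))
    age <- c(runif(n_y, config$age_range_young[1], config$age_range_young[2]),
             runif(n_a, config$age_range_apa[1], config$age_range_apa[2]))

    meth <- matrix(0L, n_sites, n_y + n_a)
    unmeth <- matrix(0L, n_sites, n_y + n_a)
    for (j in seq_len(n_y + n_a)) {
      mu <- baseline
      if (grp[j] == "APA") {
        mu <- mu + effect +
          sign(effect) * config$age_slope_per_year * max(0, age[j] - 50)
      }
      frac <- rbeta_mean(n_sites, mu / 100, config$dispersion)
      reads <- rpois(n_sites, config$coverage_mean)
      m <- rbinom(n_sites, reads, frac)
      meth[, j] <- m
      unmeth[, j] <- reads - m
    }
    dataset <- methylation_dataset(sites, meth, unmeth, ids, grp, age)

    spiked <- lapply(c(spikes$hyper, spikes$hypo), function(i) {
      m <- which(island_of == i)
      data.frame(chrom = isl$chrom[i],
                 start = min(sites$pos[m]),
                 end = max(sites$pos[m]) + 1L,
                 direction = direction[m][1],
                 effect = effect[m][1],
                 n_cpgs = length(m))
    })
    spiked <- if (length(spiked)) do.call(rbind, spiked) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 direction = character(0), effect = numeric(0),
                 n_cpgs = integer(0))
    truth <- build_truth(genome, config, spiked)
    list(dataset = dataset, truth = truth)
  })
}

# assemble the SyntheticTruth record, including planted gene sets
build_truth <- function(genome, config, spiked) {
  genes <- genome$genes
  if (nrow(spiked)) {
    prom <- gene_promoters(genes)
    body_hit <- GenomicRanges::findOverlaps(as_granges(spiked),
                                            as_granges(genes))
    prom_hit <- GenomicRanges::findOverlaps(as_granges(spiked),
                                            as_granges(prom))
    spiked_genes <- sort(unique(genes$symbol[
      c(S4Vectors::subjectHits(body_hit), S4Vectors::subjectHits(prom_hit))]))
  } else spiked_genes <- character(0)
  universe <- genes$symbol
  other <- setdiff(universe, spiked_genes)
  sets <- list(); fracs <- numeric(0)
  for (nm in names(config$gene_set_specs)) {
    spec <- config$gene_set_specs[[nm]]
    f <- spec$frac
    if (is.na(f)) f <- length(spiked_genes) / length(universe)
    n_in <- min(round(f * spec$size), length(spiked_genes))
    n_out <- min(spec$size - n_in, length(other))
    sets[[nm]] <- sort(c(spiked_genes[sample.int(length(spiked_genes), n_in)],
                         other[sample.int(length(other), n_out)]))
    fracs[nm] <- f
  }
  structure(list(spiked_dmrs = spiked,
                 spiked_genes = spiked_genes,
                 gene_sets = sets,
                 enriched_gene_sets = fracs,
                 seed = config$seed),
            class = "SyntheticTruth")
}

#' Simulate a 450K-style beta matrix with spiked ground truth
#'
#' Analogue of [simulate_counts()] for array data: beta values are drawn
#' directly from the beta noise distribution (no read sampling), one probe
#' per CpG site.
#'
#' @param genome A `sim_genome`.
#' @param config A [sim_config()]; `effect_sizes` are interpreted on the
#'   percent scale and spike the group-2 mean by `effect/100` on the beta
#'   scale.
#' @return List with `bm` (a `BetaMatrix`, groups labelled `young`/`APA`)
#'   and `truth` (a `SyntheticTruth`).
#' @export
simulate_beta_matrix <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 3L), {
    sites <- genome$cpg_sites
    n_sites <- nrow(sites)
    isl_gr <- as_granges(genome$islands)
    hits <- GenomicRanges::findOverlaps(pos_granges(sites$chrom, sites$pos),
                                        isl_gr)
    island_of <- rep(NA_integer_, n_sites)
    island_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    spikes <- plan_spikes(genome, config)
    baseline <- ifelse(is.na(island_of),
                       config$background_baseline_meth,
                       config$island_baseline_meth)
    effect <- numeric(n_sites)
    direction <- rep(NA_character_, n_sites)
    eff_cycle <- rep(abs(config$effect_sizes),
                     length.out = length(spikes$hyper) + length(spikes$hypo))
    k <- 0
    for (i in spikes$hyper) {
      k <- k + 1; m <- which(island_of == i)
      effect[m] <- eff_cycle[k]; direction[m] <- "hyper"
    }
    for (i in spikes$hypo) {
      k <- k + 1; m <- which(island_of == i)
      baseline[m] <- config$background_baseline_meth
      effect[m] <- -eff_cycle[k]; direction[m] <- "hypo"
    }
    n_y <- config$n_young; n_a <- config$n_apa
    ids <- c(sprintf("young_%02d", seq_len(n_y)),
             sprintf("apa_%02d", seq_len(n_a)))
    grp <- c(rep("young", n_y), rep("APA", n_a))
    beta <- matrix(0, n_sites, n_y + n_a)
    for (j in seq_len(n_y + n_a)) {
      mu <- baseline + if (grp[j] == "APA") effect else 0
      beta[, j] <- rbeta_mean(n_sites, mu / 100, config$dispersion)
    }
    probes <- data.frame(probe_id = sprintf("cg%07d", seq_len(n_sites)),
                         chrom = sites$chrom, pos = sites$pos)
    bm <- beta_matrix(probes, beta, ids, grp)
    spiked <- lapply(c(spikes$hyper, spikes$hypo), function(i) {
      m <- which(island_of == i)
      data.frame(chrom = sites$chrom[m][1],
                 start = min(sites$pos[m]), end = max(sites$pos[m]) + 1L,
                 direction = direction[m][1], effect = effect[m][1],
                 n_cpgs = length(m))
    })
    spiked <- if (length(spiked)) do.call(rbind, spiked) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 direction = character(0), effect = numeric(0),
                 n_cpgs = integer(0))
    list(bm = bm, truth = build_truth(genome, config, spiked))
  })
}

#' Drop sites failing a minimum per-sample coverage
#'
#' In-memory counterpart of the merge-time read-count filter: retains only
#' sites where every sample has at least `min_coverage` reads.
#'
#' @param dataset A `MethylationDataset`.
#' @param min_coverage Minimum total reads per site per sample (default 5).
#' @return Filtered `MethylationDataset`.
#' @export
filter_coverage <- function(dataset, min_coverage = 5) {
  keep <- rowSums((dataset$meth + dataset$unmeth) >= min_coverage) ==
    ncol(dataset$meth)
  if (!any(keep)) stop("no sites pass coverage in all samples")
  methylation_dataset(dataset$sites[keep, , drop = FALSE],
                      dataset$meth[keep, , drop = FALSE],
                      dataset$unmeth[keep, , drop = FALSE],
                      dataset$samples$sample_id, dataset$samples$group,
                      dataset$samples$age)
}

#' Write a simulated study to disk in the pipeline's file dialects
#'
#' Emits one Bismark-style coverage file per sample, islands/nucleosomes as
#' BED, cytobands as a UCSC-style table, gene models as refFlat-like TSV,
#' each planted gene list, a sample sheet, and a truth table.
#'
#' @param genome A `sim_genome`.
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(genome, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  for (j in seq_len(nrow(ds$samples))) {
    counts <- data.frame(chrom = ds$sites$chrom, pos = ds$sites$pos,
                         n_meth = ds$meth[, j], n_unmeth = ds$unmeth[, j])
    write_coverage_file(counts,
                        file.path(dir, paste0(ds$samples$sample_id[j],
                                              ".cov.tsv")))
  }
  write_bed(genome$islands, file.path(dir, "islands.bed"))
  write_bed(genome$nucleosomes, file.path(dir, "nucleosomes.bed"))
  write_cytobands(genome$cytobands, file.path(dir, "cytobands.tsv"))
  write_gene_models(genome$genes, file.path(dir, "genes.tsv"))
  for (nm in names(sim$truth$gene_sets)) {
    write_gene_list(sim$truth$gene_sets[[nm]],
                    file.path(dir, paste0("geneset_", nm, ".txt")))
  }
  write.table(ds$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$spiked_dmrs, file.path(dir, "truth_dmrs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
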