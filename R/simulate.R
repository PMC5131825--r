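# Synthetic-data generators: genomes, annotations, binding landscapes,
# AP-MS count matrices and expression matrices with planted ground truth,
# so that every downstream analysis is testable without external data.

#' Configuration for the synthetic world
#'
#' Bundles every tunable of the generators with defaults chosen to emulate
#' the statistical structure of the study's inputs at desk scale: a small
#' multi-chromosome genome, proteins organised in planted binding-site
#' clusters with replicate ChIP experiments, planted PWMs occurring at a
#' fraction of summits, ERE annotation with class structure, SNPs depleted
#' inside motif occurrences, AP-MS counts with planted interaction modules
#' plus contaminant preys, and expression shifted for bound-promoter genes.
#'
#' @param genome_length Bases per chromosome (default 3e5).
#' @param n_chromosomes Number of chromosomes (default 2).
#' @param dinucleotide_bias 4x4 transition matrix P(next | previous), rows
#'   and columns in A, C, G, T order; rows must sum to 1 (default uniform).
#' @param n_proteins Number of proteins (default 12).
#' @param n_clusters Planted binding-site clusters (default 3).
#' @param peaks_per_protein True binding sites per protein (default 150).
#' @param replicates_per_protein ChIP replicates per protein (default 2).
#' @param within_cluster_jaccard Target base-pair Jaccard of same-cluster
#'   protein pairs (default 0.5).
#' @param between_cluster_jaccard Target for different-cluster pairs
#'   (default 0.02); must be below the within-cluster target.
#' @param peak_width Width of every true site, bp (default 200).
#' @param motif_length PWM columns (default 16, matching the long motifs
#'   typical of C2H2-ZF arrays).
#' @param motif_fraction Fraction of a protein's sites carrying a planted
#'   motif occurrence at the summit (default 0.7).
#' @param summit_jitter_sd SD of the replicate summit jitter in bp
#'   (default 10).
#' @param peak_dropout Probability a replicate misses a true site
#'   (default 0.1).
#' @param ere_classes Tibble/data frame with columns `class`,
#'   `instance_count`, `instance_length`.
#' @param ere_site_fraction Fraction of each cluster's binding sites placed
#'   inside instances of the cluster's preferred ERE class (default 0.3).
#' @param n_tss Number of genes/TSS (default 400).
#' @param n_dhs Number of DHS intervals (default 200).
#' @param dhs_width DHS width, bp (default 300).
#' @param snp_density SNPs per bp (default 0.005).
#' @param snp_depletion_factor Multiplier in (0, 1\] applied to SNP density
#'   inside motif occurrences (default 0.3).
#' @param ppi_modules List of planted interaction modules, each a list with
#'   `baits` (indices into proteins), `preys` (prey labels) and
#'   `mean_count` (Poisson mean). Default: one module per cluster linking
#'   its proteins to 6 module-specific preys at mean 30.
#' @param contaminant_prey_count Ubiquitous contaminant preys (default 10).
#' @param contaminant_mean Poisson mean of contaminant counts per replicate
#'   (default 20; abundant ubiquitous contaminants are what the
#'   low-variation filter targets).
#' @param background_mean Poisson mean of non-planted counts (default 0.2).
#' @param ppi_profile_sd Log-normal SD of the per-pair interaction strength
#'   multiplier (default 0.8); gives each bait an individual profile that
#'   its replicates share, as real AP-MS profiles do.
#' @param n_negative_control_baits Negative-control baits (default 3).
#' @param ppi_replicates AP-MS replicates per bait (default 2).
#' @param promoter_distance TSS-proximity radius (bp) used by [sim_world()]
#'   to derive bound-promoter gene sets (default 500). The 10 kb radius used
#'   on real data would cover every gene of a desk-scale genome; 500 bp
#'   keeps the bound fraction of genes realistic at the synthetic gene
#'   spacing.
#' @param expression_effect Log-scale shift of bound-promoter genes in the
#'   matching induction (default 1).
#' @param expression_noise_sd Log-scale expression noise SD (default 0.5).
#' @param seed Integer seed (default 1).
#' @return A validated list of class `zf_sim_config`.
#' @export
sim_world_config <- function(genome_length = 3e5,
                             n_chromosomes = 2,
                             dinucleotide_bias = matrix(0.25, 4, 4),
                             n_proteins = 12,
                             n_clusters = 3,
                             peaks_per_protein = 150,
                             replicates_per_protein = 2,
                             within_cluster_jaccard = 0.5,
                             between_cluster_jaccard = 0.02,
                             peak_width = 200,
                             motif_length = 16,
                             motif_fraction = 0.7,
                             summit_jitter_sd = 10,
                             peak_dropout = 0.1,
                             ere_classes = data.frame(
                               class = c("LINE", "SINE", "LTR"),
                               instance_count = c(60, 120, 40),
                               instance_length = c(500, 300, 400)),
                             ere_site_fraction = 0.3,
                             n_tss = 400,
                             n_dhs = 200,
                             dhs_width = 300,
                             snp_density = 0.005,
                             snp_depletion_factor = 0.3,
                             ppi_modules = NULL,
                             contaminant_prey_count = 10,
                             contaminant_mean = 20,
                             background_mean = 0.2,
                             ppi_profile_sd = 0.8,
                             n_negative_control_baits = 3,
                             ppi_replicates = 2,
                             promoter_distance = 500,
                             expression_effect = 1,
                             expression_noise_sd = 0.5,
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(genome_length, n_chromosomes, n_proteins, n_clusters,
              peaks_per_protein, replicates_per_protein, peak_width,
              motif_length, n_tss, n_dhs, ppi_replicates)
  if (any(counts <= 0)) abort("all counts must be positive")
  probs <- c(within_cluster_jaccard, between_cluster_jaccard,
             motif_fraction, peak_dropout, ere_site_fraction,
             snp_depletion_factor)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  if (snp_depletion_factor <= 0) abort("snp_depletion_factor must be in (0, 1]")
  if (within_cluster_jaccard <= between_cluster_jaccard) {
    abort("within_cluster_jaccard must exceed between_cluster_jaccard")
  }
  db <- as.matrix(dinucleotide_bias)
  if (!all(dim(db) == c(4, 4)) || any(db < 0) ||
      any(abs(rowSums(db) - 1) > 1e-6)) {
    abort("dinucleotide_bias rows must be probabilities summing to 1")
  }
  if (is.null(cfg$ppi_modules)) {
    cl <- cluster_assignment(n_proteins, n_clusters)
    cfg$ppi_modules <- lapply(seq_len(n_clusters), function(c) {
      list(baits = which(cl == c),
           preys = paste0("modprey_", c, "_", 1:6),
           mean_count = 30)
    })
  }
  structure(cfg, class = "zf_sim_config")
}

cluster_assignment <- function(n_proteins, n_clusters) {
  rep_len(seq_len(n_clusters), n_proteins)[order(rep_len(seq_len(n_clusters),
                                                         n_proteins))]
}

protein_labels <- function(cfg) sprintf("ZNF%03d", seq_len(cfg$n_proteins))

#' Generate a genome as a first-order Markov chain
#'
#' Per-chromosome sequences over A/C/G/T whose dinucleotide frequencies
#' converge to the configured transition matrix as length grows. A uniform
#' bias reduces to i.i.d. sampling (vectorised); a non-uniform bias walks
#' the chain.
#'
#' @param config A `zf_sim_config`.
#' @return Named character vector of chromosome sequences (chr1, chr2, ...).
#' @export
sim_genome <- function(config) {
  if (config$genome_length < 1e4) abort("genome_length must be >= 10 kb")
  set.seed(config$seed)
  db <- as.matrix(config$dinucleotide_bias)
  uniform <- max(abs(db - 0.25)) < 1e-12
  # stationary distribution of the chain for the first base
  ev <- eigen(t(db))
  stat <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
  stat <- stat / sum(stat)
  seqs <- vapply(seq_len(config$n_chromosomes), function(ch) {
    L <- config$genome_length
    if (uniform) {
      return(paste(DNA[sample.int(4, L, replace = TRUE)], collapse = ""))
    }
    cdf <- t(apply(db, 1, cumsum))
    u <- runif(L)
    b <- integer(L)
    b[1] <- findInterval(u[1], cumsum(stat)) + 1L
    for (i in 2:L) b[i] <- findInterval(u[i], cdf[b[i - 1L], ],
                                        rightmost.closed = TRUE) + 1L
    b[b > 4L] <- 4L
    paste(DNA[b], collapse = "")
  }, character(1))
  stats::setNames(seqs, paste0("chr", seq_len(config$n_chromosomes)))
}

# Sample k non-overlapping intervals of width w: the genome is tiled into
# width-w cells and k cells are drawn without replacement, guaranteeing
# non-overlap in O(genome/w). Returns a chrom/start/end tibble.
place_intervals <- function(lens, k, w) {
  if (k == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (k * w > 0.8 * sum(lens)) abort("requested annotation mass exceeds genome")
  cells <- bind_rows(lapply(names(lens), function(ch) {
    starts <- seq(0, lens[[ch]] - w, by = w)
    tibble(chrom = ch, start = starts, end = starts + w)
  }))
  if (k > nrow(cells)) abort("could not place non-overlapping intervals")
  cells[sample.int(nrow(cells), k), ]
}

#' Plant ERE, TSS, DHS and SNP annotations on a genome
#'
#' EREs are non-overlapping within each class; TSS are points; DHS are
#' intervals; SNP positions are drawn per base at `snp_density` and thinned
#' by `snp_depletion_factor` inside the supplied motif-occurrence intervals
#' (no thinning when `motif_intervals` is NULL). All coordinates 0-based
#' half-open within chromosome bounds.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param config A `zf_sim_config`.
#' @param motif_intervals Optional interval tibble of planted motif
#'   occurrences inside which SNPs are depleted.
#' @return List with `ere` (tibble with `class` column), `tss` (chrom,
#'   pos), `dhs`, `snps` (chrom, pos).
#' @export
sim_annotations <- function(genome, config, motif_intervals = NULL) {
  set.seed(config$seed + 1L)
  lens <- chrom_lengths(genome)
  ec <- as.data.frame(config$ere_classes)
  if (sum(ec$instance_count * ec$instance_length) > 0.8 * sum(lens)) {
    abort("requested ERE mass exceeds genome length")
  }
  ere <- bind_rows(lapply(seq_len(nrow(ec)), function(i) {
    x <- place_intervals(lens, ec$instance_count[i], ec$instance_length[i])
    if (nrow(x) > 0) x$class <- ec$class[i]
    x
  }))
  tss <- bind_rows(lapply(names(lens), function(ch) {
    k <- round(config$n_tss * lens[[ch]] / sum(lens))
    tibble(chrom = ch, pos = sort(floor(runif(k, 0, lens[[ch]]))))
  }))
  dhs <- place_intervals(lens, config$n_dhs, config$dhs_width)
  snps <- sim_snps(genome, config, motif_intervals)
  list(ere = ere, tss = tss, dhs = dhs, snps = snps)
}

#' Draw SNP positions with configurable depletion inside motif occurrences
#'
#' @inheritParams sim_annotations
#' @return Tibble `chrom`, `pos`.
#' @export
sim_snps <- function(genome, config, motif_intervals = NULL) {
  set.seed(config$seed + 2L)
  lens <- chrom_lengths(genome)
  mi <- if (!is.null(motif_intervals) && nrow(motif_intervals) > 0) {
    merge_intervals(motif_intervals)
  } else NULL
  bind_rows(lapply(names(lens), function(ch) {
    hit <- which(runif(lens[[ch]]) < config$snp_density) - 1L
    if (!is.null(mi)) {
      inside <- count_mask(hit, mi[mi$chrom == ch, ])
      drop <- inside & runif(length(hit)) > config$snp_depletion_factor
      hit <- hit[!drop]
    }
    tibble(chrom = ch, pos = as.numeric(hit))
  }))
}

count_mask <- function(pos, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, intervals$start)
  idx >= 1 & pos < intervals$end[pmax(idx, 1)]
}

#' Generate the binding landscape: peaks, replicates, planted PWMs
#'
#' Each protein is assigned to one of `n_clusters` planted clusters.
#' Binding sites are drawn from three non-overlapping pools so that the
#' expected base-pair Jaccard between same-cluster proteins matches
#' `within_cluster_jaccard` and between different-cluster proteins matches
#' `between_cluster_jaccard` (exact when jitter and dropout are zero): a
#' global pool shared by all proteins, a per-cluster pool, and private
#' sites. A fraction of each cluster's sites is placed inside instances of
#' the cluster's preferred ERE class. Each cluster carries one planted
#' sharp PWM; an occurrence sampled from it is written into the genome at
#' the summit of `motif_fraction` of the cluster's sites. Replicate peak
#' sets are jittered copies of the truth (summit noise, dropout), with
#' positive MACS-like scores.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param annotations Annotation bundle from [sim_annotations()] (EREs used
#'   for site placement); may be NULL.
#' @param config A `zf_sim_config`.
#' @return List with `peaks` (tibble: protein, replicate, chrom, start,
#'   end, summit, score), `truth_sites` (per-protein true sites with
#'   `has_motif`), `pwms` (one `zf_pwm` per protein), `motif_intervals`
#'   (planted occurrence intervals), `clusters` (tibble protein, cluster)
#'   and `genome` (with occurrences written in).
#' @export
sim_binding_landscape <- function(genome, annotations, config) {
  set.seed(config$seed + 3L)
  lens <- chrom_lengths(genome)
  N <- config$peaks_per_protein
  w <- config$peak_width
  jw <- config$within_cluster_jaccard
  jb <- config$between_cluster_jaccard
  n_shared_total <- round(2 * N * jw / (1 + jw))  # global + cluster pool
  n_global <- round(2 * N * jb / (1 + jb))
  n_cluster <- max(n_shared_total - n_global, 0)
  n_private <- N - n_global - n_cluster
  if (n_private < 0) abort("jaccard targets incompatible with peaks_per_protein")
  prots <- protein_labels(config)
  cl <- cluster_assignment(config$n_proteins, config$n_clusters)
  ere <- if (!is.null(annotations)) annotations$ere else NULL
  ere_classes <- if (!is.null(ere)) unique(ere$class) else character()

  # one pool of non-overlapping slots for all sites, so shared/private
  # sites never collide and bp Jaccard is exact
  n_slots <- n_global + config$n_clusters * n_cluster +
    config$n_proteins * n_private
  slots_free <- place_intervals(lens, n_slots, w)
  slots_free <- slots_free[sample.int(nrow(slots_free)), ]
  take <- local({
    i <- 0L
    function(k) {
      out <- slots_free[i + seq_len(k), ]
      i <<- i + k
      out
    }
  })
  # per cluster, relocate a fraction of its sites into its preferred ERE
  # class (replaces the uniform slot with one inside an instance)
  relocate_into_ere <- function(sites, cls) {
    if (is.null(ere) || length(ere_classes) == 0 ||
        config$ere_site_fraction == 0) return(sites)
    pref <- ere_classes[(cls - 1L) %% length(ere_classes) + 1L]
    inst <- ere[ere$class == pref & (ere$end - ere$start) >= w, ]
    if (nrow(inst) == 0) return(sites)
    k <- round(config$ere_site_fraction * nrow(sites))
    if (k == 0) return(sites)
    pick <- sample.int(nrow(inst), k, replace = nrow(inst) < k)
    off <- floor(runif(k, 0, inst$end[pick] - inst$start[pick] - w + 1))
    sites$start[seq_len(k)] <- inst$start[pick] + off
    sites$end[seq_len(k)] <- sites$start[seq_len(k)] + w
    sites$chrom[seq_len(k)] <- inst$chrom[pick]
    sites
  }

  global_sites <- take(n_global)
  cluster_sites <- lapply(seq_len(config$n_clusters), function(c) {
    relocate_into_ere(take(n_cluster), c)
  })
  pwms <- lapply(seq_len(config$n_clusters), function(c) {
    sharp_random_pwm(config$motif_length, name = sprintf("cluster%d", c))
  })

  truth <- vector("list", config$n_proteins)
  motif_iv <- list()
  for (p in seq_len(config$n_proteins)) {
    sites <- bind_rows(global_sites, cluster_sites[[cl[p]]], take(n_private))
    sites$summit <- floor((sites$start + sites$end) / 2)
    sites$has_motif <- runif(nrow(sites)) < config$motif_fraction
    sites$protein <- prots[p]
    truth[[p]] <- sites
  }
  truth <- bind_rows(truth)
  # implant one PWM draw at each motif-carrying summit (sites shared across
  # proteins of a cluster receive the cluster motif once; implanting twice
  # is idempotent up to the sampled instance, so dedupe by location)
  imp <- truth[truth$has_motif, c("chrom", "summit", "protein")]
  imp$cluster <- cl[match(imp$protein, prots)]
  imp <- imp[!duplicated(imp[, c("chrom", "summit", "cluster")]), ]
  L <- config$motif_length
  for (i in seq_len(nrow(imp))) {
    inst <- sample_pwm_instance(pwms[[imp$cluster[i]]])
    s <- imp$summit[i] - floor(L / 2)
    if (s < 0 || s + L > lens[[imp$chrom[i]]]) next
    substr(genome[[imp$chrom[i]]], s + 1, s + L) <- inst
    motif_iv[[length(motif_iv) + 1L]] <-
      tibble(chrom = imp$chrom[i], start = s, end = s + L)
  }
  motif_intervals <- if (length(motif_iv) > 0) bind_rows(motif_iv) else
    tibble(chrom = character(), start = numeric(), end = numeric())

  # replicate peak sets: dropout + summit jitter + positive scores; sites
  # carrying the motif lean toward higher scores so top-peak analyses see
  # motif-enriched peaks
  base_score <- rgamma(nrow(truth), shape = 2, scale = 40) + 20 +
    30 * truth$has_motif
  peaks <- bind_rows(lapply(seq_len(config$replicates_per_protein), function(r) {
    keep <- runif(nrow(truth)) >= config$peak_dropout
    t2 <- truth[keep, ]
    jit <- round(rnorm(nrow(t2), 0, config$summit_jitter_sd))
    clen <- lens[as.character(t2$chrom)]
    summit <- pmin(pmax(t2$summit + jit, 0), clen - 1)
    start <- pmax(summit - floor(w / 2), 0)
    end <- pmin(start + w, clen)
    start <- pmax(end - w, 0)  # keep full width unless the chromosome is short
    tibble(protein = t2$protein, replicate = r, chrom = t2$chrom,
           start = unname(start), end = unname(end), summit = unname(summit),
           score = base_score[keep] * exp(rnorm(nrow(t2), 0, 0.2)))
  }))
  list(peaks = peaks,
       truth_sites = truth,
       pwms = stats::setNames(lapply(seq_len(config$n_proteins),
                                     function(p) pwms[[cl[p]]]), prots),
       motif_intervals = motif_intervals,
       clusters = tibble(protein = prots, cluster = cl),
       genome = genome)
}

# A sharp random PWM: one dominant base per column at `sharp`, the rest
# uniform.
sharp_random_pwm <- function(L, sharp = 0.85, name = "planted") {
  m <- matrix((1 - sharp) / 3, 4, L)
  dom <- sample.int(4, L, replace = TRUE)
  m[cbind(dom, seq_len(L))] <- sharp
  pwm(m, name = name)
}

sample_pwm_instance <- function(x) {
  m <- x$matrix
  paste(DNA[apply(m, 2, function(p) sample.int(4, 1, prob = p))],
        collapse = "")
}

#' Generate an AP-MS spectral-count matrix with planted interactions
#'
#' Planted bait-prey module pairs draw counts from Poisson(mean_count);
#' contaminant preys draw low-mean counts in every bait including the
#' negative controls; all other cells draw from a small background mean.
#' Replicates are independent draws.
#'
#' @param config A `zf_sim_config`.
#' @return List with `counts` (long tibble: bait, prey, replicate, count),
#'   `truth` (tibble bait, prey, planted), `control_baits`.
#' @export
sim_ppi_counts <- function(config) {
  set.seed(config$seed + 4L)
  prots <- protein_labels(config)
  ctrl <- if (config$n_negative_control_baits > 0) {
    sprintf("CTRL%02d", seq_len(config$n_negative_control_baits))
  } else character()
  baits <- c(prots, ctrl)
  mod_preys <- unique(unlist(lapply(config$ppi_modules, `[[`, "preys")))
  cont <- if (config$contaminant_prey_count > 0) {
    sprintf("contam_%02d", seq_len(config$contaminant_prey_count))
  } else character()
  preys <- c(mod_preys, cont)
  mu <- matrix(config$background_mean, length(baits), length(preys),
               dimnames = list(baits, preys))
  planted <- matrix(FALSE, length(baits), length(preys),
                    dimnames = list(baits, preys))
  if (length(cont) > 0) mu[, cont] <- config$contaminant_mean
  for (mod in config$ppi_modules) {
    # per-pair strength multiplier: shared by replicates, not by baits, so
    # every bait keeps an individual profile over the module preys
    np <- length(mod$baits) * length(mod$preys)
    mu[prots[mod$baits], mod$preys] <- mod$mean_count *
      exp(rnorm(np, 0, config$ppi_profile_sd))
    planted[prots[mod$baits], mod$preys] <- TRUE
  }
  counts <- bind_rows(lapply(seq_len(config$ppi_replicates), function(r) {
    tibble(bait = rep(baits, times = length(preys)),
           prey = rep(preys, each = length(baits)),
           replicate = r,
           count = stats::rpois(length(mu), as.vector(mu)))
  }))
  truth <- tibble(bait = rep(baits, times = length(preys)),
                  prey = rep(preys, each = length(baits)),
                  planted = as.vector(planted))
  list(counts = counts, truth = truth, control_baits = ctrl)
}

#' Genes whose promoter lies within a distance of a protein's peaks
#'
#' @param peaks Peak tibble with `protein`.
#' @param tss Tibble `chrom`, `pos` (one gene per TSS, named gene_1, ... in
#'   TSS order) or with an explicit `gene` column.
#' @param distance Maximum TSS distance in bp (default 10000, i.e. a
#'   promoter within 10 kb).
#' @return Named list: protein -> character vector of bound genes.
#' @export
bound_promoter_genes <- function(peaks, tss, distance = 1e4) {
  if (!"gene" %in% names(tss)) tss$gene <- paste0("gene_", seq_len(nrow(tss)))
  lapply(split(peaks, peaks$protein), function(p) {
    hit <- logical(nrow(tss))
    for (ch in unique(p$chrom)) {
      ti <- which(tss$chrom == ch)
      if (length(ti) == 0) next
      s <- p$summit[p$chrom == ch]
      near <- vapply(tss$pos[ti],
                     function(x) any(abs(s - x) <= distance), TRUE)
      hit[ti] <- near
    }
    tss$gene[hit]
  })
}

#' Generate an expression matrix with bound-promoter genes shifted
#'
#' One gene per TSS. Baseline log-scale abundance per gene plus Gaussian
#' noise per condition; in the induction of protein i, genes whose promoter
#' is bound by protein i shift by `expression_effect`.
#'
#' @param annotations Annotation bundle (for the TSS table) or a tibble of
#'   TSS.
#' @param bound_promoter_sets Named list protein -> bound gene vector (see
#'   [bound_promoter_genes()]).
#' @param config A `zf_sim_config`.
#' @return List with `expr` (long tibble: gene, condition, expression) and
#'   `truth` (the bound sets used).
#' @export
sim_expression <- function(annotations, bound_promoter_sets, config) {
  set.seed(config$seed + 5L)
  tss <- if (is.data.frame(annotations)) annotations else annotations$tss
  if (!"gene" %in% names(tss)) tss$gene <- paste0("gene_", seq_len(nrow(tss)))
  genes <- tss$gene
  base <- rnorm(length(genes), 8, 1)
  mk <- function(cond, shift_genes = character()) {
    tibble(gene = genes, condition = cond,
           expression = base + rnorm(length(genes), 0,
                                     config$expression_noise_sd) +
             config$expression_effect * (genes %in% shift_genes))
  }
  expr <- bind_rows(
    mk("control"),
    bind_rows(lapply(names(bound_promoter_sets), function(b) {
      mk(b, bound_promoter_sets[[b]])
    }))
  )
  list(expr = expr, truth = bound_promoter_sets)
}

#' Generate the complete synthetic world
#'
#' Runs every generator in order (genome, ERE/TSS/DHS annotation, binding
#' landscape with planted motifs, SNPs depleted inside the planted motif
#' occurrences, AP-MS counts, expression) and returns data plus ground
#' truth for every stage. Deterministic given the config seed.
#'
#' @param config A `zf_sim_config` (default: `sim_world_config()`).
#' @return List with `genome`, `annotations`, `binding`, `ppi`,
#'   `expression`, `bound_genes` and `config`.
#' @export
sim_world <- function(config = sim_world_config()) {
  genome <- sim_genome(config)
  ann <- sim_annotations(genome, config)  # SNPs regenerated after planting
  binding <- sim_binding_landscape(genome, ann, config)
  ann$snps <- sim_snps(binding$genome, config, binding$motif_intervals)
  ppi <- sim_ppi_counts(config)
  bound <- bound_promoter_genes(binding$peaks, ann$tss,
                                distance = config$promoter_distance)
  expr <- sim_expression(ann, bound, config)
  list(genome = binding$genome, annotations = ann, binding = binding,
       ppi = ppi, expression = expr, bound_genes = bound, config = config)
}
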