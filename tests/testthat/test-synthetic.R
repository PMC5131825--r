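# The synthetic-data generators: genome composition, annotations with SNP
# depletion, planted binding clusters, PPI counts, expression shifts, and
# end-to-end determinism.

# local helpers
total_bp_of <- function(x) sum(merge_intervals(x)$end -
                                 merge_intervals(x)$start)
count_in <- function(snps, intervals) {
  mi <- merge_intervals(intervals)
  n <- 0
  for (ch in unique(snps$chrom)) {
    pos <- snps$pos[snps$chrom == ch]
    sub <- mi[mi$chrom == ch, ]
    idx <- findInterval(pos, sub$start)
    n <- n + sum(idx >= 1 & pos < sub$end[pmax(idx, 1)])
  }
  n
}

test_that("uniform-bias genomes have near-uniform dinucleotide frequencies", {
  cfg <- sim_world_config(genome_length = 5e5, n_chromosomes = 1, seed = 30)
  g <- sim_genome(cfg)
  counts <- dinucleotide_counts(g[["chr1"]])
  freqs <- counts / sum(counts)
  # each frequency within 3 SE of 1/16
  se <- sqrt((1 / 16) * (15 / 16) / sum(counts))
  expect_true(all(abs(freqs - 1 / 16) < 3.5 * se))
})

test_that("genomes are deterministic given the seed", {
  cfg <- sim_world_config(genome_length = 1e4, seed = 31)
  expect_identical(sim_genome(cfg), sim_genome(cfg))
  cfg2 <- sim_world_config(genome_length = 1e4, seed = 32)
  expect_false(identical(sim_genome(cfg), sim_genome(cfg2)))
})

test_that("a forced-zero transition makes the dinucleotide absent", {
  bias <- matrix(0.25, 4, 4)
  bias[2, ] <- c(0.4, 0.3, 0, 0.3)  # P(G | C) = 0
  cfg <- sim_world_config(genome_length = 1e4, n_chromosomes = 1,
                          dinucleotide_bias = bias, seed = 33)
  g <- sim_genome(cfg)
  expect_equal(unname(dinucleotide_counts(g[["chr1"]])[["CG"]]), 0)
  # invalid rows rejected
  bad <- matrix(0.3, 4, 4)
  expect_error(sim_world_config(dinucleotide_bias = bad), "sum")
})

test_that("annotation masses and bounds are validated", {
  cfg <- small_world_config()
  g <- sim_genome(cfg)
  ann <- sim_annotations(g, cfg)
  lens <- stats::setNames(nchar(g), names(g))
  for (x in list(ann$ere, ann$dhs)) {
    expect_true(all(x$start >= 0))
    expect_true(all(x$end <= lens[as.character(x$chrom)]))
  }
  # EREs non-overlapping within each class
  for (cl in unique(ann$ere$class)) {
    sub <- ann$ere[ann$ere$class == cl, ]
    expect_equal(total_bp_of(sub), nrow(sub) * (sub$end[1] - sub$start[1]))
  }
  # a zero-count class yields no intervals
  cfg0 <- small_world_config()
  cfg0$ere_classes$instance_count[1] <- 0
  ann0 <- sim_annotations(g, cfg0)
  expect_equal(sum(ann0$ere$class == cfg0$ere_classes$class[1]), 0)
  # over-full annotation mass rejected
  cfg_big <- small_world_config()
  cfg_big$ere_classes$instance_count <- c(1000, 1000)
  cfg_big$ere_classes$instance_length <- c(400, 400)
  expect_error(sim_annotations(g, cfg_big), "exceeds")
})

test_that("SNP density is thinned by the depletion factor inside motifs", {
  lens <- c(chr1 = 2e5)
  motif <- tibble::tibble(chrom = "chr1", start = (0:999) * 200,
                          end = (0:999) * 200 + 100)  # 1e5 bp inside
  ratios <- vapply(1:20, function(s) {
    cfg <- sim_world_config(snp_density = 0.01, snp_depletion_factor = 0.3,
                            seed = s)
    snps <- sim_snps(lens, cfg, motif)
    inside <- count_in(snps, motif)
    dens_in <- inside / 1e5
    dens_out <- (nrow(snps) - inside) / 1e5
    dens_in / dens_out
  }, numeric(1))
  expect_equal(mean(ratios), 0.3, tolerance = 0.05)
  # factor 1 leaves densities equal
  cfg1 <- sim_world_config(snp_density = 0.01, snp_depletion_factor = 1,
                           seed = 1)
  snps1 <- sim_snps(lens, cfg1, motif)
  r1 <- (count_in(snps1, motif) / 1e5) /
    ((nrow(snps1) - count_in(snps1, motif)) / 1e5)
  expect_equal(r1, 1, tolerance = 0.15)
})

test_that("binding landscape hits its Jaccard targets", {
  # no jitter, no dropout: within-cluster Jaccard is exact
  cfg <- small_world_config(summit_jitter_sd = 0, peak_dropout = 0,
                            within_cluster_jaccard = 1,
                            between_cluster_jaccard = 0.01)
  w <- sim_world(cfg)
  m <- as.matrix(jaccard_matrix(w$binding$peaks))
  cl <- w$binding$clusters$cluster
  same <- outer(cl, cl, "==") & upper.tri(m)
  expect_true(all(m[same] == 1))

  # replicates identical to the truth set without noise
  pk <- w$binding$peaks
  r1 <- pk[pk$protein == "ZNF001" & pk$replicate == 1,
           c("chrom", "start", "end")]
  truth <- w$binding$truth_sites[w$binding$truth_sites$protein == "ZNF001",
                                 c("chrom", "start", "end")]
  expect_equal(interval_jaccard(r1, truth), 1)

  # realized Jaccard within +-0.1 of the 0.5 / 0.02 targets (12 proteins,
  # 3 clusters, default jitter), averaged over seeds
  vals <- vapply(1:5, function(s) {
    cfg2 <- sim_world_config(seed = s)
    w2 <- sim_world(cfg2)
    m2 <- as.matrix(jaccard_matrix(w2$binding$peaks))
    cl2 <- w2$binding$clusters$cluster
    c(within = mean(m2[outer(cl2, cl2, "==") & upper.tri(m2)]),
      between = mean(m2[outer(cl2, cl2, "!=") & upper.tri(m2)]))
  }, numeric(2))
  expect_lt(abs(mean(vals["within", ]) - 0.5), 0.1)
  expect_lt(abs(mean(vals["between", ]) - 0.02), 0.1)
})

test_that("PPI counts carry planted modules, Poisson noise and truth", {
  cfg <- sim_world_config(seed = 34)
  pp <- sim_ppi_counts(cfg)
  expect_true(all(pp$counts$count >= 0))
  expect_true(all(pp$counts$count == round(pp$counts$count)))
  # contaminant preys look Poisson across baits: variance ~ mean
  m <- t(vapply(split(pp$counts, pp$counts$prey), function(s) {
    c(mean = mean(s$count), var = stats::var(s$count))
  }, numeric(2)))
  cont <- grepl("contam", rownames(m))
  disp <- m[cont, "var"] / m[cont, "mean"]
  expect_lt(abs(mean(disp) - 1), 0.35)
  # a zero-mean module yields zero counts
  cfg0 <- sim_world_config(
    ppi_modules = list(list(baits = 1:2, preys = "deadprey",
                            mean_count = 0)),
    contaminant_prey_count = 2, seed = 35)
  pp0 <- sim_ppi_counts(cfg0)
  dead <- pp0$counts$prey == "deadprey" &
    pp0$counts$bait %in% c("ZNF001", "ZNF002")
  expect_true(all(pp0$counts$count[dead] == 0))
  # truth marks exactly the planted pairs
  expect_true(all(c("bait", "prey", "planted") %in% names(pp$truth)))
  expect_gt(sum(pp$truth$planted), 0)
})

test_that("expression shifts bound genes by the configured effect", {
  tss <- tibble::tibble(chrom = "chr1", pos = seq(1000, 400000, by = 1000))
  bound <- list(ZNF001 = paste0("gene_", 1:200))
  cfg <- sim_world_config(expression_effect = 1, seed = 36)
  ex <- sim_expression(tss, bound, cfg)
  wide <- tidyr::pivot_wider(ex$expr, names_from = "condition",
                             values_from = "expression")
  delta <- wide$ZNF001 - wide$control
  is_bound <- wide$gene %in% bound$ZNF001
  expect_equal(stats::median(delta[is_bound]), 1, tolerance = 0.15)
  expect_equal(stats::median(delta[!is_bound]), 0, tolerance = 0.15)
  # negative effects shift down
  cfg_dn <- sim_world_config(expression_effect = -2, seed = 36)
  ex2 <- sim_expression(tss, bound, cfg_dn)
  wide2 <- tidyr::pivot_wider(ex2$expr, names_from = "condition",
                              values_from = "expression")
  expect_lt(stats::median((wide2$ZNF001 - wide2$control)[is_bound]), -1)
  # zero effect: downstream test is null-calibrated
  cfg00 <- sim_world_config(expression_effect = 0, seed = 37)
  ex0 <- sim_expression(tss, bound, cfg00)
  res <- expression_response_test(ex0$expr, bound)
  expect_false(any(res$significant))
})

test_that("the whole synthetic world is deterministic given config + seed", {
  cfg <- small_world_config(seed = 38)
  w1 <- sim_world(cfg)
  w2 <- sim_world(cfg)
  expect_identical(w1$genome, w2$genome)
  expect_identical(w1$binding$peaks, w2$binding$peaks)
  expect_identical(w1$ppi$counts, w2$ppi$counts)
  expect_identical(w1$expression$expr, w2$expression$expr)
  expect_identical(w1$annotations$snps, w2$annotations$snps)
})

test_that("generators return their ground truth alongside the data", {
  w <- sim_world(small_world_config(seed = 39))
  expect_true(all(c("peaks", "truth_sites", "pwms", "motif_intervals",
                    "clusters") %in% names(w$binding)))
  expect_s3_class(w$binding$truth_sites, "tbl_df")
  expect_equal(sort(unique(w$binding$clusters$cluster)), 1:2)
  expect_true(all(c("counts", "truth", "control_baits") %in% names(w$ppi)))
  # all emitted intervals respect chromosome bounds
  lens <- stats::setNames(nchar(w$genome), names(w$genome))
  for (x in list(w$binding$peaks, w$binding$motif_intervals,
                 w$annotations$ere, w$annotations$dhs)) {
    if (nrow(x) == 0) next
    expect_true(all(x$start >= 0 & x$start < x$end))
    expect_true(all(x$end <= lens[as.character(x$chrom)]))
  }
})
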