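# Genomic-context statistics of binding sites: feature fold-enrichment,
# histone fold-change, ERE overlap/enrichment, SNP depletion.

#' Fold-enrichment of binding sites around genomic feature points
#'
#' Histograms the signed distance from each site summit to its nearest
#' feature point (TSS, DHS centre, ...) and divides bin-wise by the same
#' histogram for uniformly drawn random genomic points (matched count, same
#' chromosomes). Bins with zero random mass are reported as NA, not
#' infinite.
#'
#' @param sites Peak tibble with `summit`.
#' @param feature_points Tibble with `chrom`, `pos`.
#' @param genome Named character vector of chromosome sequences, or a named
#'   numeric vector of chromosome lengths.
#' @param max_dist Distance range considered, bp (default 5000).
#' @param n_bins Number of distance bins (default 50).
#' @param n_random Number of random points (default: matched to sites).
#' @param seed Optional seed for the random points.
#' @return Tibble: `bin_mid`, `site_count`, `random_count`, `fold`.
#' @export
feature_fold_enrichment <- function(sites, feature_points, genome,
                                    max_dist = 5000, n_bins = 50,
                                    n_random = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(genome)
  pts <- tibble(chrom = as.character(sites$chrom), pos = sites$summit)
  n_random <- n_random %||% nrow(pts)
  # random points on the same chromosomes, matched per-chromosome counts
  rnd <- lapply(split(pts, pts$chrom), function(p) {
    k <- round(n_random * nrow(p) / nrow(pts))
    tibble(chrom = p$chrom[1],
           pos = floor(runif(max(k, 1), 0, lens[[p$chrom[1]]])))
  })
  rnd <- bind_rows(rnd)
  breaks <- seq(-max_dist, max_dist, length.out = n_bins + 1)
  hist_of <- function(p) {
    d <- nearest_signed_distance(p, feature_points)
    d <- d[!is.na(d) & d >= -max_dist & d <= max_dist]
    tabulate(findInterval(d, breaks, rightmost.closed = TRUE), n_bins)
  }
  h_site <- hist_of(pts)
  h_rand <- hist_of(rnd)
  # normalise to densities so unequal point counts cancel
  f_site <- h_site / max(sum(h_site), 1)
  f_rand <- h_rand / max(sum(h_rand), 1)
  tibble(bin_mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
         site_count = h_site, random_count = h_rand,
         fold = ifelse(h_rand == 0, NA_real_, f_site / f_rand))
}

chrom_lengths <- function(genome) {
  if (is.numeric(genome)) return(genome)
  stats::setNames(nchar(genome), names(genome))
}

#' Log10 fold-change of a signal track around binding sites
#'
#' Mean signal over the +/- `halfwidth` bp windows around site summits,
#' divided by the genome-wide mean of the track, on a log10 scale. Windows
#' straddling chromosome ends are truncated. Bases not covered by the track
#' carry signal 0.
#'
#' @param track Signal tibble with `chrom`, `start`, `end`, `value`
#'   (bedGraph semantics, non-overlapping per chromosome).
#' @param sites Peak tibble with `summit`.
#' @param genome Chromosome sequences or lengths (see
#'   [feature_fold_enrichment()]).
#' @param halfwidth Window half-width in bp (default 1000).
#' @return Log10 fold-change (single number).
#' @export
histone_fold_change <- function(track, sites, genome, halfwidth = 1000) {
  check_intervals(track, arg = "track")
  if (!"value" %in% names(track)) abort("`track` needs a `value` column")
  lens <- chrom_lengths(genome)
  genome_mean <- sum((track$end - track$start) * track$value) / sum(lens)
  if (genome_mean <= 0) abort("track has non-positive genome-wide mean")
  win_sum <- 0; win_bp <- 0
  for (i in seq_len(nrow(sites))) {
    ch <- as.character(sites$chrom[i])
    s <- max(sites$summit[i] - halfwidth, 0)
    e <- min(sites$summit[i] + halfwidth + 1, lens[[ch]])
    tr <- track[track$chrom == ch & track$end > s & track$start < e, ]
    ov <- pmin(tr$end, e) - pmax(tr$start, s)
    win_sum <- win_sum + sum(ov * tr$value)
    win_bp <- win_bp + (e - s)
  }
  if (win_bp == 0) abort("no site windows on the genome")
  log10((win_sum / win_bp) / genome_mean)
}

#' Fraction of top peaks overlapping each ERE class
#'
#' @param peaks Peak tibble with `score`.
#' @param ere_by_class Named list of interval tibbles, one per ERE class, or
#'   a single tibble with a `class` column.
#' @param n_top Number of highest-score peaks considered (default 500).
#' @return Tibble: `class`, `n_overlapping`, `fraction`. A peak overlapping
#'   several classes counts once for each.
#' @export
ere_overlap_fraction <- function(peaks, ere_by_class, n_top = 500) {
  tp <- top_peaks(peaks, n_top)
  eres <- as_ere_list(ere_by_class)
  rows <- lapply(names(eres), function(cl) {
    merged <- merge_intervals(eres[[cl]])
    k <- sum(overlaps_any(tp, merged))
    tibble(class = cl, n_overlapping = k, fraction = k / nrow(tp))
  })
  bind_rows(rows)
}

as_ere_list <- function(ere_by_class) {
  if (is.data.frame(ere_by_class)) {
    if (!"class" %in% names(ere_by_class)) {
      abort("ERE tibble needs a `class` column")
    }
    split(ere_by_class, ere_by_class$class)
  } else {
    ere_by_class
  }
}

#' Binomial enrichment of motif-containing peaks in ERE classes
#'
#' For each ERE class, tests whether more of the peaks overlap the class
#' than expected if peaks fell at random: the success probability is the
#' genomic coverage fraction of the class after dilating each instance by
#' half the median peak width on each side (approximating the chance that a
#' random peak overlaps the class). For classes whose dilated coverage
#' exceeds `perm_threshold`, a within-chromosome permutation test
#' (length-preserving peak shuffles) replaces the binomial. One-sided
#' (enrichment) p-values, BH-corrected across classes.
#'
#' @param motif_peaks Peak tibble (typically motif-containing peaks only).
#' @param ere_by_class Named list of interval tibbles or tibble with `class`.
#' @param genome Chromosome sequences or lengths.
#' @param fdr BH threshold for reporting a class (default 0.01).
#' @param perm_threshold Coverage above which the permutation test is used
#'   (default 0.2).
#' @param n_perm Permutations for the permutation alternative (default 1000).
#' @param seed Optional seed (permutation branch only).
#' @return List with `table` (class, n_overlapping, n_peaks, background_p,
#'   p_value, q_value, method), `enriched` (classes with q < fdr) and
#'   `top_class` (smallest p among enriched, else NA).
#' @export
ere_enrichment_test <- function(motif_peaks, ere_by_class, genome, fdr = 0.01,
                                perm_threshold = 0.2, n_perm = 1000,
                                seed = NULL) {
  if (nrow(motif_peaks) == 0) abort("zero peaks supplied")
  if (!is.null(seed)) set.seed(seed)
  eres <- as_ere_list(ere_by_class)
  lens <- chrom_lengths(genome)
  gsize <- sum(lens)
  med_w <- stats::median(motif_peaks$end - motif_peaks$start)
  n <- nrow(motif_peaks)
  rows <- lapply(names(eres), function(cl) {
    merged <- merge_intervals(eres[[cl]])
    k <- sum(overlaps_any(motif_peaks, merged))
    dil <- merged
    dil$start <- pmax(dil$start - med_w / 2, 0)
    dil$end <- dil$end + med_w / 2
    p0 <- min(total_bp(merge_intervals(dil)) / gsize, 1)
    if (p0 <= perm_threshold) {
      p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
      method <- "binomial"
    } else {
      perm <- vapply(seq_len(n_perm), function(.) {
        shuf <- shuffle_peaks_within_chrom(motif_peaks, lens)
        sum(overlaps_any(shuf, merged))
      }, numeric(1))
      p <- (1 + sum(perm >= k)) / (1 + n_perm)
      method <- "permutation"
    }
    tibble(class = cl, n_overlapping = k, n_peaks = n, background_p = p0,
           p_value = p, method = method)
  })
  tab <- bind_rows(rows)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  enriched <- tab$class[tab$q_value < fdr]
  top <- if (length(enriched) > 0) {
    sub <- tab[tab$class %in% enriched, ]
    sub$class[which.min(sub$p_value)]
  } else NA_character_
  list(table = tab[, c("class", "n_overlapping", "n_peaks", "background_p",
                       "p_value", "q_value", "method")],
       enriched = enriched, top_class = top)
}

shuffle_peaks_within_chrom <- function(peaks, lens) {
  w <- peaks$end - peaks$start
  maxs <- lens[as.character(peaks$chrom)] - w
  s <- floor(runif(nrow(peaks), 0, pmax(maxs, 1)))
  tibble(chrom = peaks$chrom, start = s, end = s + w)
}

#' SNP depletion inside motif hits versus flanking sequence
#'
#' For each protein, the motif territory is the union of its motif-hit
#' intervals; the flank territory is the union of the +/- `flank` bp beyond
#' each hit, minus any base belonging to a motif hit of the same protein.
#' SNPs falling in each territory are counted and the motif count tested for
#' depletion with a one-sided binomial test: s_motif ~ Binomial(s_motif +
#' s_flank, motif_bp / (motif_bp + flank_bp)), lower tail. BH correction
#' across proteins; a pooled test aggregates counts over all proteins.
#'
#' @param hits Motif-hit tibble with `chrom`, `start`, `end`, `protein`.
#' @param snps Tibble of SNP positions: `chrom`, `pos`.
#' @param flank Flank width in bp (default 20).
#' @param fdr BH threshold (default 0.025).
#' @param alternative "less" (depletion, default) or "two.sided".
#' @return List with `per_protein` (tibble: protein, snps_in_motifs,
#'   snps_in_flanks, motif_bp, flank_bp, p_value, q_value, significant) and
#'   `pooled` (same columns, one row).
#' @export
snp_depletion_test <- function(hits, snps, flank = 20, fdr = 0.025,
                               alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  check_intervals(hits, arg = "hits")
  if (!"protein" %in% names(hits)) abort("`hits` needs a `protein` column")
  one <- function(h) {
    motif <- merge_intervals(h)
    fl <- h
    fl$start <- pmax(fl$start - flank, 0)
    fl$end <- fl$end + flank
    flanks <- interval_setdiff(merge_intervals(fl), motif)
    s_m <- count_points_in(snps, motif)
    s_f <- count_points_in(snps, flanks)
    bp_m <- total_bp(motif); bp_f <- total_bp(flanks)
    tibble(snps_in_motifs = s_m, snps_in_flanks = s_f,
           motif_bp = bp_m, flank_bp = bp_f)
  }
  per <- bind_rows(lapply(split(hits, hits$protein), one), .id = "protein")
  per$p_value <- binom_p(per$snps_in_motifs, per$snps_in_flanks,
                         per$motif_bp, per$flank_bp, alternative)
  per$q_value <- stats::p.adjust(per$p_value, method = "BH")
  per$significant <- per$q_value < fdr
  pooled <- tibble(protein = "pooled",
                   snps_in_motifs = sum(per$snps_in_motifs),
                   snps_in_flanks = sum(per$snps_in_flanks),
                   motif_bp = sum(per$motif_bp),
                   flank_bp = sum(per$flank_bp))
  pooled$p_value <- binom_p(pooled$snps_in_motifs, pooled$snps_in_flanks,
                            pooled$motif_bp, pooled$flank_bp, alternative)
  pooled$q_value <- pooled$p_value
  pooled$significant <- pooled$p_value < fdr
  if (sum(per$snps_in_motifs) + sum(per$snps_in_flanks) == 0) {
    warn("no SNPs in motif or flank territory; p-values are 1")
  }
  list(per_protein = as_tibble(per), pooled = pooled)
}

binom_p <- function(s_m, s_f, bp_m, bp_f, alternative) {
  n <- s_m + s_f
  p0 <- bp_m / (bp_m + bp_f)
  p <- numeric(length(n))
  for (i in seq_along(n)) {
    if (n[i] == 0) { p[i] <- 1; next }
    if (alternative == "less") {
      p[i] <- stats::pbinom(s_m[i], n[i], p0[i], lower.tail = TRUE)
    } else {
      p[i] <- stats::binom.test(s_m[i], n[i], p0[i],
                                alternative = "two.sided")$p.value
    }
  }
  p
}
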