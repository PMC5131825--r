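# Format readers/writers and the end-to-end pipeline driver.
#
# All coordinates are 0-based half-open on disk and in memory. Peaks use the
# MACS BED convention: column 5 = score, column 7 = summit offset from the
# interval start.

#' Read a BED file of intervals or peaks
#'
#' BED3+ minimum. Column 4 becomes `name`, column 5 `score`, column 7 the
#' summit offset from start (stored as the absolute `summit` coordinate).
#' Unsorted input is sorted with a warning; malformed lines (start >= end,
#' negative coordinates, non-numeric fields) raise an error naming the line.
#'
#' @param path File path.
#' @return Interval tibble.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(parts, length, 1L)
  if (any(ncol < 3)) {
    abort(sprintf("BED line %d has fewer than 3 columns", which(ncol < 3)[1]))
  }
  grab <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i]
                             else NA_character_, character(1))
  start <- suppressWarnings(as.numeric(grab(2)))
  end <- suppressWarnings(as.numeric(grab(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("BED line %d: invalid interval (need 0 <= start < end)",
                  bad[1]))
  }
  out <- tibble(chrom = grab(1), start = start, end = end)
  if (max(ncol) >= 4) out$name <- grab(4)
  if (max(ncol) >= 5) out$score <- suppressWarnings(as.numeric(grab(5)))
  if (max(ncol) >= 7) {
    off <- suppressWarnings(as.numeric(grab(7)))
    if (any(!is.na(off) & (off < 0 | off >= end - start))) {
      abort("BED column 7 (summit offset) outside interval")
    }
    out$summit <- start + off
  }
  resorted <- out[order(out$chrom, out$start, out$end), ]
  if (!identical(resorted$start, out$start) ||
      !identical(resorted$chrom, out$chrom)) {
    warn("BED input not sorted; sorting by chrom, start")
    out <- resorted
  }
  out
}

#' Write intervals or peaks as BED
#'
#' Writes BED3, BED5 (when `score` is present; column 4 from `name` or
#' `protein` or "."), or BED6+1 with the summit offset in column 7 when
#' `summit` is present.
#'
#' @param x Interval tibble.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, arg = "x")
  nm <- if ("name" %in% names(x)) x$name
  else if ("protein" %in% names(x)) as.character(x$protein)
  else rep(".", nrow(x))
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  if ("score" %in% names(x) || "summit" %in% names(x)) {
    cols <- c(cols, list(nm, x$score %||% rep(0, nrow(x))))
  }
  if ("summit" %in% names(x)) {
    cols <- c(cols, list(rep(".", nrow(x)),
                         format_coord(x$summit - x$start)))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read/write genomes as FASTA
#'
#' Thin wrappers over Biostrings keeping the package's plain named
#' character-vector genome representation.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param genome Named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the alphabet, background frequencies and letter-probability
#' matrices of a MEME minimal motif file. Rows off unit sum by up to 1e-3
#' are renormalised; worse rows raise an error. A missing background line
#' falls back to uniform with a warning.
#'
#' @param path File path.
#' @param pseudocount Pseudocount stored on the returned PWMs.
#' @return List of `zf_pwm` objects, in file order.
#' @export
read_meme_motifs <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bg_line <- grep("^Background letter frequencies", lines)
  if (length(bg_line) == 1 && bg_line < length(lines)) {
    toks <- strsplit(lines[bg_line + 1], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    if (length(vals) == 4 && !any(is.na(vals))) bg <- vals
  } else {
    warn("no background line; assuming uniform background")
  }
  starts <- grep("^MOTIF", lines)
  pwms <- lapply(starts, function(s) {
    name <- strsplit(lines[s], "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(rows, function(r) {
      as.numeric(strsplit(r, "\\s+")[[1]])
    }, numeric(4)))
    sums <- rowSums(m)
    if (any(abs(sums - 1) > 1e-3)) {
      abort(sprintf("motif %s: probability row off unit sum by > 1e-3", name))
    }
    m <- m / sums
    pwm(t(m), name = name, background = bg, pseudocount = pseudocount)
  })
  pwms
}

#' Write motifs in MEME minimal format
#'
#' @param pwms List of `zf_pwm` objects (sharing a background).
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_meme_motifs <- function(pwms, path) {
  if (inherits(pwms, "zf_pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
           "")
  for (p in pwms) {
    out <- c(out, sprintf("MOTIF %s", p$name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     ncol(p$matrix)),
             apply(p$matrix, 2, function(col) {
               sprintf("%.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])
             }),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a synthetic world from `config`, pushes it through every
#' analysis stage (replicate merging and Jaccard diversity; motif AUROC,
#' window, cutoff and hits; ERE overlap/enrichment and SNP depletion; PPI
#' filtering, odds ratios, replicate specificity and expression response;
#' profile-count estimation and cross-parameter correlation; neutral-
#' evolution simulation) and, when `out_dir` is given, writes stage outputs
#' as TSV/FASTA/BED/MEME plus a JSON run manifest (parameters, seed,
#' package version, output checksums). Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A `zf_sim_config`.
#' @param out_dir Optional output directory (created if missing).
#' @param n_top Top-peak count for the motif and ERE stages (default 100;
#'   the synthetic worlds are smaller than a real ChIP experiment).
#' @return List of stage results.
#' @export
run_pipeline <- function(config = sim_world_config(), out_dir = NULL,
                         n_top = 100) {
  world <- sim_world(config)
  prots <- protein_labels(config)
  genome <- world$genome

  merged <- bind_rows(lapply(split(world$binding$peaks,
                                   world$binding$peaks$protein),
                             merge_replicate_peaks))
  jac <- jaccard_matrix(world$binding$peaks)
  repspec <- replicate_specificity(world$binding$peaks)

  p1 <- prots[1]
  peaks1 <- merged[merged$protein == p1, ]
  pwm1 <- world$binding$pwms[[p1]]
  auroc <- motif_auroc(pwm1, peaks1, genome, n_top = n_top,
                       seed = config$seed + 10)
  win <- central_enrichment_window(pwm1, peaks1, genome, n_top = n_top)
  cutf <- optimize_affinity_cutoff(pwm1, peaks1, genome,
                                   window = win$halfwidth)
  hits <- bind_rows(lapply(prots, function(p) {
    find_motif_hits(world$binding$pwms[[p]],
                    merged[merged$protein == p, ],
                    genome, cutoff = cutf$cutoff, window = win$halfwidth)
  }))

  ere_frac <- ere_overlap_fraction(peaks1, world$annotations$ere,
                                   n_top = n_top)
  ere_enr <- ere_enrichment_test(head(peaks1[order(-peaks1$score), ], n_top),
                                 world$annotations$ere, genome,
                                 seed = config$seed + 11)
  snp <- snp_depletion_test(hits, world$annotations$snps)

  filt <- filter_low_variation_preys(world$ppi$counts)
  ors <- spectral_odds_ratios(world$ppi$counts,
                              control_baits = world$ppi$control_baits,
                              preys = filt$prey[filt$retained])
  real_counts <- world$ppi$counts[
    !world$ppi$counts$bait %in% world$ppi$control_baits, ]
  ppispec <- replicate_profile_specificity(real_counts,
                                           preys = filt$prey[filt$retained])
  exprtest <- expression_response_test(world$expression$expr,
                                       world$bound_genes)

  dmat <- similarity_to_distance(jac)
  prof <- estimate_profile_count(dmat, k_max = min(config$n_proteins - 1, 20))
  or_mat <- or_similarity(ors, baits = prots)
  xcor <- cross_parameter_correlation(list(peaks = jac, ppi = or_mat))

  evo <- simulate_neutral_evolution(n_domains = 2e4, seed = config$seed + 12)

  results <- list(
    merged_peaks = merged, jaccard = jac, replicate_specificity = repspec,
    motif_auroc = auroc, central_window = win, affinity_cutoff = cutf,
    motif_hits = hits, ere_overlap = ere_frac, ere_enrichment = ere_enr,
    snp_depletion = snp, prey_filter = filt, odds_ratios = ors,
    ppi_specificity = ppispec, expression_response = exprtest,
    profile_count = prof, cross_correlation = xcor, neutral_evo = evo,
    config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(out_dir, "genome.fa"))
    write_bed(world$binding$peaks, file.path(out_dir, "peaks.bed"))
    write_bed(hits, file.path(out_dir, "motif_hits.bed"))
    write_meme_motifs(unname(world$binding$pwms[!duplicated(
      vapply(world$binding$pwms, function(p) p$name, character(1)))]),
      file.path(out_dir, "planted_motifs.meme"))
    tsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    tsv(tidy(jac), "jaccard_pairs.tsv")
    tsv(repspec$per_experiment, "replicate_specificity.tsv")
    tsv(ere_frac, "ere_overlap.tsv")
    tsv(snp$per_protein, "snp_depletion.tsv")
    tsv(ors, "odds_ratios.tsv")
    tsv(exprtest, "expression_response.tsv")
    tsv(tidy(prof), "silhouette_profile.tsv")
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- list(
      package = "zfdiv",
      version = as.character(utils::packageVersion("zfdiv")),
      seed = config$seed,
      parameters = config[!vapply(config, is.function, TRUE)],
      estimated_k = prof$estimated_k,
      checksums = as.list(tools::md5sum(files))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results
}

#' Pearson similarity of baits from log odds-ratio profiles
#'
#' Builds the bait-by-bait Pearson correlation of log-transformed
#' odds-ratio vectors over preys, the PPI branch of the multiparameter
#' comparison.
#'
#' @param interactions Interaction tibble from [spectral_odds_ratios()].
#' @param baits Optional bait subset/order.
#' @return A `zf_similarity` (value_kind "pearson").
#' @export
or_similarity <- function(interactions, baits = NULL) {
  m <- tidyr::pivot_wider(interactions[, c("bait", "prey", "odds_ratio")],
                          names_from = "prey", values_from = "odds_ratio")
  labs <- m$bait
  v <- log(as.matrix(m[, -1]) + 1e-6)
  rownames(v) <- labs
  if (!is.null(baits)) v <- v[baits, , drop = FALSE]
  cm <- suppressWarnings(stats::cor(t(v)))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  new_similarity(cm, value_kind = "pearson")
}
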