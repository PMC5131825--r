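# PWM scanning and motif evaluation: dinucleotide-shuffle nulls, AUROC,
# central-window selection, affinity-cutoff optimisation, hit calling.

DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param matrix 4 x L numeric matrix of per-position probabilities, rows in
#'   A, C, G, T order; each column must sum to 1 within 1e-6. L >= 4.
#' @param name Motif identifier.
#' @param background Length-4 background probabilities (default uniform).
#' @param pseudocount Added to matrix and background before taking log-odds
#'   (default 0.01).
#' @return A `zf_pwm` object.
#' @export
pwm <- function(matrix, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.01) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4) abort("PWM matrix must have 4 rows (A, C, G, T)")
  if (ncol(m) < 4) abort("PWM must have at least 4 columns")
  if (any(abs(colSums(m) - 1) > 1e-6)) abort("PWM columns must each sum to 1")
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  dimnames(m) <- list(DNA, NULL)
  structure(list(name = name, matrix = m, background = background,
                 pseudocount = pseudocount),
            class = "zf_pwm")
}

#' @export
print.zf_pwm <- function(x, ...) {
  cat(sprintf("<zf_pwm> %s, width %d\n", x$name, ncol(x$matrix)))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

pwm_width <- function(x) ncol(x$matrix)

#' @rdname pwm
#' @param x A `zf_pwm` object.
#' @export
pwm_consensus <- function(x) paste(DNA[apply(x$matrix, 2, which.max)],
                                   collapse = "")

# Log2-odds score matrix (4 x L) with pseudocount.
pwm_log_odds <- function(x) {
  eps <- x$pseudocount
  log2((x$matrix + eps) / (x$background + eps))
}

# Reverse-complement PWM: reverse columns, swap A<->T and C<->G rows.
pwm_revcomp <- function(x) {
  m <- x$matrix[c(4, 3, 2, 1), rev(seq_len(ncol(x$matrix))), drop = FALSE]
  rownames(m) <- DNA
  x$matrix <- m
  x$background <- x$background[c(4, 3, 2, 1)]
  x
}

# Encode A/C/G/T string as integers 1..4; anything else (N) becomes NA.
encode_dna <- function(sequence) {
  map <- rep(NA_integer_, 127)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
  map[utf8ToInt("a")] <- 1L; map[utf8ToInt("c")] <- 2L
  map[utf8ToInt("g")] <- 3L; map[utf8ToInt("t")] <- 4L
  map[utf8ToInt(sequence)]
}

decode_dna <- function(idx) paste(DNA[idx], collapse = "")

# Per-offset log-odds scores of a log-odds matrix along an encoded sequence.
# Windows containing N score -Inf. Returns numeric(0) if sequence < L.
scan_scores <- function(lom, idx) {
  L <- ncol(lom)
  n <- length(idx) - L + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    v <- unname(lom[, j][idx[seq_len(n) + j - 1]])
    v[is.na(v)] <- -Inf
    s <- s + v
  }
  s
}

#' Scan a sequence with a PWM
#'
#' Scores every placement of the motif on both strands as the sum of
#' per-position log2 odds against the background (with pseudocount). The
#' best hit is the maximum over positions and strands; ties are broken by
#' leftmost position, then + strand. Positions overlapping an N score -Inf.
#'
#' @param pwm A `zf_pwm` object.
#' @param sequence Character scalar over A, C, G, T, N (case-insensitive),
#'   length >= motif width.
#' @return List with `best` (tibble: start (0-based), strand, score; zero
#'   rows if no placement has finite score), `forward` and `reverse`
#'   per-offset score vectors.
#' @export
score_sequence <- function(pwm, sequence) {
  L <- pwm_width(pwm)
  idx <- encode_dna(sequence)
  if (length(idx) < L) abort("sequence shorter than motif width")
  fwd <- scan_scores(pwm_log_odds(pwm), idx)
  rev <- scan_scores(pwm_log_odds(pwm_revcomp(pwm)), idx)
  best_val <- max(c(fwd, rev))
  if (!is.finite(best_val)) {
    best <- tibble(start = integer(), strand = character(), score = numeric())
  } else {
    # leftmost position first, + strand before - at the same position
    pf <- which(fwd == best_val); pr <- which(rev == best_val)
    pos <- c(pf, pr)
    strand <- rep(c(1L, 2L), c(length(pf), length(pr)))
    pick <- order(pos, strand)[1]
    best <- tibble(start = as.integer(pos[pick]) - 1L,
                   strand = c("+", "-")[strand[pick]],
                   score = best_val)
  }
  list(best = best, forward = fwd, reverse = rev)
}

best_score <- function(pwm, sequence) {
  sc <- score_sequence(pwm, sequence)
  if (nrow(sc$best) == 0) -Inf else sc$best$score
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a sequence while exactly preserving its dinucleotide counts,
#' length, and first and last nucleotide, using the Altschul-Erickson
#' Eulerian-path algorithm. Runs of characters outside A/C/G/T (e.g. N) are
#' held fixed in place and the intervening A/C/G/T segments are shuffled
#' independently.
#'
#' @param sequence Character scalar, length >= 2.
#' @param seed Optional integer seed for reproducibility.
#' @return The shuffled sequence (character scalar).
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) < 2) abort("sequence must have length >= 2")
  is_acgt <- chars %in% DNA
  seg <- cumsum(c(TRUE, is_acgt[-1] != is_acgt[-length(is_acgt)]))
  out <- chars
  for (s in unique(seg)) {
    pos <- which(seg == s)
    if (!is_acgt[pos[1]] || length(pos) < 3) next
    out[pos] <- shuffle_acgt(chars[pos])
  }
  paste(out, collapse = "")
}

# Altschul-Erickson shuffle of a pure-ACGT character vector.
shuffle_acgt <- function(chars) {
  n <- length(chars)
  idx <- match(chars, DNA)
  first <- idx[1]; last <- idx[n]
  # adjacency: edges[[v]] = multiset of successors of letter v
  edges <- lapply(1:4, function(v) idx[which(idx[-n] == v) + 1])
  present <- which(vapply(edges, length, 1L) > 0 | seq_len(4) == last)
  if (length(unique(idx)) == 1) return(chars)
  repeat {
    # choose a random candidate last edge out of every vertex except `last`
    last_edge <- rep(NA_integer_, 4)
    for (v in present) {
      if (v == last || length(edges[[v]]) == 0) next
      last_edge[v] <- edges[[v]][sample.int(length(edges[[v]]), 1)]
    }
    # the chosen last edges must form a tree rooted at `last`
    ok <- TRUE
    for (v in present) {
      if (v == last || is.na(last_edge[v])) next
      seen <- v; cur <- v
      while (cur != last) {
        cur <- last_edge[cur]
        if (is.na(cur) || cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute the remaining edges of each vertex, append its last edge
  walk_edges <- lapply(1:4, function(v) {
    e <- edges[[v]]
    if (!is.na(last_edge[v])) {
      drop1 <- match(last_edge[v], e)
      e <- e[-drop1]
    }
    e <- if (length(e) > 1) e[sample.int(length(e))] else e
    c(e, if (!is.na(last_edge[v])) last_edge[v])
  })
  ptr <- rep(1L, 4)
  res <- integer(n)
  res[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- walk_edges[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  DNA[res]
}

# Count the 16 dinucleotides of a sequence (helper used by tests and the
# generator's bias estimation).
#' Dinucleotide count vector of a sequence
#'
#' @param sequence Character scalar.
#' @return Named integer vector of the 16 A/C/G/T dinucleotide counts.
#' @export
dinucleotide_counts <- function(sequence) {
  idx <- encode_dna(sequence)
  keep <- !is.na(idx[-length(idx)]) & !is.na(idx[-1])
  a <- idx[-length(idx)][keep]; b <- idx[-1][keep]
  tab <- table(factor(a, 1:4), factor(b, 1:4))
  v <- as.integer(tab)
  names(v) <- as.vector(outer(DNA, DNA, function(x, y) paste0(x, y)))
  # table() is row-major over the first factor; build names to match
  names(v) <- as.vector(outer(DNA, DNA, paste0))
  v
}

# Extract the +/- flank sequence around each peak summit, truncated at
# chromosome ends. Returns character vector aligned with rows of peaks.
summit_sequences <- function(peaks, genome, flank) {
  vapply(seq_len(nrow(peaks)), function(i) {
    ch <- as.character(peaks$chrom[i])
    if (!ch %in% names(genome)) abort(sprintf("chromosome %s not in genome", ch))
    len <- nchar(genome[[ch]])
    s <- max(peaks$summit[i] - flank, 0)
    e <- min(peaks$summit[i] + flank + 1, len)
    substr(genome[[ch]], s + 1, e)
  }, character(1))
}

top_peaks <- function(peaks, n_top) {
  if (!"score" %in% names(peaks) || any(is.na(peaks$score))) {
    abort("peaks must carry scores")
  }
  peaks[order(-peaks$score, peaks$chrom, peaks$start), ][
    seq_len(min(n_top, nrow(peaks))), ]
}

#' AUROC of a motif for distinguishing peaks from shuffled sequence
#'
#' Takes the `n_top` highest-scoring peaks, extracts the +/- `flank` bp
#' around each summit, and scores each real sequence and one
#' dinucleotide-shuffled counterpart with the best PWM log-odds per
#' sequence. The AUROC for real vs shuffled is computed from the
#' Mann-Whitney rank statistic, ties contributing 1/2.
#'
#' @param pwm A `zf_pwm`.
#' @param peaks Peak tibble with `summit` and `score`.
#' @param genome Named character vector of chromosome sequences.
#' @param n_top Number of top peaks used (default 500).
#' @param flank Half-width of the summit window in bp (default 250).
#' @param seed Optional seed controlling the shuffles.
#' @return AUROC in \[0, 1\].
#' @export
motif_auroc <- function(pwm, peaks, genome, n_top = 500, flank = 250,
                        seed = NULL) {
  check_intervals(peaks, need = c("chrom", "start", "end", "summit", "score"),
                  arg = "peaks")
  if (nrow(peaks) < 10) abort("fewer than 10 scored peaks; AUROC not meaningful")
  if (!is.null(seed)) set.seed(seed)
  tp <- top_peaks(peaks, n_top)
  seqs <- summit_sequences(tp, genome, flank)
  pos <- vapply(seqs, function(s) best_score(pwm, s), numeric(1))
  neg <- vapply(seqs, function(s) best_score(pwm, dinucleotide_shuffle(s)),
                numeric(1))
  rank_auroc(pos, neg)
}

# Mann-Whitney AUROC with tie correction (-Inf scores allowed; they tie).
rank_auroc <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Central-enrichment window around peak summits
#'
#' Finds the half-width w (grid 10, 20, ..., `flank`) for which the motif's
#' best hits are most centrally enriched in the top peaks: the fraction of
#' peaks whose best hit centre lies within +/- w of the summit is compared
#' with the uniform expectation w / `flank` by a one-sided binomial test,
#' and the w with the smallest p-value is returned (ties to the smallest w).
#' If no w reaches `alpha` after Bonferroni correction over the grid, the
#' full `flank` is returned with `significant = FALSE`.
#'
#' @inheritParams motif_auroc
#' @param alpha Significance level for the centrality call (default 0.05).
#' @return List with `halfwidth`, `p_value`, `significant` and the per-w
#'   `table` (tibble: halfwidth, n_within, fraction, expected, p_value).
#' @export
central_enrichment_window <- function(pwm, peaks, genome, n_top = 500,
                                      flank = 250, alpha = 0.05) {
  tp <- top_peaks(peaks, n_top)
  seqs <- summit_sequences(tp, genome, flank)
  L <- pwm_width(pwm)
  offs <- vapply(seq_along(seqs), function(i) {
    sc <- score_sequence(pwm, seqs[[i]])
    if (nrow(sc$best) == 0) return(NA_real_)
    # hit centre relative to the summit; window start in the genome
    win_start <- max(tp$summit[i] - flank, 0)
    centre <- win_start + sc$best$start + L / 2
    centre - tp$summit[i]
  }, numeric(1))
  offs <- offs[!is.na(offs)]
  n <- length(offs)
  if (n == 0) abort("no finite-scoring motif placement in any top peak")
  ws <- seq(10, flank, by = 10)
  tab <- lapply(ws, function(w) {
    k <- sum(abs(offs) <= w)
    p0 <- min(w / flank, 1)
    tibble(halfwidth = w, n_within = k, fraction = k / n, expected = p0,
           p_value = stats::pbinom(k - 1, n, p0, lower.tail = FALSE))
  })
  tab <- bind_rows(tab)
  best <- which.min(tab$p_value)  # which.min takes the first (smallest w) tie
  signif <- tab$p_value[best] * length(ws) < alpha
  list(halfwidth = if (signif) tab$halfwidth[best] else flank,
       p_value = tab$p_value[best],
       significant = signif,
       table = tab)
}

#' Optimise the motif affinity-score cutoff
#'
#' Chooses the log-odds cutoff maximising the enrichment of motif-containing
#' peaks among the highest-MACS-score peaks: enrichment(c) = (fraction of
#' the top `top_fraction` peaks whose best hit within +/- `window` of the
#' summit scores >= c) / (the same fraction among the remaining peaks),
#' subject to >= `min_hit_fraction` of all peaks containing a hit. The
#' candidate grid is the observed best-score quantiles; ties go to the
#' higher cutoff.
#'
#' @inheritParams motif_auroc
#' @param window Half-width of the scanned summit window, bp.
#' @param top_fraction Fraction of peaks treated as top-scoring (default 0.2).
#' @param min_hit_fraction Minimum fraction of all peaks with a hit at the
#'   returned cutoff (default 0.05).
#' @param grid_probs Quantile probabilities defining the candidate grid.
#' @return List with `cutoff`, `enrichment`, `flat` (TRUE when no cutoff is
#'   meaningfully enriched, enrichment <= 1) and the per-candidate `table`.
#' @export
optimize_affinity_cutoff <- function(pwm, peaks, genome, window,
                                     top_fraction = 0.2,
                                     min_hit_fraction = 0.05,
                                     grid_probs = seq(0.05, 0.95, by = 0.05)) {
  check_intervals(peaks, need = c("chrom", "start", "end", "summit", "score"),
                  arg = "peaks")
  seqs <- summit_sequences(peaks, genome, window)
  sc <- vapply(seqs, function(s) best_score(pwm, s), numeric(1))
  fin <- sc[is.finite(sc)]
  if (length(fin) == 0) abort("no peak has a finite-scoring motif placement")
  cand <- sort(unique(stats::quantile(fin, probs = grid_probs, names = FALSE)))
  n_topset <- max(1, round(top_fraction * nrow(peaks)))
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  is_top <- logical(nrow(peaks)); is_top[ord[seq_len(n_topset)]] <- TRUE
  tab <- lapply(cand, function(ct) {
    hit <- sc >= ct
    f_top <- mean(hit[is_top]); f_rest <- mean(hit[!is_top])
    tibble(cutoff = ct, hit_fraction = mean(hit), top_fraction_hit = f_top,
           rest_fraction_hit = f_rest,
           enrichment = if (f_top == 0) 0 else f_top / max(f_rest, .Machine$double.eps))
  })
  tab <- bind_rows(tab)
  ok <- tab$hit_fraction >= min_hit_fraction
  if (!any(ok)) abort("no candidate cutoff retains the minimum hit fraction")
  sub <- tab[ok, ]
  best_e <- max(sub$enrichment)
  cut <- max(sub$cutoff[sub$enrichment == best_e])  # tie -> higher cutoff
  list(cutoff = cut, enrichment = best_e, flat = best_e <= 1 + 1e-9,
       table = tab)
}

#' Motif hits inside peak regions
#'
#' Scans the +/- `window` bp around each peak summit on both strands and
#' reports every placement scoring at least `cutoff`. Overlapping same-strand
#' hits within a peak are greedily resolved to the best-scoring placement
#' (ties to the leftmost).
#'
#' @inheritParams optimize_affinity_cutoff
#' @param cutoff Log-odds score threshold.
#' @return Tibble of hits: `chrom`, `start`, `end` (0-based half-open,
#'   width = motif length), `strand`, `score`, `peak_id` and, when present in
#'   `peaks`, `protein`.
#' @export
find_motif_hits <- function(pwm, peaks, genome, cutoff, window) {
  check_intervals(peaks, need = c("chrom", "start", "end", "summit"),
                  arg = "peaks")
  L <- pwm_width(pwm)
  lom_f <- pwm_log_odds(pwm)
  lom_r <- pwm_log_odds(pwm_revcomp(pwm))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    ch <- as.character(peaks$chrom[i])
    len <- nchar(genome[[ch]])
    s0 <- max(peaks$summit[i] - window, 0)
    e0 <- min(peaks$summit[i] + window + 1, len)
    idx <- encode_dna(substr(genome[[ch]], s0 + 1, e0))
    if (length(idx) < L) return(NULL)
    fwd <- scan_scores(lom_f, idx)
    rev <- scan_scores(lom_r, idx)
    hits <- bind_rows(
      tibble(offset = which(fwd >= cutoff), strand = "+",
             score = fwd[fwd >= cutoff]),
      tibble(offset = which(rev >= cutoff), strand = "-",
             score = rev[rev >= cutoff])
    )
    if (nrow(hits) == 0) return(NULL)
    hits$start <- s0 + hits$offset - 1
    hits$end <- hits$start + L
    hits$chrom <- ch
    hits$peak_id <- i
    # greedy same-strand overlap resolution: best score first, leftmost ties
    keep <- lapply(split(hits, hits$strand), function(h) {
      h <- h[order(-h$score, h$start), ]
      sel <- logical(nrow(h))
      taken_s <- numeric(0); taken_e <- numeric(0)
      for (j in seq_len(nrow(h))) {
        if (!any(h$start[j] < taken_e & h$end[j] > taken_s)) {
          sel[j] <- TRUE
          taken_s <- c(taken_s, h$start[j]); taken_e <- c(taken_e, h$end[j])
        }
      }
      h[sel, ]
    })
    bind_rows(keep)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), score = numeric(), peak_id = integer()))
  }
  out <- out[, c("chrom", "start", "end", "strand", "score", "peak_id")]
  if ("protein" %in% names(peaks)) out$protein <- peaks$protein[out$peak_id]
  out[order(out$chrom, out$start, out$strand), ]
}
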