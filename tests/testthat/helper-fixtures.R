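# Shared fixtures: toy interval sets, a small synthetic world, and
# brute-force oracles kept independent of the implementation paths they
# check.

toy_peaks <- function(chrom, summit, score, width = 100,
                      protein = "ZNF001", replicate = 1L) {
  tibble::tibble(chrom = chrom,
                 start = summit - width / 2,
                 end = summit + width / 2,
                 summit = summit, score = score,
                 protein = protein, replicate = replicate)
}

small_world_config <- function(seed = 1, ...) {
  sim_world_config(
    genome_length = 5e4, n_chromosomes = 2, n_proteins = 6, n_clusters = 2,
    peaks_per_protein = 60,
    ere_classes = data.frame(class = c("LINE", "SINE"),
                             instance_count = c(20, 40),
                             instance_length = c(300, 200)),
    n_tss = 80, n_dhs = 30, seed = seed, ...)
}

# Per-base set oracle for the base-pair Jaccard (chromosomes <= 10 kb).
bruteforce_jaccard <- function(a, b, max_len = 1e4) {
  chroms <- union(a$chrom, b$chrom)
  inter <- 0; uni <- 0
  for (ch in chroms) {
    cover <- function(x) {
      xx <- x[x$chrom == ch, ]
      out <- rep(FALSE, max_len)
      for (i in seq_len(nrow(xx))) {
        out[(xx$start[i] + 1):xx$end[i]] <- TRUE
      }
      out
    }
    ca <- cover(a); cb <- cover(b)
    inter <- inter + sum(ca & cb)
    uni <- uni + sum(ca | cb)
  }
  if (uni == 0) 0 else inter / uni
}

# Pair-counting oracle for the AUROC (ties count 1/2).
bruteforce_auroc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive scan oracle for the best PWM hit on a short sequence.
bruteforce_best_hit <- function(pwm_obj, sequence) {
  L <- ncol(pwm_obj$matrix)
  eps <- pwm_obj$pseudocount
  lo <- log2((pwm_obj$matrix + eps) / (pwm_obj$background + eps))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(lo[cbind(match(ch, c("A", "C", "G", "T")), seq_len(L))])
  }
  best <- -Inf
  for (i in seq_len(nchar(sequence) - L + 1)) {
    win <- substr(sequence, i, i + L - 1)
    best <- max(best, score_one(win), score_one(rc(win)))
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All permutations of a short character vector (enumeration oracle input).
enumerate_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- enumerate_permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# Planted block-structured distance matrix: `sizes` clusters with tight
# within distances and looser between distances plus symmetric jitter.
block_distance <- function(sizes, within = 0.1, between = 1, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n) + matrix(stats::runif(n * n, 0, 0.05), n, n)
  d[outer(lab, lab, "==")] <- within
  d <- (d + t(d)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("e", seq_len(n))
  list(d = d, labels = lab)
}

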