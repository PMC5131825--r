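# Peak-set post-processing and diversity statistics.

#' Merge replicate peak summits within a distance threshold
#'
#' Summits of peaks from biological replicates that lie within `distance` bp
#' of each other (single-linkage, applied transitively per chromosome) are
#' collapsed into a single peak. The merged peak score is the sum of the
#' constituent scores; the merged summit is the score-weighted mean of the
#' constituent summit coordinates rounded to the nearest integer (ties toward
#' the lower coordinate); the merged interval is re-centred on the merged
#' summit with the widest constituent width.
#'
#' Note that single-linkage chaining means a merged group can span more than
#' `distance` bp end to end: summits at 0, 40 and 80 with `distance = 50`
#' form one peak.
#'
#' @param replicate_sets A peak tibble (columns `chrom`, `start`, `end`,
#'   `summit`, `score`, optionally `replicate`) or a list of such tibbles,
#'   all for the same protein.
#' @param distance Maximum summit separation merged, in bp (default 50).
#' @return A peak tibble with one row per merged peak.
#' @export
merge_replicate_peaks <- function(replicate_sets, distance = 50) {
  x <- if (is.data.frame(replicate_sets)) replicate_sets else bind_rows(replicate_sets)
  check_intervals(x, need = c("chrom", "start", "end", "summit", "score"),
                  arg = "replicate_sets")
  if (nrow(x) == 0) return(x)
  prot <- if ("protein" %in% names(x)) unique(x$protein) else NULL
  if (length(prot) > 1) {
    abort(sprintf("all replicate sets must share one protein label, got: %s",
                  paste(prot, collapse = ", ")))
  }
  x <- x[order(x$chrom, x$summit), ]
  out <- lapply(split(x, x$chrom), function(p) {
    gap <- diff(p$summit)
    grp <- cumsum(c(TRUE, gap > distance))
    width <- p$end - p$start
    merged <- lapply(split(seq_len(nrow(p)), grp), function(i) {
      sc <- p$score[i]
      # round half up would bias upward; nearest integer, ties toward the
      # lower coordinate
      wmean <- sum(p$summit[i] * sc) / sum(sc)
      summit <- ceiling(wmean - 0.5)
      w <- max(width[i])
      tibble(chrom = p$chrom[1],
             start = summit - floor(w / 2),
             end = summit - floor(w / 2) + w,
             summit = summit,
             score = sum(sc))
    })
    bind_rows(merged)
  })
  res <- bind_rows(out)
  res$start <- pmax(res$start, 0)
  if (!is.null(prot)) res$protein <- prot
  res[order(res$chrom, res$start), ]
}

#' Pairwise base-pair Jaccard similarity matrix across proteins
#'
#' One row/column per protein label. When either protein has several
#' replicate experiments, the entry is the maximum [interval_jaccard()] over
#' all replicate-pair combinations.
#'
#' @param experiments Peak tibble with columns `chrom`, `start`, `end`,
#'   `protein` and optionally `replicate`, or a list of per-experiment
#'   tibbles.
#' @return A `zf_similarity` object (symmetric matrix, unit diagonal,
#'   `value_kind = "jaccard"`).
#' @seealso [pair_fraction()] for the fraction of distinct-protein pairs
#'   above a similarity threshold.
#' @export
jaccard_matrix <- function(experiments) {
  x <- if (is.data.frame(experiments)) experiments else bind_rows(experiments)
  check_intervals(x, arg = "experiments")
  if (!"protein" %in% names(x)) abort("`experiments` needs a `protein` column")
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  sets <- split(x, list(x$protein, x$replicate), drop = TRUE)
  sets <- lapply(sets, merge_intervals)
  set_prot <- vapply(split(x, list(x$protein, x$replicate), drop = TRUE),
                     function(p) as.character(p$protein[1]), character(1))
  proteins <- sort(unique(as.character(x$protein)))
  n <- length(proteins)
  # cache pairwise experiment-level Jaccards
  ne <- length(sets)
  jac <- matrix(NA_real_, ne, ne)
  for (i in seq_len(ne)) {
    jac[i, i] <- 1
    for (j in seq_len(ne)[-seq_len(i)]) {
      jac[i, j] <- jac[j, i] <- interval_jaccard(sets[[i]], sets[[j]])
    }
  }
  m <- matrix(1, n, n, dimnames = list(proteins, proteins))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      ia <- which(set_prot == proteins[a])
      ib <- which(set_prot == proteins[b])
      m[a, b] <- m[b, a] <- max(jac[ia, ib, drop = FALSE])
    }
  }
  new_similarity(m, value_kind = "jaccard", experiment_jaccard = jac,
                 experiment_protein = set_prot)
}

#' Fraction of distinct-entity pairs at or above a similarity threshold
#'
#' @param sim A `zf_similarity` object.
#' @param tau Similarity threshold (default 0.2).
#' @return Fraction of off-diagonal pairs with value `>= tau`.
#' @export
pair_fraction <- function(sim, tau = 0.2) {
  m <- unclass_sim(sim)
  v <- m[upper.tri(m)]
  if (length(v) == 0) return(NA_real_)
  mean(v >= tau)
}

#' Replicate specificity of ChIP experiments
#'
#' For every experiment whose protein has at least one other replicate, all
#' other experiments are ranked by base-pair Jaccard similarity; the
#' experiment is flagged specific iff the top-ranked experiment belongs to
#' the same protein. Rank ties at the top are resolved in favour of the
#' replicate (a replicate tied for first still counts).
#'
#' @param experiments Peak tibble with `protein` and `replicate` columns.
#' @return A list with `per_experiment` (tibble: protein, replicate,
#'   best_replicate_jaccard, best_other_jaccard, specific) and `fraction`,
#'   the fraction of eligible experiments flagged specific.
#' @export
replicate_specificity <- function(experiments) {
  x <- if (is.data.frame(experiments)) experiments else bind_rows(experiments)
  check_intervals(x, arg = "experiments")
  if (!all(c("protein", "replicate") %in% names(x))) {
    abort("`experiments` needs `protein` and `replicate` columns")
  }
  key <- interaction(x$protein, x$replicate, drop = TRUE)
  sets <- lapply(split(x, key), merge_intervals)
  prot <- vapply(split(x, key), function(p) as.character(p$protein[1]),
                 character(1))
  ne <- length(sets)
  if (ne < 2) abort("need at least 2 experiments")
  if (!any(duplicated(prot))) abort("no protein has >= 2 replicates")
  jac <- matrix(0, ne, ne)
  for (i in seq_len(ne)) {
    for (j in seq_len(ne)[-seq_len(i)]) {
      jac[i, j] <- jac[j, i] <- interval_jaccard(sets[[i]], sets[[j]])
    }
  }
  eligible <- which(prot %in% prot[duplicated(prot)])
  rows <- lapply(eligible, function(i) {
    same <- which(prot == prot[i]); same <- setdiff(same, i)
    other <- setdiff(seq_len(ne), c(i, same))
    b_rep <- max(jac[i, same])
    b_oth <- if (length(other) > 0) max(jac[i, other]) else -Inf
    tibble(protein = prot[i],
           replicate = sub("^.*\\.", "", names(sets)[i]),
           best_replicate_jaccard = b_rep,
           best_other_jaccard = ifelse(is.finite(b_oth), b_oth, NA_real_),
           specific = b_rep >= b_oth)
  })
  per <- bind_rows(rows)
  list(per_experiment = per, fraction = mean(per$specific))
}

#' Composite-background weights by non-negative least squares
#'
#' Fits non-negative weights `w` minimising `||A w - y||_2` by the
#' Lawson-Hanson active-set algorithm, where `y` is the target experiment's
#' binned read counts and the columns of `A` are candidate input tracks.
#' Tracks are library-size normalised before fitting (each column and the
#' target scaled to unit sum); the returned composite is rescaled to the
#' target library size.
#'
#' @param target_bin_counts Numeric vector of per-bin counts (>= 0).
#' @param input_bin_counts Matrix of candidate input tracks, one column per
#'   track, same number of bins.
#' @param normalize Library-size normalise before fitting (default TRUE).
#' @return List with `weights` (on the normalised scale), `composite`
#'   (fitted background rescaled to the target library size) and `residual`
#'   (Euclidean norm on the fitting scale).
#' @export
fit_nnls_background <- function(target_bin_counts, input_bin_counts,
                                normalize = TRUE) {
  y <- as.numeric(target_bin_counts)
  A <- as.matrix(input_bin_counts)
  if (nrow(A) != length(y)) abort("bin count mismatch between target and inputs")
  if (any(y < 0) || any(A < 0)) abort("counts must be non-negative")
  csum <- colSums(A)
  if (any(csum == 0)) abort("all-zero input track(s): ",
                            paste(which(csum == 0), collapse = ", "))
  if (normalize) {
    ys <- sum(y)
    if (ys == 0) abort("target track is all zero")
    yf <- y / ys
    Af <- sweep(A, 2, csum, "/")
  } else {
    yf <- y; Af <- A; ys <- 1
  }
  fit <- pracma::lsqnonneg(Af, yf)
  comp <- as.numeric(Af %*% fit$x)
  if (normalize && sum(comp) > 0) comp <- comp / sum(comp) * sum(y)
  list(weights = as.numeric(fit$x),
       composite = comp,
       residual = sqrt(max(fit$resnorm, 0)))
}
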