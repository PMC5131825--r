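# Multiparameter diversity framework: PAM clustering, silhouette profiling,
# the 95%-of-max cluster-count estimator, motif distances, cross-parameter
# correlation.

check_distance <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (any(!is.finite(d))) abort("distance matrix must be finite")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix must have zero diagonal")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("e", seq_len(nrow(d)))
  }
  d
}

#' Partitioning Around Medoids (k-medoids) on a distance matrix
#'
#' Classic PAM: BUILD greedily selects k medoids minimising total
#' within-cluster distance, then SWAP repeatedly applies the single
#' medoid/non-medoid exchange with the largest objective decrease until no
#' exchange improves. All ties break to the lowest index, making the result
#' deterministic. SWAP is a local search; for small problems (at most
#' `exact_limit` candidate medoid sets) the globally optimal set is found
#' by exhaustive enumeration instead, so tiny instances are solved exactly.
#'
#' @param d Symmetric distance matrix (zero diagonal).
#' @param k Number of clusters, 2 <= k < n.
#' @param seed Accepted for interface symmetry; the algorithm is
#'   deterministic and ignores it.
#' @param exact_limit Enumerate all medoid sets when choose(n, k) is at
#'   most this (default 2000); 0 forces BUILD+SWAP.
#' @return List with `medoids` (indices), `assignment` (integer vector,
#'   cluster = index into `medoids`), `objective` (total distance of points
#'   to their medoid) and `labels`.
#' @export
pam_cluster <- function(d, k, seed = NULL, exact_limit = 2000) {
  d <- check_distance(d)
  n <- nrow(d)
  if (k < 2 || k >= n) abort("k must satisfy 2 <= k < n")
  objective_exact <- function(med) {
    sum(do.call(pmin, lapply(med, function(m) d[, m])))
  }
  if (choose(n, k) <= exact_limit) {
    combs <- utils::combn(n, k)
    objs <- apply(combs, 2, objective_exact)
    medoids <- combs[, which.min(objs)]  # first = lexicographically smallest
    assignment <- apply(d[, medoids, drop = FALSE], 1, which.min)
    return(list(medoids = medoids, assignment = as.integer(assignment),
                objective = min(objs), labels = rownames(d)))
  }
  # BUILD
  medoids <- which.min(colSums(d))
  while (length(medoids) < k) {
    best_gain <- -Inf; best_c <- NA_integer_
    cur_min <- apply(d[, medoids, drop = FALSE], 1, min)
    for (c in setdiff(seq_len(n), medoids)) {
      gain <- sum(pmax(cur_min - d[, c], 0))
      if (gain > best_gain + 1e-12) { best_gain <- gain; best_c <- c }
    }
    medoids <- c(medoids, best_c)
  }
  objective_of <- function(med) {
    sum(do.call(pmin, lapply(med, function(m) d[, m])))
  }
  obj <- objective_of(medoids)
  # SWAP: best-improvement passes
  repeat {
    best_obj <- obj; best_pair <- NULL
    for (mi in seq_along(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        cand <- medoids; cand[mi] <- h
        o <- objective_of(cand)
        if (o < best_obj - 1e-12) { best_obj <- o; best_pair <- c(mi, h) }
      }
    }
    if (is.null(best_pair)) break
    medoids[best_pair[1]] <- best_pair[2]
    obj <- best_obj
  }
  medoids <- sort(medoids)
  assignment <- apply(d[, medoids, drop = FALSE], 1, which.min)
  list(medoids = medoids, assignment = as.integer(assignment),
       objective = objective_of(medoids), labels = rownames(d))
}

#' Mean silhouette value of a partition
#'
#' Standard silhouette s(i) = (b - a) / max(a, b) with a the mean distance
#' of i to its own cluster's other members and b the minimum over other
#' clusters of the mean distance to that cluster. Members of singleton
#' clusters get s = 0 (Rousseeuw's convention).
#'
#' @param d Symmetric distance matrix.
#' @param assignment Integer cluster labels, one per entity.
#' @return Mean silhouette over entities, in \[-1, 1\].
#' @export
mean_silhouette <- function(d, assignment) {
  d <- check_distance(d)
  n <- nrow(d)
  if (length(assignment) != n) abort("assignment length mismatch")
  cl <- unique(assignment)
  if (length(cl) < 2) abort("need at least 2 clusters for a silhouette")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, assignment[i]), function(c2) {
      mean(d[i, assignment == c2])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Estimate the number of unique profiles by the 95%-of-max silhouette rule
#'
#' Runs PAM for every k in 2..`k_max`, computes the mean silhouette of each
#' partition, and reports the largest k whose silhouette is at least 95% of
#' the maximum over k. This estimates the highest number of distinct
#' profiles that still retain high intra-cluster similarity.
#'
#' @param d Symmetric distance matrix.
#' @param k_max Largest cluster count evaluated (default min(n - 1, 100)).
#' @param seed Passed through to [pam_cluster()] (deterministic; unused).
#' @param frac Fraction of the maximum silhouette required (default 0.95).
#' @return A `zf_profile` object: tibble of per-k silhouettes plus
#'   `estimated_k`, `max_silhouette` and a `degenerate` flag (TRUE when all
#'   silhouettes are 0, e.g. for an all-zero distance matrix; then
#'   `estimated_k = k_max`).
#' @export
estimate_profile_count <- function(d, k_max = NULL, seed = NULL, frac = 0.95) {
  d <- check_distance(d)
  n <- nrow(d)
  k_max <- k_max %||% min(n - 1, 100)
  if (k_max < 2) abort("k_max must be >= 2")
  ks <- 2:min(k_max, n - 1)
  sil <- vapply(ks, function(k) {
    fit <- pam_cluster(d, k, seed = seed)
    # ties can collapse every entity onto one medoid (e.g. d identically
    # zero); such partitions carry no structure and score 0
    if (length(unique(fit$assignment)) < 2) return(0)
    mean_silhouette(d, fit$assignment)
  }, numeric(1))
  mx <- max(sil)
  degenerate <- all(abs(sil) < 1e-12)
  est <- if (degenerate) max(ks) else max(ks[sil >= frac * mx])
  structure(list(table = tibble(k = ks, mean_silhouette = sil),
                 estimated_k = est, max_silhouette = mx,
                 frac = frac, degenerate = degenerate),
            class = "zf_profile")
}

#' @export
print.zf_profile <- function(x, ...) {
  cat(sprintf("<zf_profile> estimated number of profiles: %d (max silhouette %.3f%s)\n",
              x$estimated_k, x$max_silhouette,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @method tidy zf_profile
#' @export
tidy.zf_profile <- function(x, ...) x$table

#' @method glance zf_profile
#' @export
glance.zf_profile <- function(x, ...) {
  tibble(estimated_k = x$estimated_k, max_silhouette = x$max_silhouette,
         k_max = max(x$table$k), degenerate = x$degenerate)
}

#' Silhouette profile plot with the 95%-of-max estimate
#'
#' @param object A `zf_profile` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zf_profile
#' @export
autoplot.zf_profile <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$frac * object$max_silhouette,
                        linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$estimated_k,
                        linetype = "dashed", colour = "blue") +
    ggplot2::labs(x = "number of clusters (PAM)", y = "mean silhouette") +
    ggplot2::theme_minimal()
}

#' Hierarchical-clustering alternative for the profile-count estimate
#'
#' Average-linkage hierarchical clustering cut at every k, scored with the
#' same silhouette and 95%-of-max rule; a robustness check for
#' [estimate_profile_count()].
#'
#' @inheritParams estimate_profile_count
#' @return A `zf_profile` object.
#' @export
estimate_profile_count_hclust <- function(d, k_max = NULL, frac = 0.95) {
  d <- check_distance(d)
  n <- nrow(d)
  k_max <- k_max %||% min(n - 1, 100)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ks <- 2:min(k_max, n - 1)
  sil <- vapply(ks, function(k) {
    mean_silhouette(d, stats::cutree(hc, k = k))
  }, numeric(1))
  mx <- max(sil)
  degenerate <- all(abs(sil) < 1e-12)
  est <- if (degenerate) max(ks) else max(ks[sil >= frac * mx])
  structure(list(table = tibble(k = ks, mean_silhouette = sil),
                 estimated_k = est, max_silhouette = mx, frac = frac,
                 degenerate = degenerate),
            class = "zf_profile")
}

#' Distance between two PWMs by best-offset column correlation
#'
#' Similarity is the maximum, over relative offsets with at least
#' `min_overlap` aligned columns and over both orientations (the second
#' motif also tried as its reverse complement), of the mean per-column
#' Pearson correlation between the aligned probability columns; distance is
#' 1 - similarity, in \[0, 2\]. Identical columns correlate 1 even when
#' uniform; a uniform column against a non-uniform one contributes 0.
#'
#' @param a,b `zf_pwm` objects.
#' @param min_overlap Minimum aligned columns (default 4).
#' @return Distance in \[0, 2\].
#' @export
motif_distance <- function(a, b, min_overlap = 4) {
  sim <- max(pwm_best_similarity(a$matrix, b$matrix, min_overlap),
             pwm_best_similarity(a$matrix, pwm_revcomp(b)$matrix, min_overlap))
  1 - sim
}

col_cor <- function(x, y) {
  if (max(abs(x - y)) < 1e-12) return(1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

pwm_best_similarity <- function(ma, mb, min_overlap) {
  La <- ncol(ma); Lb <- ncol(mb)
  if (min(La, Lb) < min_overlap) abort("motifs shorter than min_overlap")
  best <- -Inf
  for (off in (-(Lb - min_overlap)):(La - min_overlap)) {
    ia <- max(1, 1 + off):min(La, Lb + off)
    ib <- ia - off
    cors <- vapply(seq_along(ia),
                   function(t) col_cor(ma[, ia[t]], mb[, ib[t]]),
                   numeric(1))
    best <- max(best, mean(cors))
  }
  best
}

#' Pearson correlation between similarity measures across entity pairs
#'
#' Vectorises the upper triangle of each similarity matrix (optionally
#' restricted to a subset of entity pairs, e.g. paralog pairs) and computes
#' all pairwise Pearson correlations between the parameters. Pairs with
#' missing values are dropped listwise per parameter pair.
#'
#' @param similarities Named list of `zf_similarity` objects or symmetric
#'   matrices sharing entity labels.
#' @param pair_subset Optional two-column matrix/data frame of entity label
#'   pairs to restrict to.
#' @return A `zf_similarity` object (value_kind "pearson") of parameter x
#'   parameter correlations.
#' @export
cross_parameter_correlation <- function(similarities, pair_subset = NULL) {
  mats <- lapply(similarities, unclass_sim)
  labs <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(sort(rownames(m)), sort(labs))) {
      abort("similarity matrices must share entity labels")
    }
  }
  mats <- lapply(mats, function(m) m[labs, labs])
  if (is.null(pair_subset)) {
    idx <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  } else {
    ps <- as.matrix(pair_subset)
    idx <- cbind(match(ps[, 1], labs), match(ps[, 2], labs))
    if (any(is.na(idx))) abort("pair_subset contains unknown entity labels")
  }
  if (nrow(idx) < 3) abort("need at least 3 usable entity pairs")
  vecs <- vapply(mats, function(m) m[idx], numeric(nrow(idx)))
  k <- ncol(vecs)
  out <- matrix(1, k, k, dimnames = list(names(similarities),
                                         names(similarities)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(vecs[, c(i, j)])
      out[i, j] <- out[j, i] <-
        if (sum(ok) >= 3) stats::cor(vecs[ok, i], vecs[ok, j]) else NA_real_
    }
  }
  new_similarity(out, value_kind = "pearson", n_pairs = nrow(idx))
}

#' Sequence distance from pairwise global alignment identity
#'
#' 1 minus the fractional identity of a Needleman-Wunsch global alignment
#' (default Biostrings scoring), for protein or DNA sequences; used to
#' compare zinc-finger-array or full-length sequences across proteins.
#'
#' @param seqs Named character vector of sequences.
#' @param type "protein" (default) or "dna".
#' @return Symmetric distance matrix in \[0, 1\].
#' @export
sequence_identity_distance <- function(seqs, type = c("protein", "dna")) {
  type <- match.arg(type)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[j]],
                                          type = "global")
      d[i, j] <- d[j, i] <- 1 - Biostrings::pid(al) / 100
    }
  }
  d
}
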