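# AP-MS spectral-count post-processing: prey filtering, odds-ratio
# interaction scoring, replicate specificity, regulatory-direction
# classification, expression-response consistency.
#
# Spectral counts are held as a long tibble with columns bait, prey,
# replicate, count (non-negative integers).

check_counts <- function(counts) {
  need <- c("bait", "prey", "replicate", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    abort(paste0("`counts` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    abort("spectral counts must be non-negative integers")
  }
  invisible(counts)
}

# Summed counts per bait x prey as a matrix (baits in rows).
sum_count_matrix <- function(counts) {
  baits <- sort(unique(as.character(counts$bait)))
  preys <- sort(unique(as.character(counts$prey)))
  m <- matrix(0, length(baits), length(preys), dimnames = list(baits, preys))
  agg <- stats::aggregate(count ~ bait + prey, data = counts, FUN = sum)
  m[cbind(as.character(agg$bait), as.character(agg$prey))] <- agg$count
  m
}

#' Drop low-variation (ubiquitous contaminant) preys
#'
#' Computes, for each prey, the coefficient of variation of its summed
#' spectral counts across all baits; preys with CV below `min_cv` are
#' flagged for exclusion. Preys that vary little across unrelated baits are
#' typically ubiquitous contaminants rather than specific interactors.
#'
#' @param counts Long count tibble (`bait`, `prey`, `replicate`, `count`).
#' @param min_cv Minimum coefficient of variation retained (default 0.5).
#' @return Tibble: `prey`, `mean_count`, `cv`, `retained`.
#' @export
filter_low_variation_preys <- function(counts, min_cv = 0.5) {
  check_counts(counts)
  m <- sum_count_matrix(counts)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  cv <- ifelse(mu == 0, 0, s / mu)
  tibble(prey = colnames(m), mean_count = as.numeric(mu), cv = as.numeric(cv),
         retained = cv >= min_cv)
}

#' Odds ratios for bait-prey interactions from spectral counts
#'
#' Converts summed spectral counts to odds ratios by estimating, for each
#' prey, the background probability of observing one of its peptides in the
#' profiles of non-interacting baits. With pseudocount `alpha` and P preys:
#' the background probability for pair (i, j) is p_ij = (sum of prey j's
#' counts over baits k != i where (k, j) is not significant + alpha) /
#' (total counts of those baits + alpha * P) -- the scored bait never
#' informs its own background; the bait-level probability is q_ij =
#' (c_ij + alpha) / (T_i + alpha * P) with T_i the bait's total counts; the
#' reported odds ratio is (q/(1-q)) / (p/(1-p)).
#'
#' Significance calls define the "non-interacting" background. They come
#' from SAINTexpress AvgP scores at `avgp_cutoff` when supplied, otherwise
#' from a count-threshold fallback: a pair is called significant when its
#' summed count is at least 5 and at least twice the prey's expected count
#' under proportional allocation. A prey significant in every bait falls
#' back to the negative-control baits for its background; if there are
#' none, this is an error.
#'
#' @param counts Long count tibble.
#' @param avgp Optional tibble `bait`, `prey`, `avgp` of SAINTexpress
#'   scores in \[0, 1\].
#' @param avgp_cutoff AvgP threshold for significance (default 1).
#' @param control_baits Character vector of negative-control bait labels.
#' @param alpha Pseudocount (default 1).
#' @param preys Optional prey subset (e.g. the retained preys from
#'   [filter_low_variation_preys()]).
#' @return Interaction tibble: `bait`, `prey`, `summed_count`, `odds_ratio`,
#'   `significant`.
#' @export
spectral_odds_ratios <- function(counts, avgp = NULL, avgp_cutoff = 1,
                                 control_baits = character(), alpha = 1,
                                 preys = NULL) {
  check_counts(counts)
  m <- sum_count_matrix(counts)
  if (!is.null(preys)) m <- m[, colnames(m) %in% preys, drop = FALSE]
  B <- nrow(m); P <- ncol(m)
  Ti <- rowSums(m)
  if (!is.null(avgp)) {
    sig <- matrix(FALSE, B, P, dimnames = dimnames(m))
    keep <- avgp$bait %in% rownames(m) & avgp$prey %in% colnames(m)
    a <- avgp[keep, ]
    sig[cbind(as.character(a$bait), as.character(a$prey))] <-
      a$avgp >= avgp_cutoff
  } else {
    # fallback: summed count >= 5 and >= 2x proportional expectation
    expected <- outer(Ti, colSums(m) / max(sum(m), 1))
    sig <- m >= 5 & m >= 2 * expected
  }
  is_ctrl <- rownames(m) %in% control_baits
  sig[is_ctrl, ] <- FALSE  # controls never count as true interactions
  # leave-one-out background: for pair (i, j) the background pool is every
  # bait k != i with (k, j) not significant, so a bait never informs its
  # own background (keeps ORs invariant to rescaling one bait as alpha -> 0)
  p_mat <- matrix(NA_real_, B, P, dimnames = dimnames(m))
  for (j in seq_len(P)) {
    bg <- !sig[, j]
    c_bg <- sum(m[bg, j]); t_bg <- sum(Ti[bg])
    for (i in seq_len(B)) {
      use_c <- c_bg - if (bg[i]) m[i, j] else 0
      use_t <- t_bg - if (bg[i]) Ti[i] else 0
      if ((sum(bg) - bg[i]) == 0) {
        if (!any(is_ctrl)) {
          abort(sprintf(
            "prey %s is significant in every other bait and no negative-control baits exist",
            colnames(m)[j]))
        }
        pool <- is_ctrl & seq_len(B) != i
        if (!any(pool)) pool <- seq_len(B) != i  # scored bait is the only control
        use_c <- sum(m[pool, j]); use_t <- sum(Ti[pool])
      }
      p_mat[i, j] <- (use_c + alpha) / (use_t + alpha * P)
    }
  }
  q <- (m + alpha) / (Ti + alpha * P)  # Ti recycles down columns
  or <- (q / (1 - q)) / (p_mat / (1 - p_mat))
  out <- tibble(bait = rep(rownames(m), times = P),
                prey = rep(colnames(m), each = B),
                summed_count = as.vector(m),
                odds_ratio = as.vector(or),
                significant = as.vector(sig))
  arrange(out, .data$bait, .data$prey)
}

#' Replicate specificity of AP-MS profiles
#'
#' For each bait with at least two replicates, compares the Pearson
#' correlation between its own replicate count vectors (over the prey set)
#' with its correlation to every other bait's replicates. A bait is flagged
#' specific iff its maximum within-bait correlation strictly exceeds its
#' maximum between-bait correlation; exact ties resolve to FALSE with a
#' warning.
#'
#' @param counts Long count tibble with replicate structure.
#' @param preys Optional prey subset (the filtered prey list).
#' @return List with `per_bait` (tibble: bait, within_cor, between_cor,
#'   specific) and `fraction`.
#' @export
replicate_profile_specificity <- function(counts, preys = NULL) {
  check_counts(counts)
  x <- counts
  if (!is.null(preys)) x <- x[x$prey %in% preys, ]
  prey_all <- sort(unique(as.character(x$prey)))
  key <- paste(x$bait, x$replicate, sep = "\r")
  profs <- lapply(split(x, key), function(p) {
    v <- stats::setNames(rep(0, length(prey_all)), prey_all)
    v[as.character(p$prey)] <- p$count
    v
  })
  bait_of <- vapply(split(x, key), function(p) as.character(p$bait[1]),
                    character(1))
  V <- do.call(cbind, profs)
  C <- suppressWarnings(stats::cor(V))
  C[is.na(C)] <- 0  # constant profiles carry no evidence
  baits <- unique(bait_of)
  eligible <- baits[vapply(baits, function(b) sum(bait_of == b) >= 2, TRUE)]
  if (length(eligible) == 0) abort("no bait has >= 2 replicates")
  tied <- FALSE
  rows <- lapply(eligible, function(b) {
    own <- which(bait_of == b); other <- which(bait_of != b)
    wc <- max(C[own, own][upper.tri(C[own, own])])
    bc <- if (length(other) > 0) max(C[own, other]) else -Inf
    if (isTRUE(all.equal(wc, bc))) tied <<- TRUE
    tibble(bait = b, within_cor = wc,
           between_cor = ifelse(is.finite(bc), bc, NA_real_),
           specific = wc > bc & !isTRUE(all.equal(wc, bc)))
  })
  if (tied) warn("within- and between-bait correlations tie for some bait; tie counted as non-specific")
  per <- bind_rows(rows)
  list(per_bait = per, fraction = mean(per$specific))
}

#' Classify baits by the regulatory direction of their interactors
#'
#' A bait is labelled by the union of directions over its significant preys
#' with a known direction: "activator-only", "repressor-only", "both" or
#' "none". A prey annotated "both" contributes to both sides.
#'
#' @param interactions Interaction tibble (from [spectral_odds_ratios()])
#'   with `bait`, `prey`, `significant`.
#' @param annotations Tibble `prey`, `direction` with direction in
#'   activator/repressor/both/unknown (a curated literature annotation).
#' @return Tibble: `bait`, `n_activator`, `n_repressor`, `label`.
#' @export
classify_regulatory_direction <- function(interactions, annotations) {
  if (!all(c("prey", "direction") %in% names(annotations))) {
    abort("`annotations` needs `prey` and `direction` columns")
  }
  bad <- setdiff(unique(annotations$direction),
                 c("activator", "repressor", "both", "unknown"))
  if (length(bad) > 0) {
    abort(paste0("unknown direction value(s): ", paste(bad, collapse = ", ")))
  }
  sig <- interactions[interactions$significant, c("bait", "prey")]
  sig <- left_join(sig, annotations[, c("prey", "direction")], by = "prey")
  sig$direction[is.na(sig$direction)] <- "unknown"
  rows <- lapply(split(sig, sig$bait), function(s) {
    n_act <- sum(s$direction %in% c("activator", "both"))
    n_rep <- sum(s$direction %in% c("repressor", "both"))
    label <- if (n_act > 0 && n_rep > 0) "both"
    else if (n_act > 0) "activator-only"
    else if (n_rep > 0) "repressor-only"
    else "none"
    tibble(bait = as.character(s$bait[1]), n_activator = n_act,
           n_repressor = n_rep, label = label)
  })
  bind_rows(rows)
}

#' Expression response of genes with bound promoters
#'
#' For each bait, compares the induced-minus-control expression change of
#' genes whose promoter (within 10 kb of the TSS) is bound by that protein
#' against the change of all other genes, with a two-sided Wilcoxon
#' rank-sum test; BH correction across baits. The direction for significant
#' baits is the sign of the median difference.
#'
#' @param expr Long expression tibble: `gene`, `condition`, `expression`,
#'   where condition is "control" or a bait label.
#' @param bound_genes Named list: bait -> character vector of bound genes.
#' @param fdr BH threshold (default 0.01).
#' @return Tibble: `bait`, `n_bound`, `median_shift`, `p_value`, `q_value`,
#'   `significant`, `direction` ("up", "down" or NA).
#' @export
expression_response_test <- function(expr, bound_genes, fdr = 0.01) {
  need <- c("gene", "condition", "expression")
  if (!all(need %in% names(expr))) {
    abort(paste0("`expr` needs columns: ", paste(need, collapse = ", ")))
  }
  ctrl <- expr[expr$condition == "control", ]
  if (nrow(ctrl) == 0) abort("`expr` has no control condition")
  ctrl_v <- stats::setNames(ctrl$expression, ctrl$gene)
  rows <- lapply(names(bound_genes), function(b) {
    ind <- expr[expr$condition == b, ]
    if (nrow(ind) == 0) {
      warn(sprintf("no expression data for bait %s; skipped", b))
      return(NULL)
    }
    delta <- ind$expression - ctrl_v[ind$gene]
    bound <- ind$gene %in% bound_genes[[b]]
    if (sum(bound) == 0 || sum(!bound) == 0) {
      warn(sprintf("bait %s has an empty bound or unbound gene set; skipped",
                   b))
      return(NULL)
    }
    wt <- suppressWarnings(stats::wilcox.test(delta[bound], delta[!bound],
                                              alternative = "two.sided"))
    tibble(bait = b, n_bound = sum(bound),
           median_shift = stats::median(delta[bound]) -
             stats::median(delta[!bound]),
           p_value = wt$p.value)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("no bait could be tested")
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < fdr
  out$direction <- ifelse(out$significant,
                          ifelse(out$median_shift > 0, "up", "down"),
                          NA_character_)
  out
}
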