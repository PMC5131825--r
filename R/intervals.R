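# Interval arithmetic on tibbles of genomic intervals.
#
# All coordinates are 0-based half-open [start, end). An "interval tibble"
# has at least columns chrom, start, end; peak tibbles add summit (absolute
# coordinate), score, protein and optionally replicate.

check_intervals <- function(x, need = c("chrom", "start", "end"),
                            arg = deparse(substitute(x))) {
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg,
                  paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$start >= x$end)) {
    bad <- which(x$start < 0 | x$start >= x$end)[1]
    abort(sprintf("`%s` row %d violates 0 <= start < end", arg, bad))
  }
  if ("summit" %in% need) {
    ok <- !is.na(x$summit) & x$summit >= x$start & x$summit < x$end
    if (!all(ok)) {
      abort(sprintf("`%s` row %d: summit missing or outside [start, end)",
                    arg, which(!ok)[1]))
    }
  }
  if ("score" %in% need && (any(is.na(x$score)) || any(x$score < 0))) {
    abort(sprintf("`%s` row %d: score missing or negative", arg,
                  which(is.na(x$score) | x$score < 0)[1]))
  }
  invisible(x)
}

#' Collapse an interval tibble to its union
#'
#' Merges overlapping (book-ended intervals are kept separate) intervals per
#' chromosome, returning the minimal sorted set covering the same bases.
#'
#' @param x Tibble with columns `chrom`, `start`, `end`.
#' @return Tibble with columns `chrom`, `start`, `end`, sorted, non-overlapping.
#' @export
merge_intervals <- function(x) {
  check_intervals(x)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  x <- x[order(x$chrom, x$start, x$end), c("chrom", "start", "end")]
  out <- lapply(split(x, x$chrom), function(p) {
    cme <- cummax(p$end)
    grp <- cumsum(c(TRUE, p$start[-1] > cme[-nrow(p)]))
    tibble(chrom = p$chrom[1],
           start = as.numeric(tapply(p$start, grp, min)),
           end   = as.numeric(tapply(p$end, grp, max)))
  })
  bind_rows(out)
}

total_bp <- function(x) if (nrow(x) == 0) 0 else sum(x$end - x$start)

#' Base-pair Jaccard similarity of two interval sets
#'
#' Intersection over union of covered base pairs, summed across chromosomes
#' (the bedtools-jaccard convention). Each set is internally merged first, so
#' overlapping peaks within one set are not double counted. Two empty sets
#' have similarity 0 by definition.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @return A number in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  ma <- merge_intervals(a)
  mb <- merge_intervals(b)
  bp_a <- total_bp(ma)
  bp_b <- total_bp(mb)
  if (bp_a + bp_b == 0) return(0)
  bp_u <- total_bp(merge_intervals(bind_rows(ma, mb)))
  bp_i <- bp_a + bp_b - bp_u
  bp_i / bp_u
}

# Subtract merged set `b` from merged set `a` (both outputs of
# merge_intervals); returns the merged remainder.
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  out <- lapply(split(a, a$chrom), function(pa) {
    pb <- b[b$chrom == pa$chrom[1], , drop = FALSE]
    if (nrow(pb) == 0) return(pa)
    res_s <- numeric(0); res_e <- numeric(0)
    for (i in seq_len(nrow(pa))) {
      s <- pa$start[i]; e <- pa$end[i]
      ov <- pb[pb$end > s & pb$start < e, , drop = FALSE]
      cur <- s
      if (nrow(ov) > 0) {
        for (j in seq_len(nrow(ov))) {
          if (ov$start[j] > cur) { res_s <- c(res_s, cur); res_e <- c(res_e, ov$start[j]) }
          cur <- max(cur, ov$end[j])
        }
      }
      if (cur < e) { res_s <- c(res_s, cur); res_e <- c(res_e, e) }
    }
    tibble(chrom = pa$chrom[1], start = res_s, end = res_e)
  })
  bind_rows(out)
}

# For each query interval, TRUE iff it overlaps >= 1 bp of the merged subject
# set. Subject must be merged and sorted (merge_intervals output).
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  res <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sub <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    # idx = last subject interval starting at or before the query start
    idx <- findInterval(query$start[qi], sub$start)
    hit <- (idx >= 1 & sub$end[pmax(idx, 1)] > query$start[qi]) |
      (idx < nrow(sub) & sub$start[pmin(idx + 1, nrow(sub))] < query$end[qi])
    res[qi] <- hit
  }
  res
}

# Count points (chrom, pos) falling inside a merged interval set.
count_points_in <- function(points, subject) {
  if (nrow(points) == 0 || nrow(subject) == 0) return(0L)
  n <- 0L
  for (ch in unique(points$chrom)) {
    pos <- points$pos[points$chrom == ch]
    sub <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    idx <- findInterval(pos, sub$start)
    n <- n + sum(idx >= 1 & pos < sub$end[pmax(idx, 1)])
  }
  n
}

# Signed distance from each point to its nearest feature point on the same
# chromosome (NA if the chromosome has no feature).
nearest_signed_distance <- function(points, features) {
  out <- rep(NA_real_, nrow(points))
  for (ch in unique(points$chrom)) {
    qi <- which(points$chrom == ch)
    f <- sort(features$pos[features$chrom == ch])
    if (length(f) == 0) next
    p <- points$pos[qi]
    idx <- findInterval(p, f)
    lo <- pmax(idx, 1); hi <- pmin(idx + 1, length(f))
    d_lo <- p - f[lo]; d_hi <- p - f[hi]
    take_lo <- idx >= 1 & (idx >= length(f) | abs(d_lo) <= abs(d_hi))
    out[qi] <- ifelse(take_lo, d_lo, d_hi)
  }
  out
}
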