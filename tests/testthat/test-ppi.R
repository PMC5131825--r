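# AP-MS post-processing: prey filtering, odds ratios, replicate
# specificity, direction classification, expression response.

long_counts <- function(m, replicate = 1L) {
  tibble::tibble(bait = rep(rownames(m), times = ncol(m)),
                 prey = rep(colnames(m), each = nrow(m)),
                 replicate = replicate,
                 count = as.vector(m))
}

test_that("low-variation filter drops flat preys and keeps specific ones", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("B", 1:4), paste0("p", 1:3)))
  m[, 1] <- 10L           # identical in every bait: CV 0 -> dropped
  m[1, 2] <- 40L          # nonzero in exactly one bait -> retained
  m[, 3] <- c(0L, 2L, 30L, 1L)
  res <- filter_low_variation_preys(long_counts(m))
  expect_false(res$retained[res$prey == "p1"])
  expect_true(res$retained[res$prey == "p2"])
  expect_true(res$retained[res$prey == "p3"])
})

test_that("contaminants are dropped and module preys kept across seeds", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_world_config(n_proteins = 9, n_clusters = 3, seed = s)
    pp <- sim_ppi_counts(cfg)
    f <- filter_low_variation_preys(pp$counts)
    contam <- grepl("contam", f$prey)
    c(dropped = mean(!f$retained[contam]),
      kept = mean(f$retained[!contam]))
  }, numeric(2))
  expect_gte(mean(hits["dropped", ]), 0.9)
  expect_gte(mean(hits["kept", ]), 0.95)
})

test_that("odds ratios match the stated formula on a hand-computed toy", {
  # 3 baits x 2 preys, alpha = 1, fallback significance off (none reach 5)
  m <- matrix(c(2L, 1L, 0L,
                1L, 1L, 2L), 3, 2,
              dimnames = list(c("B1", "B2", "B3"), c("p1", "p2")))
  res <- spectral_odds_ratios(long_counts(m), alpha = 1)
  P <- 2
  Ti <- rowSums(m)
  # background for (B1, p1): the other two baits (leave-one-out), no pair
  # significant under the count fallback
  p1 <- (sum(m[2:3, 1]) + 1) / (sum(Ti[2:3]) + 1 * P)
  q11 <- (m[1, 1] + 1) / (Ti[1] + 1 * P)
  expect_equal(res$odds_ratio[res$bait == "B1" & res$prey == "p1"],
               unname((q11 / (1 - q11)) / (p1 / (1 - p1))))
  expect_false(any(res$significant))
})

test_that("a bait-exclusive prey gets the top odds ratio in that bait", {
  set.seed(8)
  m <- matrix(stats::rpois(50, 3), 5, 10,
              dimnames = list(paste0("B", 1:5), paste0("p", 1:10)))
  m[, 10] <- 0L
  m[2, 10] <- 60L  # exclusive to B2
  res <- spectral_odds_ratios(long_counts(m))
  b2 <- res[res$bait == "B2", ]
  expect_equal(b2$prey[which.max(b2$odds_ratio)], "p10")
  expect_gt(max(b2$odds_ratio), 10)
})

test_that("proportional counts give odds ratios near 1", {
  Ti <- c(100L, 200L, 400L)
  frac <- c(0.3, 0.7)
  m <- outer(Ti, frac)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("B", 1:3), paste0("p", 1:2))
  res <- spectral_odds_ratios(long_counts(m), alpha = 0.01)
  expect_true(all(abs(log(res$odds_ratio)) < 0.15))
})

test_that("odds ratios are prey-order invariant and scale-stable as alpha -> 0", {
  set.seed(9)
  m <- matrix(stats::rpois(40, 5) + 1L, 4, 10,
              dimnames = list(paste0("B", 1:4), paste0("p", 1:10)))
  x <- long_counts(m)
  r1 <- spectral_odds_ratios(x)
  r2 <- spectral_odds_ratios(x[sample.int(nrow(x)), ])
  expect_equal(r1, r2)
  # at alpha -> 0, scaling one bait's counts leaves its ORs unchanged
  # (up to the significance fallback, which we hold fixed by alpha = 1e-9)
  x2 <- x
  x2$count <- ifelse(x2$bait == "B1", x2$count * 10L, x2$count)
  a <- spectral_odds_ratios(x, alpha = 1e-9)
  b <- spectral_odds_ratios(x2, alpha = 1e-9)
  keep <- a$bait == "B1" & !a$significant & !b$significant
  expect_equal(log(a$odds_ratio[keep]), log(b$odds_ratio[keep]),
               tolerance = 1e-3)
})

test_that("AvgP-based significance uses the cutoff and controls background", {
  m <- matrix(c(50L, 0L, 0L,
                5L, 5L, 5L), 3, 2,
              dimnames = list(c("B1", "B2", "CTRL"), c("p1", "p2")))
  avgp <- tibble::tibble(bait = "B1", prey = "p1", avgp = 1)
  res <- spectral_odds_ratios(long_counts(m), avgp = avgp,
                              control_baits = "CTRL")
  expect_true(res$significant[res$bait == "B1" & res$prey == "p1"])
  expect_equal(sum(res$significant), 1)
  # prey significant in every non-control bait -> background from controls
  avgp2 <- tibble::tibble(bait = c("B1", "B2"), prey = "p1", avgp = 1)
  res2 <- spectral_odds_ratios(long_counts(m), avgp = avgp2,
                               control_baits = "CTRL")
  expect_true(all(is.finite(res2$odds_ratio)))
  # significant in every bait and no controls declared: no background left
  avgp3 <- tibble::tibble(bait = c("B1", "B2", "CTRL"), prey = "p1",
                          avgp = 1)
  expect_error(spectral_odds_ratios(long_counts(m), avgp = avgp3),
               "negative-control")
})

test_that("replicate profiles are specific when baits are orthogonal", {
  m1 <- matrix(c(20L, 0L, 0L, 20L), 2, 2,
               dimnames = list(c("B1", "B2"), c("p1", "p2")))
  x <- dplyr::bind_rows(long_counts(m1, 1L), long_counts(m1, 2L))
  res <- replicate_profile_specificity(x)
  expect_equal(res$fraction, 1)
  # a shared dominant contaminant makes correlations tie: false + warning
  m2 <- matrix(c(30L, 30L, 30L, 30L), 2, 2,
               dimnames = list(c("B1", "B2"), c("p1", "p2")))
  y <- dplyr::bind_rows(long_counts(m2, 1L), long_counts(m2, 2L))
  expect_warning(res2 <- replicate_profile_specificity(y), "tie")
  expect_equal(res2$fraction, 0)
})

test_that("planted-module worlds give specific replicate profiles", {
  fr <- vapply(1:10, function(s) {
    cfg <- sim_world_config(n_proteins = 9, n_clusters = 3, seed = s)
    pp <- sim_ppi_counts(cfg)
    f <- filter_low_variation_preys(pp$counts)
    real <- pp$counts[!pp$counts$bait %in% pp$control_baits, ]
    replicate_profile_specificity(real, preys = f$prey[f$retained])$fraction
  }, numeric(1))
  expect_gte(mean(fr), 0.9)
})

test_that("regulatory direction labels follow the union rule", {
  ints <- tibble::tibble(
    bait = c("A", "A", "B", "C", "C", "D"),
    prey = c("act1", "unk1", "both1", "act1", "rep1", "unk1"),
    significant = TRUE)
  ann <- tibble::tibble(
    prey = c("act1", "rep1", "both1"),
    direction = c("activator", "repressor", "both"))
  res <- classify_regulatory_direction(ints, ann)
  lab <- stats::setNames(res$label, res$bait)
  expect_equal(lab[["A"]], "activator-only")
  expect_equal(lab[["B"]], "both")
  expect_equal(lab[["C"]], "both")
  expect_equal(lab[["D"]], "none")
  expect_error(classify_regulatory_direction(
    ints, tibble::tibble(prey = "x", direction = "enhancer")),
    "direction")
})

test_that("expression response recovers a planted shift and its sign", {
  set.seed(10)
  genes <- paste0("g", 1:1000)
  base <- stats::rnorm(1000, 8, 1)
  mk_expr <- function(effect) {
    bound <- genes[1:200]
    expr <- dplyr::bind_rows(
      tibble::tibble(gene = genes, condition = "control",
                     expression = base + stats::rnorm(1000, 0, 0.5)),
      tibble::tibble(gene = genes, condition = "ZNF001",
                     expression = base + stats::rnorm(1000, 0, 0.5) +
                       effect * (genes %in% bound)))
    list(expr = expr, bound = list(ZNF001 = bound))
  }
  up <- mk_expr(1)
  res <- expression_response_test(up$expr, up$bound)
  expect_true(res$significant)
  expect_equal(res$direction, "up")
  expect_equal(res$median_shift, 1, tolerance = 0.25)
  dn <- mk_expr(-1)
  res2 <- expression_response_test(dn$expr, dn$bound)
  expect_equal(res2$direction, "down")
  # empty bound set is skipped with a warning
  expect_warning(
    expect_error(expression_response_test(up$expr, list(ZNF001 = character())),
                 "no bait"),
    "empty")
})

test_that("expression response is calibrated under the null", {
  set.seed(11)
  genes <- paste0("g", 1:400)
  base <- stats::rnorm(400, 8, 1)
  n_sig <- vapply(1:20, function(i) {
    baits <- paste0("B", 1:5)
    expr <- dplyr::bind_rows(
      tibble::tibble(gene = genes, condition = "control",
                     expression = base + stats::rnorm(400, 0, 0.5)),
      dplyr::bind_rows(lapply(baits, function(b) {
        tibble::tibble(gene = genes, condition = b,
                       expression = base + stats::rnorm(400, 0, 0.5))
      })))
    bound <- stats::setNames(lapply(baits, function(b) sample(genes, 50)),
                             baits)
    sum(expression_response_test(expr, bound)$significant)
  }, numeric(1))
  expect_lte(mean(n_sig > 0), 0.05)
})

test_that("the Wilcoxon p-value matches an exact permutation oracle", {
  # two small groups pushed through expression_response_test
  set.seed(12)
  genes <- paste0("g", 1:12)
  delta <- stats::rnorm(12)
  expr <- dplyr::bind_rows(
    tibble::tibble(gene = genes, condition = "control", expression = 0),
    tibble::tibble(gene = genes, condition = "B1", expression = delta))
  bound <- list(B1 = genes[1:5])
  res <- expression_response_test(expr, bound)
  # oracle: exact distribution of the rank-sum over all C(12,5) splits
  splits <- utils::combn(12, 5)
  obs <- sum(rank(delta)[1:5])
  null <- apply(splits, 2, function(ix) sum(rank(delta)[ix]))
  mu <- 5 * 13 / 2
  p_exact <- mean(abs(null - mu) >= abs(obs - mu) - 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 1e-10)
})

test_that("odds-ratio ranking separates planted preys from contaminants", {
  aur <- vapply(1:10, function(s) {
    cfg <- sim_world_config(n_proteins = 9, n_clusters = 3, seed = s)
    pp <- sim_ppi_counts(cfg)
    f <- filter_low_variation_preys(pp$counts)
    ors <- spectral_odds_ratios(pp$counts, control_baits = pp$control_baits)
    tr <- dplyr::left_join(ors, pp$truth, by = c("bait", "prey"))
    tr <- tr[!tr$bait %in% pp$control_baits, ]
    per_bait <- vapply(split(tr, tr$bait), function(s2) {
      if (!any(s2$planted) || all(s2$planted)) return(NA_real_)
      bruteforce_auroc(s2$odds_ratio[s2$planted],
                       s2$odds_ratio[!s2$planted])
    }, numeric(1))
    mean(per_bait, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(aur), 0.95)
})
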