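# PAM clustering, silhouettes, the 95%-of-max profile-count rule, motif
# distances and cross-parameter correlation.

test_that("PAM recovers two well-separated planted groups", {
  bd <- block_distance(c(5, 5))
  fit <- pam_cluster(bd$d, 2)
  expect_equal(length(unique(fit$assignment[bd$labels == 1])), 1)
  expect_equal(length(unique(fit$assignment[bd$labels == 2])), 1)
  expect_false(fit$assignment[1] == fit$assignment[10])
})

test_that("PAM objective equals the exhaustive minimum on n = 6", {
  set.seed(13)
  for (rep in 1:5) {
    d <- as.matrix(stats::dist(matrix(stats::rnorm(12), 6, 2)))
    for (k in 2:4) {
      fit <- pam_cluster(d, k)
      combs <- utils::combn(6, k)
      objs <- apply(combs, 2, function(med) {
        sum(apply(d[, med, drop = FALSE], 1, min))
      })
      expect_equal(fit$objective, min(objs), tolerance = 1e-12)
    }
  }
})

test_that("PAM agrees with the reference implementation on random matrices", {
  skip_if_not_installed("cluster")
  set.seed(14)
  for (rep in 1:5) {
    d <- as.matrix(stats::dist(matrix(stats::rnorm(40), 20, 2)))
    for (k in c(2, 4)) {
      fit <- pam_cluster(d, k)
      ref <- cluster::pam(stats::as.dist(d), k)
      # never worse than the reference local search (the exact branch can
      # beat it on small instances)
      ref_obj <- sum(apply(d[, ref$id.med, drop = FALSE], 1, min))
      expect_lte(fit$objective, ref_obj + 1e-8)
      heur <- pam_cluster(d, k, exact_limit = 0)
      expect_gte(heur$objective, fit$objective - 1e-8)
    }
  }
})

test_that("k = n - 1 leaves one non-medoid at its nearest medoid distance", {
  d <- as.matrix(stats::dist(matrix(stats::rnorm(10), 5, 2)))
  fit <- pam_cluster(d, 4)
  non_med <- setdiff(1:5, fit$medoids)
  expect_equal(fit$objective, min(d[non_med, fit$medoids]))
})

test_that("PAM is invariant under entity relabeling", {
  bd <- block_distance(c(4, 4, 4), seed = 5)
  fit1 <- pam_cluster(bd$d, 3)
  perm <- c(9:12, 1:8)
  d2 <- bd$d[perm, perm]
  fit2 <- pam_cluster(d2, 3)
  # partitions agree modulo label permutation
  part1 <- fit1$assignment[perm]
  tab <- table(part1, fit2$assignment)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("mean silhouette matches hand computation and edge cases", {
  # two tight distant clusters approach 1
  bd <- block_distance(c(5, 5), within = 0.01, between = 5)
  fit <- pam_cluster(bd$d, 2)
  expect_gt(mean_silhouette(bd$d, fit$assignment), 0.95)
  # all points equidistant: a = b -> 0
  d0 <- matrix(1, 4, 4); diag(d0) <- 0
  expect_equal(mean_silhouette(d0, c(1, 1, 2, 2)), 0)
  # 5-point hand example
  d5 <- matrix(0, 5, 5)
  d5[1, 2] <- d5[2, 1] <- 1
  d5[1, 3] <- d5[3, 1] <- 4; d5[2, 3] <- d5[3, 2] <- 4
  d5[1, 4] <- d5[4, 1] <- 5; d5[2, 4] <- d5[4, 2] <- 5
  d5[3, 4] <- d5[4, 3] <- 1
  d5[1, 5] <- d5[5, 1] <- 5; d5[2, 5] <- d5[5, 2] <- 5
  d5[3, 5] <- d5[5, 3] <- 1.5; d5[4, 5] <- d5[5, 4] <- 1.5
  asn <- c(1, 1, 2, 2, 2)
  s1 <- (4.5 - 1) / 4.5          # a(1)=1, b(1)=mean(4,5,5)=14/3? hand:
  # entity 1: a = 1, b = mean(4, 5, 5) = 14/3; s = (14/3 - 1)/(14/3)
  s1 <- (14 / 3 - 1) / (14 / 3)
  s2 <- (14 / 3 - 1) / (14 / 3)
  s3 <- ((4 + 4) / 2 - (1 + 1.5) / 2) / ((4 + 4) / 2)
  s4 <- ((5 + 5) / 2 - (1 + 1.5) / 2) / ((5 + 5) / 2)
  s5 <- ((5 + 5) / 2 - (1.5 + 1.5) / 2) / ((5 + 5) / 2)
  expect_equal(mean_silhouette(d5, asn), mean(c(s1, s2, s3, s4, s5)))
  # singleton clusters contribute 0
  expect_equal(mean_silhouette(d0, c(1, 2, 3, 4)), 0)
})

test_that("mean silhouette agrees with the reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(15)
  for (rep in 1:10) {
    n <- sample(8:50, 1)
    d <- as.matrix(stats::dist(matrix(stats::rnorm(2 * n), n, 2)))
    asn <- sample(1:3, n, replace = TRUE)
    if (length(unique(asn)) < 2) next
    ref <- cluster::silhouette(asn, stats::as.dist(d))
    expect_equal(mean_silhouette(d, asn), mean(ref[, "sil_width"]),
                 tolerance = 1e-10)
  }
})

test_that("the 95%-of-max rule recovers planted cluster counts", {
  ok <- vapply(1:20, function(s) {
    bd <- block_distance(c(8, 8, 7, 7), within = 0.2, between = 1, seed = s)
    prof <- estimate_profile_count(bd$d, k_max = 10)
    prof$estimated_k == 4
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("profile-count estimator honours its invariants and edge cases", {
  bd <- block_distance(c(6, 6, 6), seed = 16)
  prof <- estimate_profile_count(bd$d, k_max = 8)
  expect_true(prof$estimated_k %in% prof$table$k)
  sil_at <- prof$table$mean_silhouette[prof$table$k == prof$estimated_k]
  expect_gte(sil_at, 0.95 * prof$max_silhouette)
  # all-identical entities: degenerate flag, estimated_k = k_max
  d0 <- matrix(0, 6, 6)
  prof0 <- estimate_profile_count(d0, k_max = 4)
  expect_true(prof0$degenerate)
  expect_equal(prof0$estimated_k, 4)
  # n = 3 evaluates only k = 2
  d3 <- as.matrix(stats::dist(matrix(stats::rnorm(6), 3, 2)))
  prof3 <- estimate_profile_count(d3, k_max = 2)
  expect_equal(prof3$table$k, 2)
  expect_equal(prof3$estimated_k, 2)
  # broom/ggplot accessors
  expect_s3_class(tidy(prof), "tbl_df")
  expect_equal(glance(prof)$estimated_k, prof$estimated_k)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
})

test_that("hierarchical robustness check finds the same planted count", {
  bd <- block_distance(c(8, 8, 8), within = 0.2, between = 1, seed = 17)
  expect_equal(estimate_profile_count_hclust(bd$d, k_max = 8)$estimated_k, 3)
})

test_that("motif distance is zero for identical and reverse-complement PWMs", {
  set.seed(18)
  p <- zfdiv:::sharp_random_pwm(8)
  expect_equal(motif_distance(p, p), 0, tolerance = 1e-12)
  rc <- zfdiv:::pwm_revcomp(p)
  expect_equal(motif_distance(p, rc), 0, tolerance = 1e-12)
})

test_that("motif distance equals an exhaustive offset enumeration", {
  set.seed(19)
  a <- zfdiv:::sharp_random_pwm(6)
  b <- zfdiv:::sharp_random_pwm(6)
  # oracle: enumerate every offset and orientation directly
  sim_of <- function(ma, mb) {
    best <- -Inf
    for (off in -(6 - 4):(6 - 4)) {
      ia <- max(1, 1 + off):min(6, 6 + off)
      ib <- ia - off
      cors <- mapply(function(x, y) {
        cx <- ma[, x]; cy <- mb[, y]
        if (max(abs(cx - cy)) < 1e-12) 1
        else if (stats::sd(cx) == 0 || stats::sd(cy) == 0) 0
        else stats::cor(cx, cy)
      }, ia, ib)
      best <- max(best, mean(cors))
    }
    best
  }
  oracle <- 1 - max(sim_of(a$matrix, b$matrix),
                    sim_of(a$matrix, zfdiv:::pwm_revcomp(b)$matrix))
  expect_equal(motif_distance(a, b), oracle, tolerance = 1e-12)
})

test_that("cross-parameter correlation behaves on linear and null cases", {
  set.seed(20)
  n <- 20
  labs <- paste0("e", 1:n)
  mk_sim <- function(v) {
    m <- matrix(0, n, n, dimnames = list(labs, labs))
    m[upper.tri(m)] <- v
    m <- m + t(m); diag(m) <- 1
    m
  }
  base_v <- stats::runif(n * (n - 1) / 2)
  s1 <- mk_sim(base_v)
  s2 <- mk_sim(0.3 + 0.5 * base_v)  # exact linear transform
  res <- cross_parameter_correlation(list(a = s1, b = s2))
  expect_equal(as.matrix(res)["a", "b"], 1, tolerance = 1e-12)
  expect_equal(as.matrix(res)["a", "a"], 1)
  # independent random similarity matrices decorrelate
  n2 <- 50
  labs2 <- paste0("x", 1:n2)
  rnd <- function() {
    m <- matrix(0, n2, n2, dimnames = list(labs2, labs2))
    m[upper.tri(m)] <- stats::runif(n2 * (n2 - 1) / 2)
    m + t(m) + diag(n2)
  }
  rs <- vapply(1:20, function(i) {
    as.matrix(cross_parameter_correlation(list(a = rnd(), b = rnd())))["a", "b"]
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.3), 0.95)
  # pair subsets restrict the vectorisation
  ps <- cbind(labs[1:5], labs[6:10])
  res2 <- cross_parameter_correlation(list(a = s1, b = s2), pair_subset = ps)
  expect_equal(as.matrix(res2)["a", "b"], 1, tolerance = 1e-12)
  expect_error(cross_parameter_correlation(list(a = s1, b = s2),
                                           pair_subset = ps[1:2, ]),
               "at least 3")
})
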