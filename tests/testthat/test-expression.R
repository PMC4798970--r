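mk_em <- function(values, tp = NULL, dp = NULL) {
  if (is.null(tp)) tp <- seq(0, by = 30, length.out = ncol(values))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  expression_matrix(values, tp, dp)
}

test_that("detection filter keeps genes detected in any condition", {
  v <- matrix(1:12, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  dp <- matrix(0.5, 3, 4); dp[2, 3] <- 0.01
  em <- mk_em(v, dp = dp)
  kept <- filter_detected(em)
  expect_identical(rownames(kept$values), "b")
  expect_identical(rownames(filter_detected(em, p_threshold = 1)$values),
                   rownames(v))
  expect_error(filter_detected(mk_em(v)), "no detection p-values")
})

test_that("deregulation needs a strict two-fold change versus t = 0", {
  v <- rbind(flat = rep(5, 4),
             up = c(5, 6, 11, 9),        # 2.2x: log2 = 1.14
             edge = c(5, 10, 10, 5),     # exactly 2x: not deregulated
             down = c(8, 8, 3, 8))       # 0.375x: log2 = -1.41
  der <- call_deregulated(mk_em(v))
  expect_equal(der$direction, c("none", "up", "none", "down"))
  expect_error(call_deregulated(mk_em(rbind(a = c(0, 1, 2, 3)))), "positive")
  expect_error(call_deregulated(mk_em(v, tp = c(10, 40, 70, 100))), "reference")
})

test_that("standardization yields shape profiles with mean 0 and unit sd", {
  set.seed(3)
  v <- matrix(rlnorm(50, 1, 0.6), 10, 5,
              dimnames = list(paste0("g", 1:10), NULL))
  z <- standardize_profiles(mk_em(v))$z
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans(z^2)) - 1)), 1e-12)
  # scaling a profile by a constant leaves its standardized shape unchanged
  v2 <- v; v2[1, ] <- v[1, ] * 7.3
  expect_equal(standardize_profiles(mk_em(v2))$z[1, ], z[1, ])
  # re-standardizing adds nothing
  z2 <- standardize_profiles(mk_em(2^z))$z   # z is log2-scale already
  expect_equal(z2, z, tolerance = 1e-10)
  # constant rows are excluded with a warning
  v3 <- rbind(v, const = rep(4, 5))
  expect_warning(out <- standardize_profiles(mk_em(v3)), "zero-variance")
  expect_false("const" %in% rownames(out$z))
  expect_identical(out$excluded, "const")
})

test_that("fuzzy c-means recovers well-separated groups crisply", {
  set.seed(21)
  up <- t(replicate(20, seq(-1.2, 1.2, length.out = 6) + rnorm(6, 0, 0.15)))
  down <- t(replicate(20, seq(1.2, -1.2, length.out = 6) + rnorm(6, 0, 0.15)))
  x <- rbind(up, down)
  rownames(x) <- paste0("g", 1:40)
  cl <- fuzzy_cmeans(x, 2, m = 1.5, seed = 6)
  expect_equal(unname(rowSums(cl$memberships)), rep(1, 40), tolerance = 1e-12)
  cores <- extract_cores(cl$memberships)
  expect_setequal(lengths(cores), c(20, 20))
  planted <- list(paste0("g", 1:20), paste0("g", 21:40))
  expect_true(setequal(cores[[1]], planted[[1]]) ||
                setequal(cores[[1]], planted[[2]]))
  # objective decreases monotonically
  expect_true(all(diff(cl$objective) <= 1e-8))
  # near-hard limit as m -> 1
  cl_hard <- fuzzy_cmeans(x, 2, m = 1.05, seed = 6)
  expect_true(all(apply(cl_hard$memberships, 1, max) > 0.99))
  # identical seed, identical result
  expect_identical(fuzzy_cmeans(x, 2, m = 1.5, seed = 6)$memberships,
                   cl$memberships)
})

test_that("hand-rolled c-means agrees with an independent implementation", {
  set.seed(33)
  sh <- list(c(-1, -0.5, 0.3, 0.9, 1.2), c(1.2, 0.6, -0.2, -0.8, -1.1),
             c(-1, 1.2, -0.4, 1, -0.6))
  x <- do.call(rbind, lapply(sh, function(s)
    t(replicate(15, s + rnorm(5, 0, 0.2)))))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  mine <- fuzzy_cmeans(x, 3, m = 1.5, seed = 2)
  ref <- e1071::cmeans(x, 3, m = 1.5, iter.max = 300)
  # same partition up to label permutation
  hard_mine <- apply(mine$memberships, 1, which.max)
  tab <- table(hard_mine, ref$cluster)
  perm_agree <- sum(apply(tab, 1, max)) / nrow(x)
  expect_gte(perm_agree, 0.95)
})

test_that("cluster-count curve drops sharply past the planted group number", {
  set.seed(5)
  sh <- list(c(-1.3, -0.6, 0.2, 0.8, 1.3), c(1.3, 0.7, 0, -0.7, -1.3),
             c(-1, 1.3, -0.8, 1.1, -0.9))
  x <- do.call(rbind, lapply(sh, function(s)
    t(replicate(25, s + rnorm(5, 0, 0.15)))))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  curve <- select_cluster_count(x, c_range = 2:6, m = 1.5, seed = 4)
  expect_equal(nrow(curve), 5)
  expect_true(all(diff(curve$min_intercentroid) <= 1e-8))
  expect_equal(curve$c[curve$elbow], 4)  # biggest relative drop entering c = 4
})

test_that("cores honour the membership threshold boundary", {
  u <- rbind(g1 = c(0.6, 0.4), g2 = c(0.5, 0.5), g3 = c(0.2, 0.8))
  colnames(u) <- c("c1", "c2")
  cores <- extract_cores(u)
  expect_identical(cores[[1]], c("g1", "g2"))   # 0.5 counts ("at least")
  expect_identical(cores[[2]], c("g2", "g3"))
  cores_strict <- extract_cores(u, threshold = 0.50001)
  expect_false(any(duplicated(unlist(cores_strict))))
  expect_identical(sort(unlist(extract_cores(u, threshold = 0))),
                   sort(rep(rownames(u), 2)))
})

test_that("overlap coefficient is the intersection over the smaller set", {
  expect_equal(overlap_coefficient(letters[1:4], letters[1:4]), 1)
  expect_equal(overlap_coefficient(letters[1:4], letters[5:8]), 0)
  expect_equal(overlap_coefficient(letters[1:4], c("a", "b", letters[10:17])), 0.5)
  expect_error(overlap_coefficient(character(0), "a"), "non-empty")
})

test_that("enrichment p-value matches the enumeration oracle and is valid", {
  universe <- paste0("g", 1:100)
  cluster <- paste0("g", 1:10)
  target <- paste0("g", c(1:5, 40:44))
  res <- enrichment_test(cluster, target, universe)
  expect_equal(res$p_value, hypergeom_tail(5, 5, 5, 85), tolerance = 1e-12)
  expect_equal(res$neg_log10_p, -log10(res$p_value))
  # perfect association is overwhelmingly significant
  half <- paste0("g", 1:50)
  expect_lt(enrichment_test(half, half, universe)$p_value, 1e-10)
  # validity under the null: P(p <= alpha) <= alpha (conservative exact test)
  set.seed(77)
  ps <- replicate(400, {
    cl <- sample(universe, 15)
    enrichment_test(cl, target, universe)$p_value
  })
  for (alpha in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 400))
  expect_error(enrichment_test("x", "x", character(0)), "empty universe")
})
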