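test_that("PCA ratios match a covariance eigendecomposition and its identities", {
  # collinear points: one component carries everything
  line <- cbind(1:6, 2 * (1:6))
  p1 <- score_pca(line, 2)
  expect_equal(p1$explained_variance_ratio[1], 1, tolerance = 1e-12)

  set.seed(101)
  m <- matrix(rnorm(15 * 4), 15, 4)
  p <- score_pca(m, 4)
  ev <- eigen(cov(m))$values
  expect_equal(p$explained_variance_ratio, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-9)

  # duplicating every sample leaves the ratios unchanged
  p_dup <- score_pca(rbind(m, m), 4)
  expect_equal(p_dup$explained_variance_ratio, p$explained_variance_ratio,
               tolerance = 1e-10)
  # deterministic sign: largest loading positive per component
  for (a in 1:4)
    expect_gt(p$loadings[which.max(abs(p$loadings[, a])), a], 0)
  expect_error(score_pca(matrix(0, 4, 3)), "all-zero")
})

test_that("PERMANOVA agrees with vegan::adonis2 and the hand formula", {
  set.seed(113)
  m <- matrix(rnorm(18 * 5), 18, 5) +
    rep(c(0, 1.2, 0), each = 6)[seq_len(18)]
  g <- factor(rep(c("a", "b", "c"), each = 6))
  res <- score_permanova(m, g, n_permutations = 199, seed = 4)
  brute <- brute_permanova_stats(m, g)
  expect_equal(res$pseudo_f, brute$f, tolerance = 1e-10)
  expect_equal(res$r_squared, brute$r2, tolerance = 1e-10)
  expect_equal(res$r_squared + brute$ssw_frac, 1, tolerance = 1e-12)

  df <- data.frame(g = g)
  ad <- vegan::adonis2(dist(m) ~ g, data = df, permutations = 99)
  expect_equal(res$pseudo_f, ad$F[1], tolerance = 1e-8)
  expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-8)

  mb <- abs(m)
  resb <- score_permanova(mb, g, distance = "braycurtis",
                          n_permutations = 199, seed = 4)
  adb <- vegan::adonis2(vegan::vegdist(mb, "bray") ~ g, data = df,
                        permutations = 99)
  expect_equal(resb$pseudo_f, adb$F[1], tolerance = 1e-8)
})

test_that("small designs switch to exact enumeration matching brute force", {
  set.seed(127)
  m <- matrix(rnorm(6 * 3), 6, 3)
  g <- rep(c("x", "y"), each = 3)
  expect_message(res <- score_permanova(m, g, n_permutations = 999, seed = 1),
                 "exact enumeration over 20")
  expect_true(res$exact)
  expect_equal(res$n_permutations, 20L)
  expect_equal(res$p_value, brute_exact_p_2group(m, g), tolerance = 1e-12)
  expect_gte(res$p_value, 1 / 20)
})

test_that("separated groups saturate R2 and the permutation floor", {
  set.seed(131)
  m <- rbind(matrix(rnorm(40, 0, 0.05), 8, 5),
             matrix(rnorm(40, 50, 0.05), 8, 5))
  g <- rep(c("lo", "hi"), each = 8)
  res <- score_permanova(m, g, n_permutations = 199, seed = 9)
  expect_gt(res$r_squared, 0.99)
  expect_equal(res$p_value, 1 / 200)
})

test_that("PERMANOVA seeding is reproducible and MC-consistent across seeds", {
  set.seed(137)
  m <- matrix(rnorm(20 * 4), 20, 4)
  g <- rep(c("a", "b"), each = 10)
  r1 <- score_permanova(m, g, n_permutations = 499, seed = 42)
  r2 <- score_permanova(m, g, n_permutations = 499, seed = 42)
  expect_identical(r1, r2)
  r3 <- score_permanova(m, g, n_permutations = 499, seed = 43)
  mc <- 2 * sqrt(r1$p_value * (1 - r1$p_value) / 499)
  expect_lte(abs(r1$p_value - r3$p_value), mc + 0.02)
  expect_error(score_permanova(m[1:11, ], factor(c(rep("a", 10), "b")),
                               n_permutations = 199, seed = 1),
               "at least 2 samples")
  expect_error(score_permanova(m, g, n_permutations = 199), "seed")
})

test_that("correlations match direct formulas, flag degeneracies, adjust with BH", {
  x <- c(1, 2, 3, 4, 5)
  sc <- structure(matrix(c(x, 2 * x), 5, 2,
                         dimnames = list(paste0("s", 1:5), c("lin", "double"))),
                  class = c("dietary_scores", "matrix", "array"),
                  levels = c(lin = 1L, double = 1L), fill = "zeros",
                  normalized = FALSE)
  md <- data.frame(sample_id = paste0("s", 1:5),
                   y = c(2, 1, 4, 3, 5),
                   exact = 2 * x + 3,
                   flat = rep(1, 5))
  ct <- score_correlate(sc, md)
  r_direct <- sum((x - mean(x)) * (md$y - mean(md$y))) /
    sqrt(sum((x - mean(x))^2) * sum((md$y - mean(md$y))^2))
  got <- ct[ct$category == "lin" & ct$variable == "y", ]
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  t_stat <- r_direct * sqrt(3) / sqrt(1 - r_direct^2)
  expect_equal(got$p, 2 * pt(-abs(t_stat), 3), tolerance = 1e-12)
  expect_equal(ct[ct$category == "lin" & ct$variable == "exact", "r"], 1,
               tolerance = 1e-12)
  flat_rows <- ct[ct$variable == "flat", ]
  expect_true(all(flat_rows$flag == "degenerate"))
  expect_true(all(is.na(flat_rows$q)))
  usable <- ct$flag == ""
  expect_equal(ct$q[usable], p.adjust(ct$p[usable], "BH"))
  expect_true(all(ct$q[usable] >= ct$p[usable] - 1e-12))
})

test_that("correlation is affine-invariant and self-correlation is 1", {
  set.seed(139)
  x <- rnorm(10)
  sc <- structure(matrix(x, 10, 1, dimnames = list(paste0("s", 1:10), "c1")),
                  class = c("dietary_scores", "matrix", "array"),
                  levels = c(c1 = 1L), fill = "zeros", normalized = FALSE)
  md <- data.frame(sample_id = paste0("s", 1:10), same = x,
                   affine = 3.2 * x + 7)
  ct <- score_correlate(sc, md)
  expect_equal(ct$r[ct$variable == "same"], 1, tolerance = 1e-12)
  expect_equal(ct$r[ct$variable == "affine"], 1, tolerance = 1e-12)
})

test_that("null correlation p-values are uniform (KS on 1000 simulations)", {
  set.seed(149)
  ps <- replicate(1000, {
    x <- rnorm(10); y <- rnorm(10)
    sc <- structure(matrix(x, 10, 1, dimnames = list(paste0("s", 1:10), "c1")),
                    class = c("dietary_scores", "matrix", "array"),
                    levels = c(c1 = 1L), fill = "zeros", normalized = FALSE)
    score_correlate(sc, data.frame(sample_id = paste0("s", 1:10), y = y))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
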