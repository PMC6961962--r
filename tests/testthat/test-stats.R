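test_that("Kruskal-Wallis H matches the exact rank formula", {
  got <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(got$statistic, 12 / 42 * 13.5)   # = 3.857142...
  expect_equal(got$df, 1)
  # identical groups: H = 0, p = 1
  same <- kruskal_wallis(rep(c(5, 5, 5), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("Kruskal-Wallis agrees with the base implementation on ties", {
  set.seed(51)
  v <- sample(1:6, 30, replace = TRUE)
  g <- rep(c("a", "b", "c"), each = 10)
  got <- kruskal_wallis(v, g)
  ref <- stats::kruskal.test(v, factor(g))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, unname(ref$p.value))
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(52)
  v <- rlnorm(24); g <- rep(c("a", "b", "c"), 8)
  h0 <- kruskal_wallis(v, g)$statistic
  expect_equal(kruskal_wallis(log(v), g)$statistic, h0)
  expect_equal(kruskal_wallis(rank(v), g)$statistic, h0)
})

test_that("the permutation p-value converges to the exhaustive oracle", {
  set.seed(53)
  v <- c(1.2, 3.4, 2.2, 5.1, 4.4, 4.4, 0.7)   # n = 7, one tie
  g <- rep(c("a", "b"), c(3, 4))
  exact <- exact_kw_p(v, g)
  mc <- kruskal_wallis(v, g, p_method = "permutation", n_perm = 20000,
                       seed = 2)
  expect_lt(abs(mc$p_value - exact), 0.02)
})

test_that("Dunn z-statistics collapse to H for two groups", {
  set.seed(54)
  v <- sample(1:8, 14, replace = TRUE)
  g <- rep(c("a", "b"), 7)
  z <- dunn_posthoc(v, g)$z
  H <- kruskal_wallis(v, g)$statistic
  expect_equal(z^2, H)
})

test_that("Dunn flags exactly the pairs involving a shifted group", {
  set.seed(55)
  v <- c(rnorm(15), rnorm(15), rnorm(15, 8))
  g <- rep(c("a", "b", "c"), each = 15)
  d <- dunn_posthoc(v, g)
  sig <- d$p_adjusted < 0.05
  involves_c <- d$group1 == "c" | d$group2 == "c"
  expect_equal(sig, involves_c)
  expect_true(all(d$p_adjusted >= d$p_value))
  expect_true(all(d$p_adjusted <= 1))
})

test_that("Bonferroni-adjusted alpha divides by the family size", {
  expect_equal(bonferroni_alpha(0.05, 14), 0.05 / 14)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
})

test_that("Bray-Curtis has the formula's values, bounds and symmetry", {
  m <- rbind(c(2, 2), c(2, 0))
  d <- bray_curtis(m, transform = "none")
  expect_equal(d[1, 2], 1 / 3)
  ident <- bray_curtis(rbind(c(1, 2), c(1, 2)), transform = "none")
  expect_equal(ident[1, 2], 0)
  disj <- bray_curtis(rbind(c(1, 0), c(0, 3)), transform = "none")
  expect_equal(disj[1, 2], 1)
  set.seed(56)
  x <- matrix(rpois(40, 4), 8, 5)
  dd <- unclass(bray_curtis(x))
  expect_equal(dd, t(dd))
  expect_true(all(diag(dd) == 0))
  expect_true(all(dd >= 0 & dd <= 1))
  # all-zero pair undefined but matrix-level error only when all zero
  z <- rbind(c(0, 0), c(0, 0), c(1, 2))
  dz <- bray_curtis(z, transform = "none")
  expect_true(is.na(dz[1, 2]))
  expect_equal(attr(dz, "n_undefined"), 1)
  expect_error(bray_curtis(matrix(0, 2, 2)), "All-zero")
})

test_that("Bray-Curtis matches vegan's vegdist after square roots", {
  skip_if_not_installed("vegan")
  set.seed(57)
  x <- matrix(rpois(60, 6) + 0.5, 10, 6)
  mine <- unclass(bray_curtis(x, transform = "sqrt"))
  ref <- as.matrix(vegan::vegdist(sqrt(x), method = "bray"))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PERMANOVA matches vegan and the exhaustive permutation oracle", {
  skip_if_not_installed("vegan")
  set.seed(58)
  x <- matrix(rpois(36, 5) + 0.2, 6, 6)
  lab <- rep(c("x", "y"), each = 3)
  d <- bray_curtis(x, transform = "none")
  fit <- permanova(d, lab, n_perm = 9999, seed = 4)
  ref <- vegan::adonis2(stats::as.dist(unclass(d)) ~ lab,
                        permutations = 999)
  expect_equal(fit$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$r_squared, ref$R2[1], tolerance = 1e-10)
  # exhaustive oracle over all equal-size label subsets
  exact <- exact_permanova_p(d, lab)
  expect_lt(abs(fit$p_value - exact), 0.03)
})

test_that("PERMANOVA separates constructed clusters and rejects bad input", {
  set.seed(59)
  a <- matrix(rnorm(40, 0, 0.2), 8, 5)
  b <- matrix(rnorm(40, 5, 0.2), 8, 5)
  x <- abs(rbind(a, b))
  lab <- rep(c("lo", "hi"), each = 8)
  d <- bray_curtis(x, transform = "none")
  fit <- permanova(d, lab, n_perm = 199, seed = 6)
  expect_gt(fit$r_squared, 0.5)
  expect_equal(fit$p_value, 1 / 200)
  expect_error(permanova(d, rep("one", 16)), "2 groups")
  # determinism under a fixed seed
  fit2 <- permanova(d, lab, n_perm = 199, seed = 6)
  expect_equal(fit$p_value, fit2$p_value)
})

test_that("PERMANOVA null p-values are roughly uniform", {
  set.seed(60)
  ps <- replicate(60, {
    x <- matrix(rlnorm(8 * 4), 8, 4)
    permanova(bray_curtis(x), rep(c("u", "v"), each = 4),
              n_perm = 99, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps > 0.5), 0.25)
  expect_gt(mean(ps <= 0.5), 0.25)
})

test_that("NMDS recovers exactly embeddable configurations", {
  pts <- c(0, 1, 3, 6, 10, 15, 17, 20)
  dm <- as.matrix(stats::dist(pts))
  fit <- nmds(dm, k = 1, n_restarts = 5, seed = 7)
  expect_lt(fit$stress, 0.01)
  # stress never increases within the winning restart
  expect_true(all(diff(fit$stress_trace) <= 1e-9))
  # 2-d points recovered in 2 dimensions
  xy <- cbind(runif(9), runif(9))
  fit2 <- nmds(as.matrix(stats::dist(xy)), k = 2, n_restarts = 5, seed = 8)
  expect_lt(fit2$stress, 0.01)
})

test_that("NMDS is seeded and reports glance/tidy output", {
  set.seed(61)
  x <- matrix(rpois(48, 5) + 0.3, 8, 6)
  d <- bray_curtis(x)
  f1 <- nmds(d, k = 2, n_restarts = 4, seed = 9, maxit = 80)
  f2 <- nmds(d, k = 2, n_restarts = 4, seed = 9, maxit = 80)
  expect_equal(f1$points, f2$points)
  g <- glance(f1)
  expect_named(g, c("stress", "converged", "k", "n", "n.restarts"))
  expect_equal(nrow(tidy(f1)), 8)
  expect_error(nmds(d[1:3, 1:3], k = 2), "k \\+ 2")
})
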