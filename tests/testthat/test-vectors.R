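make_pairs <- function(dtp, dcol, tp1 = 10, col1 = 10) {
  tibble::tibble(
    site_id = as.character(seq_along(dtp)),
    tp_t1 = tp1, color_t1 = col1,
    tp_t2 = pmax(tp1 + dtp, 0), color_t2 = pmax(col1 + dcol, 0)
  )
}

test_that("change vectors have the textbook magnitudes and angles", {
  v <- change_vectors(make_pairs(c(10, 3, -1, 0), c(10, 4, 0, 0)))
  expect_equal(v$angle_deg[1], 45)
  expect_equal(v$magnitude[2], 5)
  expect_equal(v$angle_deg[2], atan2(4, 3) * 180 / pi)  # ~53.13
  expect_equal(v$angle_deg[3], 180)
  expect_equal(v$magnitude[4], 0)
  expect_true(is.na(v$angle_deg[4]))
})

test_that("swapping the two visits flips the angle by 180 degrees", {
  set.seed(31)
  p <- make_pairs(rnorm(50, 5, 10), rnorm(50, 3, 6),
                  tp1 = runif(50, 5, 80), col1 = runif(50, 5, 40))
  v <- change_vectors(p)
  p_sw <- dplyr::rename(p, tp_t1 = tp_t2, tp_t2 = tp_t1,
                        color_t1 = color_t2, color_t2 = color_t1)
  v_sw <- change_vectors(p_sw)
  expect_equal(v_sw$magnitude, v$magnitude)
  ok <- !is.na(v$angle_deg)
  expect_equal(v_sw$angle_deg[ok], (v$angle_deg[ok] + 180) %% 360)
})

test_that("circular means respect symmetry and identity", {
  expect_equal(circular_mean(c(10, 350))$mean_angle, 0)
  cm <- circular_mean(c(45, 45, 45))
  expect_equal(cm$mean_angle, 45)
  expect_equal(cm$resultant_length, 1)
  expect_error(circular_mean(numeric(0)), "at least one")
  expect_warning(circular_mean(c(0, 90, 180, 270)), "unstable")
})

test_that("rotating all angles shifts the mean and leaves Rao T unchanged", {
  set.seed(32)
  ang <- runif(40, 0, 120)
  shift <- 77
  m0 <- circular_mean(ang)$mean_angle
  m1 <- circular_mean((ang + shift) %% 360)$mean_angle
  expect_equal(m1, (m0 + shift) %% 360, tolerance = 1e-9)
  expect_equal(rao_statistic((ang + shift) %% 360), rao_statistic(ang),
               tolerance = 1e-9)
})

test_that("Rao T is 0 for equal spacing and 360 - 360/n for identical angles", {
  expect_equal(rao_statistic(seq(0, 359, by = 45)), 0)
  # brute-force evaluation of the spacing formula for n identical angles:
  # spacings are n-1 zeros plus one full circle
  for (n in c(4, 7, 12)) {
    lambda <- 360 / n
    brute <- 0.5 * (sum(abs(rep(0, n - 1) - lambda)) + abs(360 - lambda))
    expect_equal(rao_statistic(rep(123.4, n)), brute)
    expect_equal(brute, 360 - 360 / n)
  }
})

test_that("Rao Monte-Carlo p-values are seeded and sensible", {
  set.seed(33)
  conc <- rep(c(40, 42, 44), each = 30)          # highly concentrated
  r1 <- rao_spacing(conc, n_rep = 2000, seed = 9)
  r2 <- rao_spacing(conc, n_rep = 2000, seed = 9)
  expect_equal(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.01)
  unif <- seq(0.5, 359.5, length.out = 90)       # near-perfect spacing
  expect_gt(rao_spacing(unif, n_rep = 2000, seed = 9)$p_value, 0.5)
})

test_that("bootstrap arcs are reproducible, tight when concentrated", {
  set.seed(34)
  ang <- nutrientcolor:::.rvonmises_deg(400, 45, 50)
  b1 <- bootstrap_mean_angle_ci(ang, n_boot = 999, seed = 5)
  b2 <- bootstrap_mean_angle_ci(ang, n_boot = 999, seed = 5)
  expect_equal(b1$ci_low, b2$ci_low)
  expect_equal(b1$ci_high, b2$ci_high)
  expect_lt(b1$arc_width, 10)
  # the point estimate sits inside the arc by construction
  dev <- ((b1$mean_angle - b1$ci_low) %% 360)
  expect_lte(dev, (b1$ci_high - b1$ci_low) %% 360 + 1e-9)
  expect_error(bootstrap_mean_angle_ci(c(10, 20, 30)), "at least 10")
})

test_that("group ANOVA matches a hand-computed decomposition", {
  v <- tibble::tibble(
    magnitude = c(1, 2, 3, 7, 8, 9),
    angle_deg = c(10, 20, 30, 40, 50, 60),
    origin_class = factor(rep(c("blue", "murky"), each = 3),
                          levels = nc_classes())
  )
  got <- vector_group_anova(v, "magnitude")
  y <- v$magnitude
  ss_b <- 3 * (mean(y[1:3]) - mean(y))^2 + 3 * (mean(y[4:6]) - mean(y))^2
  ss_w <- sum((y[1:3] - mean(y[1:3]))^2) + sum((y[4:6] - mean(y[4:6]))^2)
  f_oracle <- (ss_b / 1) / (ss_w / 4)
  expect_equal(got$statistic, f_oracle)
  expect_equal(got$df, 1)
  expect_equal(got$df_resid, 4)
  # identical group means give F ~ 0
  v0 <- v
  v0$magnitude <- c(1, 2, 3, 1, 2, 3)
  expect_lt(vector_group_anova(v0, "magnitude")$statistic, 1e-12)
})

test_that("rose bins partition the circle and conserve the sample", {
  set.seed(35)
  ang <- runif(200, 0, 360)
  rb <- rose_bins(ang, 16)
  expect_equal(nrow(rb), 16)
  expect_equal(sum(rb$count), 200)
  expect_equal(rb$bin_end - rb$bin_start, rep(22.5, 16))
})

test_that("the combined summary is deterministic under a fixed seed", {
  set.seed(36)
  p <- make_pairs(rnorm(60, 10, 8), rnorm(60, 6, 5),
                  tp1 = runif(60, 5, 80), col1 = runif(60, 5, 40))
  v <- change_vectors(p)
  s1 <- summarize_change_vectors(v, n_boot = 199, rao_n_rep = 500, seed = 3)
  s2 <- summarize_change_vectors(v, n_boot = 199, rao_n_rep = 500, seed = 3)
  expect_equal(glance(s1), glance(s2))
  expect_s3_class(tidy(s1), "tbl_df")
})
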