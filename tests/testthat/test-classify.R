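test_that("class boundaries fall on the blue/brown side of the thresholds", {
  expect_equal(as.character(nc_classify(30, 20)), "blue")
  expect_equal(as.character(nc_classify(31, 21)), "murky")
  expect_equal(as.character(nc_classify(65, 15)), "green")
  expect_equal(as.character(nc_classify(20, 30)), "brown")
})

test_that("published class medians classify back into their own class", {
  med <- nla_class_medians()
  got <- nc_classify(med$tp_median, med$color_median)
  expect_equal(got, med$class)
})

test_that("negative inputs are a domain error", {
  expect_error(nc_classify(-1, 5), "non-negative")
  expect_error(nc_classify(5, -1), "non-negative")
})

test_that("every non-negative (tp, color) pair gets exactly one label", {
  set.seed(11)
  tp <- c(runif(5000, 0, 4000), runif(5000, 25, 35))
  color <- c(runif(5000, 0, 800), runif(5000, 15, 25))
  lab <- nc_classify(tp, color)
  expect_false(any(is.na(lab)))
  expect_setequal(levels(lab), nc_classes())
})

test_that("classification is monotone in tp and color", {
  set.seed(12)
  tp <- runif(2000, 0, 100); color <- runif(2000, 0, 60)
  base_lab <- as.character(nc_classify(tp, color))
  up_tp <- as.character(nc_classify(tp + runif(2000, 0, 50), color))
  # more tp can only move blue->green and brown->murky
  allowed_tp <- list(blue = c("blue", "green"), green = "green",
                     brown = c("brown", "murky"), murky = "murky")
  expect_true(all(mapply(function(a, b) b %in% allowed_tp[[a]],
                         base_lab, up_tp)))
  up_col <- as.character(nc_classify(tp, color + runif(2000, 0, 30)))
  allowed_col <- list(blue = c("blue", "brown"), brown = "brown",
                      green = c("green", "murky"), murky = "murky")
  expect_true(all(mapply(function(a, b) b %in% allowed_col[[a]],
                         base_lab, up_col)))
})

test_that("extreme bounds are type-7 quartiles with class directions", {
  # constructed 8-value blue class checked against a direct
  # order-statistic interpolation oracle
  tp <- c(4, 6, 9, 11, 14, 18, 22, 28)
  color <- c(2, 4, 5, 7, 9, 12, 15, 19)
  q7 <- function(x, p) {       # type-7: linear interpolation on sorted x
    x <- sort(x); h <- (length(x) - 1) * p
    lo <- floor(h) + 1
    x[lo] + (h - floor(h)) * (x[min(lo + 1, length(x))] - x[lo])
  }
  d <- tibble::tibble(tp = tp, color = color,
                      class = factor("blue", levels = nc_classes()))
  # pad other classes so each has enough members
  pad <- tibble::tibble(
    tp = c(50, 60, 70, 80,      # green (low color)
           50, 60, 70, 80,      # murky (high color)
           18, 20, 24, 26),     # brown (low tp, high color)
    color = c(10, 12, 14, 16, 30, 35, 40, 45, 28, 32, 36, 40)
  )
  pad$class <- nc_classify(pad$tp, pad$color)
  th <- extreme_thresholds(dplyr::bind_rows(d, pad))
  blue <- dplyr::filter(th, class == "blue")
  expect_equal(blue$tp_bound, q7(tp, 0.25))
  expect_equal(blue$color_bound, q7(color, 0.25))
  expect_equal(blue$tp_direction, "below_q1")
  murky <- dplyr::filter(th, class == "murky")
  expect_equal(murky$tp_direction, "above_q3")
  expect_equal(murky$color_direction, "above_q3")
  # directionality invariants relative to class medians
  expect_lte(blue$tp_bound, median(tp))
  expect_gte(murky$tp_bound,
             median(pad$tp[pad$class == "murky"]))
})

test_that("an all-equal class has Q1 = Q3 and no extreme members", {
  d <- tibble::tibble(
    tp = c(rep(10, 5), rep(50, 5), rep(10, 5), rep(50, 5)),
    color = c(rep(10, 5), rep(10, 5), rep(30, 5), rep(30, 5))
  )
  d$class <- nc_classify(d$tp, d$color)
  th <- extreme_thresholds(d)
  expect_true(all(th$tp_bound %in% c(10, 50)))
  flagged <- flag_extreme(d, th)
  expect_false(any(flagged$extreme))   # strict inequality
})

test_that("classes below the minimum size raise an insufficient-data error", {
  d <- tibble::tibble(tp = c(10, 50, 10, 50), color = c(10, 10, 30, 30))
  d$class <- nc_classify(d$tp, d$color)
  expect_error(extreme_thresholds(d), "fewer than 4")
})

test_that("transition matrices conserve counts and detect stasis", {
  s <- make_survey(40, seed = 13)
  pairs <- tibble::tibble(
    site_id = s$site_id, tp_t1 = s$tp, color_t1 = s$color,
    tp_t2 = s$tp, color_t2 = s$color
  )
  m <- transition_matrix(pairs)
  expect_equal(sum(unclass(m)), 40)
  expect_equal(sum(diag(unclass(m))), 40)   # no change -> diagonal
  # conservation: margins match year-specific class counts
  pairs$tp_t2 <- pmax(s$tp + rnorm(40, 10, 30), 0)
  pairs$color_t2 <- pmax(s$color + rnorm(40, 5, 10), 0)
  m2 <- unclass(transition_matrix(pairs))
  c1 <- table(nc_classify(pairs$tp_t1, pairs$color_t1))
  c2 <- table(nc_classify(pairs$tp_t2, pairs$color_t2))
  expect_equal(as.vector(rowSums(m2)), as.vector(c1[nc_classes()]))
  expect_equal(as.vector(colSums(m2)), as.vector(c2[nc_classes()]))
})

test_that("a purely diagonal matrix summarises to 100% unchanged", {
  m <- structure(diag(c(5L, 3L, 2L, 1L)),
                 dimnames = list(nc_classes(), nc_classes()),
                 class = c("nc_transition", "matrix"))
  ts <- transition_summary(m)
  expect_equal(ts$unchanged_pct, 100)
  expect_equal(ts$changed_pct, 0)
  expect_error(transition_summary(m * 0L), "positive")
})
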