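#' Published transition counts for the 401 resampled lakes
#'
#' The printed origin-to-destination class counts for the lakes sampled in
#' both national surveys (2007 and 2012), as a tidy tibble. Pairs not
#' printed (e.g. brown to green, murky to blue) had zero lakes.
#'
#' @return A tibble with `origin`, `destination`, `n` (16 rows, summing to
#'   401).
#' @export
nla_transition_counts <- function() {
  tibble::tribble(
    ~origin, ~destination, ~n,
    "blue", "blue", 124L,
    "blue", "brown", 26L,
    "blue", "green", 43L,
    "blue", "murky", 11L,
    "brown", "blue", 3L,
    "brown", "brown", 11L,
    "brown", "green", 0L,
    "brown", "murky", 6L,
    "green", "blue", 3L,
    "green", "brown", 6L,
    "green", "green", 69L,
    "green", "murky", 33L,
    "murky", "blue", 0L,
    "murky", "brown", 2L,
    "murky", "green", 8L,
    "murky", "murky", 56L
  )
}

#' Transition matrix from the published counts
#'
#' @return A 4x4 `nc_transition` matrix built from
#'   [nla_transition_counts()].
#' @export
nla_transition_matrix <- function() {
  counts <- nla_transition_counts()
  m <- base::matrix(0L, 4, 4, dimnames = list(nc_classes(), nc_classes()))
  for (i in seq_len(nrow(counts))) {
    m[counts$origin[i], counts$destination[i]] <- counts$n[i]
  }
  structure(m, class = c("nc_transition", "matrix"))
}

#' Published national class-proportion estimates
#'
#' The printed national design-weighted percentages (with standard errors)
#' of each nutrient-color class in the 2007 and 2012 national surveys, in
#' the shape produced by [category_estimates()] so they can feed
#' [change_analysis()] directly.
#'
#' @param year 2007 or 2012.
#' @return A tibble with `scope`, `category`, `n`, `proportion`, `se`,
#'   `ci_low`, `ci_high`.
#' @export
nla_national_estimates <- function(year = c(2007, 2012)) {
  year <- match.arg(as.character(year[1]), c("2007", "2012"))
  vals <- if (year == "2007") {
    list(n = 1028L,
         p = c(blue = 45.7, green = 20.8, brown = 10.0, murky = 23.5),
         se = c(blue = 2.7, green = 2.2, brown = 1.7, murky = 2.3))
  } else {
    list(n = 950L,
         p = c(blue = 27.7, green = 20.6, brown = 16.4, murky = 35.4),
         se = c(blue = 3.0, green = 2.4, brown = 3.2, murky = 3.6))
  }
  tibble::tibble(
    scope = "national",
    category = factor(nc_classes(), levels = nc_classes()),
    n = vals$n,
    proportion = unname(vals$p[nc_classes()]),
    se = unname(vals$se[nc_classes()]),
    ci_low = pmax(.data$proportion - 1.96 * .data$se, 0),
    ci_high = pmin(.data$proportion + 1.96 * .data$se, 100)
  )
}

#' Published per-class TP and color medians
#'
#' Median total phosphorus (ug/L) and true color (PCU) of each class in
#' the 2012 survey summary, useful as classification spot-checks: each
#' median pair maps back to its own class.
#'
#' @return A tibble with `class`, `tp_median`, `color_median`.
#' @export
nla_class_medians <- function() {
  tibble::tibble(
    class = factor(nc_classes(), levels = nc_classes()),
    tp_median = c(16.5, 65, 20, 110),
    color_median = c(11, 15, 30, 30)
  )
}
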