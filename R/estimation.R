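#' Design-weighted class proportion
#'
#' Horvitz-Thompson ratio estimator of the share of the lake population in
#' one nutrient-color class: sum of design weights of lakes in the class
#' over the sum of all weights, in percent. Invariant to uniform rescaling
#' of the weights.
#'
#' @param data A classified survey tibble with `class` and `weight` columns.
#' @param category A class label (one of [nc_classes()]).
#' @param class_col,weight_col Column names holding the label and design
#'   weight.
#' @return The estimated percentage (scalar).
#' @export
ht_proportion <- function(data, category, class_col = "class",
                          weight_col = "weight") {
  cls <- data[[class_col]]
  w <- data[[weight_col]]
  keep <- !is.na(cls) & !is.na(w)
  cls <- cls[keep]; w <- w[keep]
  if (length(w) == 0 || sum(w) <= 0) {
    abort("ht_proportion needs at least one sample with positive weight.")
  }
  if (any(w <= 0)) abort("All design weights must be positive.")
  100 * sum(w * (cls == category)) / sum(w)
}

#' Local-neighborhood variance of a weighted proportion
#'
#' Variance estimator for the design-weighted proportion that exploits the
#' spatial balance of probability survey designs. Each site's linearised
#' residual is compared with a weighted local mean over its nearest
#' neighbours (great-circle distance); squared deviations are pooled with
#' inverse-distance-rank weights. A closed-form factor corrects the
#' single-pass smoothing so the estimator is unbiased when residuals are
#' independent; under spatially structured residuals it is smaller than the
#' simple-random-sampling variance, reflecting the gain from spatial
#' balance. Without coordinates (or with too few sites) it falls back to
#' the weighted SRS variance of the ratio estimator.
#'
#' @param indicator Numeric or logical vector (1 = in the category).
#' @param weight Positive design weights.
#' @param lat,lon Site coordinates in decimal degrees, or `NULL`.
#' @param neighborhood_size Number of nearest neighbours (besides the site
#'   itself) forming each local neighbourhood.
#' @return Estimated variance of the proportion on the 0-1 scale.
#' @export
local_mean_variance <- function(indicator, weight, lat = NULL, lon = NULL,
                                neighborhood_size = 4) {
  z <- as.numeric(indicator)
  w <- as.numeric(weight)
  n <- length(z)
  stopifnot(length(w) == n)
  if (n < 2) return(0)
  if (any(w <= 0)) abort("All design weights must be positive.")
  W <- sum(w)
  phat <- sum(w * z) / W
  t_i <- w * (z - phat) / W

  srs_var <- sum(t_i^2) * n / (n - 1)
  have_coords <- !is.null(lat) && !is.null(lon) &&
    all(is.finite(lat)) && all(is.finite(lon))
  if (!have_coords || n < neighborhood_size + 2) {
    if (!have_coords && n >= neighborhood_size + 2) {
      warn("No usable coordinates; falling back to weighted SRS variance.")
    }
    return(max(srs_var, 0))
  }
  nb <- .nc_neighborhoods(lat, lon, neighborhood_size)
  .lmv_from_neighborhoods(t_i, nb)
}

# Nearest-neighbour structure shared across categories within a scope:
# index matrix (rows = sites, self first) and inverse-rank weights.
.nc_neighborhoods <- function(lat, lon, neighborhood_size = 4) {
  d <- geosphere::distm(cbind(lon, lat))
  m <- neighborhood_size + 1          # neighbourhood includes the site
  idx <- t(apply(d, 1, function(r) order(r)[seq_len(m)]))
  a <- (1 / seq_len(m)) / sum(1 / seq_len(m))   # inverse-rank weights
  list(idx = idx, a = a)
}

.lmv_from_neighborhoods <- function(t_i, nb) {
  m <- length(nb$a)
  T_nb <- base::matrix(t_i[nb$idx], ncol = m)
  tbar <- as.vector(T_nb %*% nb$a)
  v_raw <- sum(sweep((T_nb - tbar)^2, 2, nb$a, `*`))
  # closed-form correction for the single-pass smoothing bias
  max(v_raw / (1 - sum(nb$a^2)), 0)
}

#' Per-scope class proportion estimates
#'
#' One design-weighted estimate per scope and nutrient-color class, with a
#' standard error from [local_mean_variance()] and a normal-approximation
#' 95% confidence interval truncated to [0, 100]. A national row pools all
#' sites; per-ecoregion rows are added when `by = "ecoregion"`.
#'
#' @param data A classified survey tibble with `class`, `weight` and
#'   optionally `lat`, `lon`, `ecoregion` columns.
#' @param by `NULL` for the national scope only, or the name of a grouping
#'   column (e.g. `"ecoregion"`) for per-region scopes in addition to the
#'   national one.
#' @param neighborhood_size Passed to [local_mean_variance()].
#' @param z Normal quantile for the confidence interval (1.96 for 95%).
#' @return A tibble with columns `scope`, `category`, `n`, `proportion`,
#'   `se`, `ci_low`, `ci_high` (all percentages).
#' @export
category_estimates <- function(data, by = NULL, neighborhood_size = 4,
                               z = 1.96) {
  stopifnot(all(c("class", "weight") %in% names(data)))
  data <- dplyr::filter(tibble::as_tibble(data), !is.na(.data$class))
  one_scope <- function(d, scope) {
    lat <- if ("lat" %in% names(d)) d$lat else NULL
    lon <- if ("lon" %in% names(d)) d$lon else NULL
    n <- nrow(d)
    have_coords <- !is.null(lat) && !is.null(lon) &&
      all(is.finite(lat)) && all(is.finite(lon)) &&
      n >= neighborhood_size + 2
    nb <- if (have_coords) .nc_neighborhoods(lat, lon, neighborhood_size)
    purrr::map_dfr(nc_classes(), function(cat) {
      p <- ht_proportion(d, cat)
      v <- if (have_coords) {
        W <- sum(d$weight)
        .lmv_from_neighborhoods(
          d$weight * ((d$class == cat) - p / 100) / W, nb)
      } else {
        local_mean_variance(d$class == cat, d$weight, lat, lon,
                            neighborhood_size)
      }
      se <- 100 * sqrt(v)
      tibble::tibble(
        scope = scope, category = cat, n = nrow(d),
        proportion = p, se = se,
        ci_low = max(p - z * se, 0), ci_high = min(p + z * se, 100)
      )
    })
  }
  out <- one_scope(data, "national")
  if (!is.null(by)) {
    stopifnot(by %in% names(data))
    groups <- split(data, data[[by]], drop = TRUE)
    empty <- setdiff(unique(as.character(data[[by]])), names(groups))
    if (length(empty) > 0) warn(paste0("Scopes without samples omitted: ",
                                       paste(empty, collapse = ", ")))
    out <- dplyr::bind_rows(
      out,
      purrr::imap_dfr(groups, function(d, g) one_scope(d, g))
    )
  }
  dplyr::mutate(out,
                category = factor(.data$category, levels = nc_classes()))
}

#' Change in class proportions between two surveys
#'
#' Differences the two surveys' estimates scope-by-scope and class-by-class
#' under an independent-surveys assumption: delta = p2 - p1, SE of the
#' delta = sqrt(se1^2 + se2^2), 95% CI = delta +/- z * SE. A change is
#' flagged significant when its confidence interval excludes zero.
#'
#' @param estimates_t1,estimates_t2 Tibbles from [category_estimates()] for
#'   the earlier and later survey.
#' @param z Normal quantile for the confidence interval.
#' @return A tibble with `scope`, `category`, `proportion_t1`,
#'   `proportion_t2`, `delta` (percentage points), `se_delta`, `ci_low`,
#'   `ci_high`, `significant`.
#' @export
change_analysis <- function(estimates_t1, estimates_t2, z = 1.96) {
  key <- function(d) paste(d$scope, d$category)
  k1 <- key(estimates_t1); k2 <- key(estimates_t2)
  if (!setequal(k1, k2)) {
    missing <- c(setdiff(k1, k2), setdiff(k2, k1))
    abort(paste0("Scope x category keys do not match: ",
                 paste(missing, collapse = "; ")))
  }
  j <- dplyr::inner_join(
    dplyr::select(estimates_t1, "scope", "category",
                  proportion_t1 = "proportion", se_t1 = "se"),
    dplyr::select(estimates_t2, "scope", "category",
                  proportion_t2 = "proportion", se_t2 = "se"),
    by = c("scope", "category")
  )
  dplyr::mutate(
    j,
    delta = .data$proportion_t2 - .data$proportion_t1,
    se_delta = sqrt(.data$se_t1^2 + .data$se_t2^2),
    ci_low = .data$delta - z * .data$se_delta,
    ci_high = .data$delta + z * .data$se_delta,
    significant = .data$ci_low > 0 | .data$ci_high < 0,
    se_t1 = NULL, se_t2 = NULL
  )
}
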