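#' Per-lake change vectors in (TP, color) space
#'
#' Treats each resampled lake's movement between surveys as a vector: the
#' x-axis is the change in total phosphorus (ug/L), the y-axis the change
#' in true color (PCU). The magnitude is the Euclidean norm in those mixed
#' native units (no standardisation, matching how the axes are reported);
#' the direction is measured counterclockwise from the +TP axis, so 45
#' degrees means equal increases in TP and color, and angles below 45 mean
#' proportionally greater TP increases. Zero-length vectors get an `NA`
#' angle and are excluded from circular statistics (they keep magnitude 0).
#'
#' @param pairs A paired-lake tibble (see [pair_resampled()]) with columns
#'   `tp_t1`, `color_t1`, `tp_t2`, `color_t2`.
#' @param thresholds Classification thresholds, see [nc_thresholds()].
#' @param standardize If `TRUE`, z-scale the TP and color deltas before
#'   computing magnitude and angle (off by default).
#' @return A tibble with `site_id`, `delta_tp`, `delta_color`, `magnitude`,
#'   `angle_deg` in [0, 360), `origin_class`, `dest_class`.
#' @export
change_vectors <- function(pairs, thresholds = nc_thresholds(),
                           standardize = FALSE) {
  stopifnot(all(c("tp_t1", "color_t1", "tp_t2", "color_t2") %in%
                  names(pairs)))
  out <- tibble::tibble(
    site_id = if ("site_id" %in% names(pairs)) pairs$site_id
              else as.character(seq_len(nrow(pairs))),
    delta_tp = pairs$tp_t2 - pairs$tp_t1,
    delta_color = pairs$color_t2 - pairs$color_t1,
    origin_class = nc_classify(pairs$tp_t1, pairs$color_t1, thresholds),
    dest_class = nc_classify(pairs$tp_t2, pairs$color_t2, thresholds)
  )
  dx <- out$delta_tp
  dy <- out$delta_color
  if (standardize) {
    dx <- dx / sd(dx)
    dy <- dy / sd(dy)
  }
  mag <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  ang[mag == 0] <- NA_real_
  dplyr::mutate(out, magnitude = mag, angle_deg = ang,
                .after = "delta_color")
}

#' Circular mean direction
#'
#' Direction of the vector sum of unit vectors at the given angles, with
#' the mean resultant length (1 = all angles identical, near 0 = no
#' preferred direction, in which case the mean is unstable).
#'
#' @param angles Angles in degrees.
#' @return A list with `mean_angle` (degrees in [0, 360)),
#'   `resultant_length`, `n`, and `stable` (`FALSE` when the resultant
#'   length is below 1e-8).
#' @export
circular_mean <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) abort("circular_mean needs at least one angle.")
  rad <- angles * pi / 180
  C <- mean(cos(rad)); S <- mean(sin(rad))
  r <- sqrt(C^2 + S^2)
  mu <- (atan2(S, C) * 180 / pi) %% 360
  if (mu >= 360 - 1e-9) mu <- 0    # guard the floating-point wrap
  if (r < 1e-8) {
    warn("Resultant length is ~0; the circular mean is unstable.")
  }
  list(mean_angle = mu, resultant_length = r, n = length(angles),
       stable = r >= 1e-8)
}

#' Bootstrap confidence arc for the mean direction
#'
#' Percentile bootstrap on the circle: resamples the angles with
#' replacement, computes each resample's circular mean, centres the
#' bootstrap means on the point estimate (deviations wrapped to
#' (-180, 180]), and takes the percentile arc of the deviations. The
#' reported arc therefore always contains the point estimate.
#'
#' @param angles Angles in degrees (at least 10 non-missing).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed making the arc reproducible.
#' @param conf Confidence level.
#' @return A list with `mean_angle`, `ci_low`, `ci_high` (degrees in
#'   [0, 360); the arc runs counterclockwise from `ci_low` to `ci_high`),
#'   `arc_width`, `resultant_length`, `n`, `n_boot`, `seed`.
#' @export
bootstrap_mean_angle_ci <- function(angles, n_boot = 999, seed = 1,
                                    conf = 0.95) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 10) abort("Need at least 10 angles to bootstrap the mean.")
  est <- circular_mean(angles)
  if (!est$stable) {
    abort("Resultant length is ~0; the bootstrap arc is undefined.")
  }
  rad <- angles * pi / 180
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  cosm <- matrix(cos(rad)[idx], nrow = n_boot)
  sinm <- matrix(sin(rad)[idx], nrow = n_boot)
  boot_mu <- (atan2(rowMeans(sinm), rowMeans(cosm)) * 180 / pi) %% 360
  dev <- ((boot_mu - est$mean_angle + 180) %% 360) - 180
  qs <- quantile(dev, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(
    mean_angle = est$mean_angle,
    ci_low = (est$mean_angle + qs[1]) %% 360,
    ci_high = (est$mean_angle + qs[2]) %% 360,
    arc_width = qs[2] - qs[1],
    resultant_length = est$resultant_length,
    n = n, n_boot = n_boot, seed = seed
  )
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Rao spacing statistic
#'
#' Computes T = 1/2 * sum |T_i - lambda| where T_i are the spacings between
#' successive sorted angles (including the wrap-around spacing) and
#' lambda = 360/n. T is 0 for perfectly equally spaced angles and reaches
#' its maximum 360 - 360/n when all angles coincide.
#'
#' @param angles Angles in degrees.
#' @return The statistic in degrees.
#' @export
rao_statistic <- function(angles) {
  angles <- sort(angles[!is.na(angles)] %% 360)
  n <- length(angles)
  if (n < 2) abort("Need at least 2 angles.")
  sp <- c(diff(angles), 360 - angles[n] + angles[1])
  lambda <- 360 / n
  0.5 * sum(abs(sp - lambda))
}

#' Null distribution of the Rao spacing statistic
#'
#' Monte-Carlo sample of the statistic under circular uniformity, used for
#' p-values. Precompute once when testing many samples of the same size.
#'
#' @param n Sample size.
#' @param n_rep Number of uniform replicates.
#' @param seed Integer seed.
#' @return Numeric vector of `n_rep` statistics.
#' @export
rao_null <- function(n, n_rep = 10000, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- matrix(runif(n_rep * n, 0, 360), nrow = n_rep)
  s <- t(apply(u, 1, sort))
  sp <- cbind(s[, -1, drop = FALSE] - s[, -n, drop = FALSE],
              360 - s[, n] + s[, 1])
  lambda <- 360 / n
  0.5 * rowSums(abs(sp - lambda))
}

#' Rao spacing test of circular uniformity
#'
#' Tests whether a set of direction angles departs from uniformity on the
#' circle, using the spacing statistic of [rao_statistic()] and a seeded
#' Monte-Carlo p-value: p = (1 + #{null T >= observed T}) / (n_rep + 1).
#'
#' @param angles Angles in degrees (n >= 4).
#' @param n_rep Monte-Carlo replicates for the null distribution.
#' @param seed Integer seed.
#' @param null_T Optional precomputed null sample from [rao_null()]
#'   (must match `length(angles)`).
#' @return An object of class `nc_rao`: list with `statistic`, `n`,
#'   `lambda`, `p_value`, `n_rep`, `seed`.
#' @export
rao_spacing <- function(angles, n_rep = 10000, seed = 1, null_T = NULL) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 4) abort("Rao spacing test needs at least 4 angles.")
  T_obs <- rao_statistic(angles)
  if (is.null(null_T)) null_T <- rao_null(n, n_rep, seed)
  p <- (1 + sum(null_T >= T_obs)) / (length(null_T) + 1)
  structure(
    list(statistic = T_obs, n = n, lambda = 360 / n, p_value = p,
         n_rep = length(null_T), seed = seed),
    class = "nc_rao"
  )
}

#' @export
print.nc_rao <- function(x, ...) {
  cat("Rao spacing test of circular uniformity\n")
  cat(sprintf("  T = %.2f degrees (n = %d, lambda = %.2f)\n",
              x$statistic, x$n, x$lambda))
  cat(sprintf("  Monte-Carlo p = %.4g (%d replicates)\n",
              x$p_value, x$n_rep))
  invisible(x)
}

#' One-way ANOVA of change-vector angle or magnitude by origin class
#'
#' Compares the raw response values across origin classes with a standard
#' one-way ANOVA. Angles are treated linearly (their circularity is
#' ignored), so interpret angle comparisons with care when directions
#' straddle 0/360. Groups with fewer than 2 usable values are excluded
#' with a warning; zero-magnitude lakes contribute magnitude 0 but no
#' angle.
#'
#' @param vectors A tibble from [change_vectors()].
#' @param response `"magnitude"` or `"angle"`.
#' @return A one-row tibble: `response`, `statistic` (F), `df`, `df_resid`,
#'   `p_value`, `n`, `n_groups`.
#' @export
vector_group_anova <- function(vectors, response = c("magnitude", "angle")) {
  response <- match.arg(response)
  y <- if (response == "magnitude") vectors$magnitude else vectors$angle_deg
  g <- vectors$origin_class
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(factor(g[keep]))
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("Excluding group(s) with < 2 values: ",
                paste(small, collapse = ", ")))
    keep2 <- !g %in% small
    y <- y[keep2]; g <- droplevels(g[keep2])
  }
  if (nlevels(g) < 2) abort("Need at least 2 groups with >= 2 values.")
  fit <- aov(y ~ g)
  tab <- anova(fit)
  tibble::tibble(
    response = response,
    statistic = tab[["F value"]][1],
    df = tab[["Df"]][1],
    df_resid = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1],
    n = length(y),
    n_groups = nlevels(g)
  )
}

#' Rose-diagram bin counts
#'
#' Counts direction angles into equal circular bins for plotting a rose
#' diagram; bins start at 0 degrees.
#'
#' @param angles Angles in degrees.
#' @param n_bins Number of bins around the circle.
#' @return A tibble with `bin_start`, `bin_mid`, `bin_end`, `count`.
#' @export
rose_bins <- function(angles, n_bins = 16) {
  angles <- angles[!is.na(angles)] %% 360
  width <- 360 / n_bins
  idx <- pmin(floor(angles / width), n_bins - 1)
  counts <- tabulate(idx + 1, nbins = n_bins)
  tibble::tibble(
    bin_start = width * (seq_len(n_bins) - 1),
    bin_mid = width * (seq_len(n_bins) - 0.5),
    bin_end = width * seq_len(n_bins),
    count = counts
  )
}

#' Summarise change vectors with circular statistics
#'
#' Convenience wrapper producing the full per-survey change-vector summary:
#' circular mean with bootstrap confidence arc, Rao spacing test, per-class
#' one-way ANOVAs of magnitude and angle, and rose-diagram bins.
#'
#' @param vectors A tibble from [change_vectors()].
#' @param n_boot Bootstrap resamples for the mean-direction arc.
#' @param rao_n_rep Monte-Carlo replicates for the Rao test.
#' @param seed Integer seed shared by the bootstrap and the Rao test.
#' @param n_bins Rose-diagram bins.
#' @return A list of class `nc_vector_summary` with elements `mean_direction`
#'   (from [bootstrap_mean_angle_ci()]), `rao` (an `nc_rao`), `anova` (a
#'   two-row tibble), `rose` (bin counts), `n_vectors`, `n_zero`.
#' @export
summarize_change_vectors <- function(vectors, n_boot = 999,
                                     rao_n_rep = 10000, seed = 1,
                                     n_bins = 16) {
  ang <- vectors$angle_deg[!is.na(vectors$angle_deg)]
  try_or_null <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      warn(paste0("Skipping ", what, ": ", conditionMessage(e)))
      NULL
    })
  }
  structure(
    list(
      mean_direction = try_or_null(
        bootstrap_mean_angle_ci(ang, n_boot, seed), "mean-direction arc"),
      rao = try_or_null(rao_spacing(ang, rao_n_rep, seed),
                        "Rao spacing test"),
      anova = dplyr::bind_rows(
        try_or_null(vector_group_anova(vectors, "magnitude"),
                    "magnitude ANOVA"),
        try_or_null(vector_group_anova(vectors, "angle"), "angle ANOVA")
      ),
      rose = rose_bins(ang, n_bins),
      n_vectors = nrow(vectors),
      n_zero = sum(vectors$magnitude == 0, na.rm = TRUE)
    ),
    class = "nc_vector_summary"
  )
}

#' @export
print.nc_vector_summary <- function(x, ...) {
  cat(sprintf(
    "Change-vector summary: %d lakes (%d with zero change)\n",
    x$n_vectors, x$n_zero))
  md <- x$mean_direction
  if (!is.null(md)) {
    cat(sprintf(
      "  Mean direction %.2f deg, 95%% arc [%.2f, %.2f] (%d bootstraps)\n",
      md$mean_angle, md$ci_low, md$ci_high, md$n_boot))
  }
  if (!is.null(x$rao)) {
    cat(sprintf("  Rao T = %.2f, p = %.4g\n",
                x$rao$statistic, x$rao$p_value))
  }
  invisible(x)
}
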