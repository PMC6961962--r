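# Shared fixture builders: everything is generated in code at test time.

make_survey <- function(n = 6, year = 2007, seed = NULL,
                        tp = NULL, color = NULL, weight = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    site_id = sprintf("L%03d", seq_len(n)),
    year = year,
    ecoregion = rep(c("East", "West"), length.out = n),
    weight = weight %||% rep(10, n),
    lat = runif(n, 30, 48),
    lon = runif(n, -120, -70),
    tp = tp %||% runif(n, 1, 100),
    color = color %||% runif(n, 1, 50),
    tp_below_detection = FALSE,
    area_ha = runif(n, 5, 500)
  )
}

write_survey_csv <- function(df, path = withr::local_tempfile(
                               fileext = ".csv",
                               .local_envir = parent.frame())) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

make_taxa <- function() {
  # two sites, two zooplankton orders (one mesh-duplicated genus),
  # one phytoplankton order
  tibble::tribble(
    ~site_id, ~group, ~order_name, ~genus_name, ~taxon_id, ~mesh,
    ~density, ~biovolume, ~biomass,
    "A", "zooplankton", "Ploima", "Keratella", "z_ker", "fine",
    10, NA, 4,
    "A", "zooplankton", "Ploima", "Keratella", "z_ker", "coarse",
    20, NA, 6,
    "A", "zooplankton", "Diplostraca", "Daphnia", "z_dap", "coarse",
    5, NA, 40,
    "B", "zooplankton", "Diplostraca", "Daphnia", "z_dap", "coarse",
    2, NA, 16,
    "A", "phytoplankton", "Chroococcales", "Microcystis", "p_mic", "none",
    1000, 1e6, NA,
    "B", "phytoplankton", "Fragilariales", "Fragilaria", "p_fra", "none",
    500, 5e6, NA
  )
}

# Exhaustive-enumeration Kruskal-Wallis permutation p-value for two groups
# (sizes fixed), independent of the package's Monte-Carlo path.
exact_kw_p <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  idx_all <- seq_along(values)
  n1 <- sum(groups == lev[1])
  H_obs <- nutrientcolor:::.kw_statistic(values, groups)
  subsets <- utils::combn(idx_all, n1)
  Hs <- apply(subsets, 2, function(s) {
    g <- factor(ifelse(idx_all %in% s, lev[1], lev[2]), levels = lev)
    nutrientcolor:::.kw_statistic(values, g)
  })
  mean(Hs >= H_obs - 1e-12)
}

# Exhaustive PERMANOVA p for two equal-size groups.
exact_permanova_p <- function(d, labels) {
  d <- unclass(d)
  labels <- factor(labels)
  lev <- levels(labels)
  n <- nrow(d)
  n1 <- sum(labels == lev[1])
  f_of <- function(lab) {
    fit <- permanova(d, lab, n_perm = 0, seed = 1)
    fit$pseudo_F
  }
  F_obs <- f_of(labels)
  subsets <- utils::combn(seq_len(n), n1)
  Fs <- apply(subsets, 2, function(s) {
    f_of(factor(ifelse(seq_len(n) %in% s, lev[1], lev[2]), levels = lev))
  })
  mean(Fs >= F_obs - 1e-12)
}
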