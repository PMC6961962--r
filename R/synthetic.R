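#' Calibrate a truncated lognormal to target quartiles
#'
#' Finds lognormal parameters such that, after truncation to (lo, hi], the
#' distribution's quartiles match the targets as closely as possible
#' (least squares on the log scale). Used to parameterise per-class TP and
#' color distributions from published quartile summaries.
#'
#' @param quartiles Numeric vector `c(q1, median, q3)` of target quartiles.
#' @param lo,hi Truncation bounds (use 0 and `Inf` for none).
#' @return A list with `meanlog`, `sdlog`, `lo`, `hi`.
#' @export
calibrate_truncated_lognormal <- function(quartiles, lo = 0, hi = Inf) {
  stopifnot(length(quartiles) == 3, all(diff(quartiles) >= 0),
            quartiles[1] > lo, quartiles[3] < hi | is.infinite(hi))
  qtrunc <- function(p, meanlog, sdlog) {
    plo <- stats::plnorm(lo, meanlog, sdlog)
    phi <- stats::plnorm(hi, meanlog, sdlog)
    stats::qlnorm(plo + p * (phi - plo), meanlog, sdlog)
  }
  obj <- function(par) {
    q <- qtrunc(c(0.25, 0.5, 0.75), par[1], exp(par[2]))
    sum((log(q) - log(quartiles))^2)
  }
  init <- c(log(quartiles[2]),
            log(max(log(quartiles[3] / quartiles[1]) / 1.349, 0.05)))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]), lo = lo, hi = hi)
}

.rtrunc_lnorm <- function(n, model) {
  plo <- stats::plnorm(model$lo, model$meanlog, model$sdlog)
  phi <- stats::plnorm(model$hi, model$meanlog, model$sdlog)
  stats::qlnorm(plo + runif(n) * (phi - plo), model$meanlog, model$sdlog)
}

.rdirichlet <- function(n, alpha) {
  x <- base::matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
                    byrow = TRUE)
  x / rowSums(x)
}

# Best-Fisher rejection sampler for von Mises directions (degrees).
.rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa <= 1e-8) return(runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1
    }
  }
  out * 180 / pi
}

.default_ecoregions <- c(
  "Coastal Plains", "Northern Appalachians", "Southern Appalachians",
  "Northern Plains", "Southern Plains", "Temperate Plains",
  "Upper Midwest", "Western Mountains", "Xeric"
)

.default_tp_color_targets <- function() {
  list(
    tp = list(
      blue = list(q = c(10, 16.5, 24), lo = 0, hi = 30),
      green = list(q = c(45, 65, 124), lo = 30, hi = Inf),
      brown = list(q = c(15, 20, 25), lo = 0, hi = 30),
      murky = list(q = c(59, 110, 297.5), lo = 30, hi = Inf)
    ),
    color = list(
      blue = list(q = c(7.5, 11, 15), lo = 0, hi = 20),
      green = list(q = c(11, 15, 18), lo = 0, hi = 20),
      brown = list(q = c(25, 30, 44), lo = 20, hi = Inf),
      murky = list(q = c(25, 30, 38), lo = 20, hi = Inf)
    )
  )
}

.default_community_model <- function() {
  orders <- c("Ploima", "Flosculariaceae", "Calanoida", "Cyclopoida",
              "Diplostraca")
  zoo_shares <- rbind(
    blue = c(0.10, 0.02, 0.15, 0.13, 0.60),
    green = c(0.13, 0.03, 0.13, 0.12, 0.59),
    brown = c(0.10, 0.03, 0.14, 0.13, 0.60),
    murky = c(0.20, 0.05, 0.13, 0.12, 0.50)
  )
  colnames(zoo_shares) <- orders
  phyto_orders <- c("Chroococcales", "Nostocales", "Fragilariales",
                    "Chlorellales", "Peridiniales")
  phyto_shares <- rbind(
    blue = c(0.15, 0.05, 0.35, 0.25, 0.20),
    green = c(0.35, 0.15, 0.20, 0.20, 0.10),
    brown = c(0.20, 0.05, 0.30, 0.25, 0.20),
    murky = c(0.40, 0.15, 0.15, 0.20, 0.10)
  )
  colnames(phyto_shares) <- phyto_orders
  genus_map <- tibble::tribble(
    ~genus, ~order, ~group,
    "Brachionus", "Ploima", "zooplankton",
    "Keratella", "Ploima", "zooplankton",
    "Asplanchna", "Ploima", "zooplankton",
    "Filinia", "Flosculariaceae", "zooplankton",
    "Hexarthra", "Flosculariaceae", "zooplankton",
    "Leptodiaptomus", "Calanoida", "zooplankton",
    "Skistodiaptomus", "Calanoida", "zooplankton",
    "Mesocyclops", "Cyclopoida", "zooplankton",
    "Acanthocyclops", "Cyclopoida", "zooplankton",
    "Daphnia", "Diplostraca", "zooplankton",
    "Bosmina", "Diplostraca", "zooplankton",
    "Microcystis", "Chroococcales", "phytoplankton",
    "Aphanocapsa", "Chroococcales", "phytoplankton",
    "Dolichospermum", "Nostocales", "phytoplankton",
    "Fragilaria", "Fragilariales", "phytoplankton",
    "Synedra", "Fragilariales", "phytoplankton",
    "Chlorella", "Chlorellales", "phytoplankton",
    "Peridinium", "Peridiniales", "phytoplankton"
  )
  list(
    # Table-style class medians of total biomass (ug dry weight/L)
    zoo_total_median = c(blue = 49.18, green = 88.37, brown = 54.66,
                         murky = 150.04),
    phyto_total_median = c(blue = 156.9, green = 579.83, brown = 211.61,
                           murky = 865.29),
    total_sdlog = 1.2,
    zoo_shares = zoo_shares,
    phyto_shares = phyto_shares,
    genus_map = genus_map,
    overdispersion = 0.02,   # Dirichlet spread; 0 = compositions at means
    mesh_dup_fraction = 0.3  # share of zoo taxa recorded in both meshes
  )
}

#' Configuration for the synthetic survey generator
#'
#' Bundles every parameter of the synthetic national lake survey: the
#' stratified design (nine ecoregion strata with population and sample
#' sizes, hence design weights), per-stratum class mixtures, per-class
#' truncated-lognormal TP and color distributions calibrated to published
#' quartile summaries, the paired-year drift model (von Mises direction,
#' lognormal magnitude), the plankton community model, and the TP
#' detection limit.
#'
#' @param seed Integer master seed.
#' @param n_sample_per_stratum Lakes sampled per ecoregion stratum.
#' @param n_population_per_stratum Population lakes represented per
#'   stratum (design weight = population / sample).
#' @param class_mixture Named numeric vector of class probabilities
#'   (summing to 1), or a 9-row matrix for per-stratum mixtures.
#' @param drift_theta0 Mean drift direction, degrees counterclockwise from
#'   the +TP axis.
#' @param drift_kappa Von Mises concentration of drift directions.
#' @param drift_magnitude_meanlog,drift_magnitude_sdlog Lognormal
#'   parameters of drift magnitude (mixed TP/color units).
#' @param revisit_fraction Share of lakes resampled in the second survey.
#' @param detection_limit TP detection limit, ug/L; generated samples
#'   below it are flagged.
#' @return A list of class `nc_synth_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_sample_per_stratum = 110,
                             n_population_per_stratum = 5500,
                             class_mixture = c(blue = 0.457, green = 0.208,
                                               brown = 0.100,
                                               murky = 0.235),
                             drift_theta0 = 32.68,
                             drift_kappa = 2,
                             drift_magnitude_meanlog = log(25),
                             drift_magnitude_sdlog = 1,
                             revisit_fraction = 0.39,
                             detection_limit = 3.9) {
  strata <- tibble::tibble(
    ecoregion = .default_ecoregions,
    n_population = n_population_per_stratum,
    n_sample = n_sample_per_stratum,
    # coarse lon/lat boxes tiling a continental extent, 3 x 3
    lon_min = rep(c(-120, -100, -85), 3),
    lon_max = rep(c(-100, -85, -70), 3),
    lat_min = rep(c(28, 36, 43), each = 3),
    lat_max = rep(c(36, 43, 49), each = 3)
  )
  if (is.null(dim(class_mixture))) {
    stopifnot(abs(sum(class_mixture) - 1) < 1e-8)
    class_mixture <- base::matrix(class_mixture, nrow = nrow(strata),
                                  ncol = 4, byrow = TRUE,
                                  dimnames = list(strata$ecoregion,
                                                  nc_classes()))
  }
  targets <- .default_tp_color_targets()
  tp_color_model <- purrr::map(c(tp = "tp", color = "color"), function(v) {
    purrr::map(targets[[v]], function(t)
      calibrate_truncated_lognormal(t$q, t$lo, t$hi))
  })
  structure(
    list(
      seed = seed,
      strata = strata,
      class_mixture = class_mixture,
      tp_color_model = tp_color_model,
      drift_model = list(theta0 = drift_theta0, kappa = drift_kappa,
                         magnitude_meanlog = drift_magnitude_meanlog,
                         magnitude_sdlog = drift_magnitude_sdlog),
      revisit_fraction = revisit_fraction,
      community_model = .default_community_model(),
      detection_limit = detection_limit
    ),
    class = "nc_synth_config"
  )
}

#' Generate a stratified synthetic lake survey
#'
#' Draws one survey under the configured stratified design: per stratum,
#' `n_sample` lakes with design weight `n_population / n_sample`, a true
#' class from the stratum's mixture, TP and color from that class's
#' truncated lognormals (so classification recovers the intended class),
#' uniform coordinates within the stratum's box, and a lognormal lake
#' area. Samples with TP below the detection limit are flagged.
#'
#' @param config A [synthetic_config()].
#' @param year Survey year recorded on each row.
#' @param seed Optional seed overriding `config$seed`.
#' @return A survey tibble (`site_id`, `year`, `ecoregion`, `weight`,
#'   `lat`, `lon`, `tp`, `color`, `tp_below_detection`, `area_ha`,
#'   `true_class`). Attribute `truth` holds the design-weighted true class
#'   proportions (percent).
#' @export
generate_population <- function(config, year = 2007, seed = NULL) {
  stopifnot(inherits(config, "nc_synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %||% config$seed)
  rows <- purrr::map_dfr(seq_len(nrow(config$strata)), function(h) {
    st <- config$strata[h, ]
    n <- st$n_sample
    mix <- config$class_mixture[h, ]
    cls <- sample(nc_classes(), n, replace = TRUE, prob = mix)
    tp <- numeric(n); col <- numeric(n)
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      tp[idx] <- .rtrunc_lnorm(length(idx), config$tp_color_model$tp[[cl]])
      col[idx] <- .rtrunc_lnorm(length(idx),
                                config$tp_color_model$color[[cl]])
    }
    tibble::tibble(
      site_id = sprintf("S%02d-%04d", h, seq_len(n)),
      year = year,
      ecoregion = st$ecoregion,
      weight = st$n_population / st$n_sample,
      lat = runif(n, st$lat_min, st$lat_max),
      lon = runif(n, st$lon_min, st$lon_max),
      tp = tp,
      color = col,
      tp_below_detection = tp < config$detection_limit,
      area_ha = rlnorm(n, log(40), 1.2),
      true_class = factor(cls, levels = nc_classes())
    )
  })
  wpop <- config$strata$n_population
  truth <- 100 * colSums(config$class_mixture * wpop) / sum(wpop)
  attr(rows, "truth") <- truth
  rows
}

#' Apply paired-year drift to a synthetic survey
#'
#' Produces the second survey by moving each lake additively in (TP,
#' color) space: direction from a von Mises distribution around the
#' configured mean drift angle, magnitude lognormal, results floored at 0
#' so concentrations stay non-negative. A `revisit_fraction` subset is
#' marked as resampled in both surveys. Class labels are always re-derived
#' from the year-specific values, never carried over.
#'
#' @param population A survey tibble from [generate_population()].
#' @param config A [synthetic_config()].
#' @param year Second survey year.
#' @param seed Optional seed overriding `config$seed + 1`.
#' @return A list with `t1` and `t2` survey tibbles (both carrying a
#'   logical `resampled` column) and `drift` (tibble of the true per-lake
#'   drift angles and magnitudes).
#' @export
apply_drift <- function(population, config, year = 2012, seed = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %||% (config$seed + 1))
  n <- nrow(population)
  dm <- config$drift_model
  theta <- .rvonmises_deg(n, dm$theta0, dm$kappa)
  mag <- rlnorm(n, dm$magnitude_meanlog, dm$magnitude_sdlog)
  t2 <- population
  t2$year <- year
  t2$tp <- pmax(population$tp + mag * cos(theta * pi / 180), 0)
  t2$color <- pmax(population$color + mag * sin(theta * pi / 180), 0)
  t2$tp_below_detection <- t2$tp < config$detection_limit
  t2$true_class <- nc_classify(t2$tp, t2$color)
  resampled <- seq_len(n) %in%
    sample.int(n, round(config$revisit_fraction * n))
  t1 <- dplyr::mutate(population, resampled = resampled)
  t2 <- dplyr::mutate(t2, resampled = resampled)
  list(
    t1 = t1, t2 = t2,
    drift = tibble::tibble(site_id = population$site_id,
                           angle_deg = theta, magnitude = mag)
  )
}

#' Generate synthetic plankton communities
#'
#' For each lake, draws total zooplankton and phytoplankton biomass from
#' class-specific lognormals (medians ordered murky > green > brown ~
#' blue), splits biomass over orders with a Dirichlet draw around the
#' class-mean composition (murky lakes carry roughly twice the rotifer
#' share of blue lakes), splits orders over genera, and duplicates a
#' subset of zooplankton taxa across the fine and coarse mesh records so
#' the mesh-merging step has real work to do. Phytoplankton rows carry
#' biovolume (um^3/mL) consistent with their biomass; densities are
#' derived from per-taxon unit masses.
#'
#' @param population A survey tibble with `tp` and `color` columns (class
#'   is re-derived).
#' @param config A [synthetic_config()].
#' @param seed Optional seed overriding `config$seed + 2`.
#' @return A taxon-count tibble (`site_id`, `group`, `order_name`,
#'   `genus_name`, `taxon_id`, `mesh`, `density`, `biovolume`, `biomass`).
#' @export
generate_communities <- function(population, config, seed = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %||% (config$seed + 2))
  cm <- config$community_model
  cls <- as.character(nc_classify(population$tp, population$color))
  n <- nrow(population)
  phi <- cm$overdispersion
  draw_shares <- function(means) {
    if (phi <= 0) return(means)
    as.vector(.rdirichlet(1, means / phi))
  }
  gmap <- cm$genus_map
  mesh_dup <- unique(gmap$genus[gmap$group == "zooplankton"])
  mesh_dup <- mesh_dup[seq_len(max(1, round(length(mesh_dup) *
                                              cm$mesh_dup_fraction)))]
  one_site <- function(i) {
    cl <- cls[i]
    out <- list()
    for (grp in c("zooplankton", "phytoplankton")) {
      shares_mat <- if (grp == "zooplankton") cm$zoo_shares
                    else cm$phyto_shares
      med <- if (grp == "zooplankton") cm$zoo_total_median[[cl]]
             else cm$phyto_total_median[[cl]]
      total <- rlnorm(1, log(med), cm$total_sdlog)
      shares <- draw_shares(shares_mat[cl, ])
      names(shares) <- colnames(shares_mat)
      rows <- purrr::map_dfr(names(shares), function(ord) {
        genera <- gmap$genus[gmap$order == ord]
        gs <- draw_shares(rep(1 / length(genera), length(genera)))
        biomass <- total * shares[[ord]] * gs
        tibble::tibble(
          site_id = population$site_id[i],
          group = grp,
          order_name = ord,
          genus_name = genera,
          taxon_id = paste0(substr(grp, 1, 1), "_", genera),
          biomass = biomass
        )
      })
      out[[grp]] <- rows
    }
    dplyr::bind_rows(out)
  }
  tab <- purrr::map_dfr(seq_len(n), one_site)
  tab <- dplyr::filter(tab, .data$biomass > 0)
  # densities from nominal per-individual (or per-cell) dry masses
  unit_mass <- setNames(rep(c(0.5, 2), length.out = nrow(gmap)),
                        gmap$genus)
  tab$density <- tab$biomass / unit_mass[tab$genus_name]
  tab$biovolume <- ifelse(tab$group == "phytoplankton",
                          tab$biomass / (1e-6 * 1000 * 0.2), NA_real_)
  is_zoo <- tab$group == "zooplankton"
  tab$mesh <- ifelse(is_zoo, "fine", "none")
  dup <- tab[is_zoo & tab$genus_name %in% mesh_dup, , drop = FALSE]
  if (nrow(dup) > 0) {
    dup$mesh <- "coarse"
    tab <- dplyr::bind_rows(tab, dup)
  }
  dplyr::arrange(tab, .data$site_id, .data$group, .data$order_name,
                 .data$genus_name, .data$mesh)
}
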