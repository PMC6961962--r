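#' Default settings for a full analysis run
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param ... Overrides for any setting: `tp_threshold`, `color_threshold`,
#'   `neighborhood_size`, `z`, `n_boot`, `rao_n_rep`, `n_perm`, `k`,
#'   `n_restarts`, `alpha`, `n_tests`, `nmds_max_sites`, `output_dir`.
#' @return A named list of settings.
#' @export
run_settings <- function(seed = 1, ...) {
  out <- list(
    seed = seed,
    tp_threshold = 30, color_threshold = 20,
    neighborhood_size = 4, z = 1.96,
    n_boot = 999, rao_n_rep = 10000,
    n_perm = 999, k = 2, n_restarts = 10,
    alpha = 0.05, n_tests = 14,
    nmds_max_sites = 150,
    output_dir = NULL
  )
  utils::modifyList(out, list(...))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full nutrient-color analysis
#'
#' Orchestrates every stage on a pair of surveys plus a plankton table:
#' detection filtering, classification, design-weighted class-proportion
#' estimates per survey (national and per ecoregion when available),
#' between-survey change analysis, pairing of resampled lakes, the class
#' transition matrix, change vectors with circular statistics, the
#' community pipeline (mesh merging, rare-taxon filtering at order then
#' genus level, rank aggregation, biomass ratios), Kruskal-Wallis/Dunn
#' comparisons of biomass across classes, and Bray-Curtis PERMANOVA and
#' NMDS of the order-level community. All randomised stages take seeds
#' derived from the master seed, so a rerun reproduces the bundle exactly.
#' When `settings$output_dir` is set, results are written as CSV/JSON and
#' a manifest records parameters and an MD5 hash of every output file.
#'
#' @param survey_t1,survey_t2 Survey tibbles (see [read_survey_table()] or
#'   [generate_population()]).
#' @param taxa Optional taxon-count tibble for the second survey's lakes.
#' @param settings A list from [run_settings()].
#' @return A list of class `nc_run` with elements `estimates_t1`,
#'   `estimates_t2`, `change`, `pairs`, `transition`, `transition_summary`,
#'   `vectors`, `vector_summary`, `community` (or `NULL`), `tests`,
#'   `permanova`, `nmds`, `settings`, `manifest`.
#' @export
run_full_analysis <- function(survey_t1, survey_t2, taxa = NULL,
                              settings = run_settings()) {
  th <- nc_thresholds(settings$tp_threshold, settings$color_threshold)
  by <- if ("ecoregion" %in% names(survey_t1)) "ecoregion" else NULL

  s1 <- .stage("detection_filter", apply_detection_filter(survey_t1))
  s2 <- .stage("detection_filter", apply_detection_filter(survey_t2))
  s1 <- .stage("classify", classify_lakes(s1, th))
  s2 <- .stage("classify", classify_lakes(s2, th))

  est1 <- .stage("estimate", category_estimates(
    s1, by = by, neighborhood_size = settings$neighborhood_size,
    z = settings$z))
  est2 <- .stage("estimate", category_estimates(
    s2, by = by, neighborhood_size = settings$neighborhood_size,
    z = settings$z))
  chg <- .stage("change", change_analysis(est1, est2, z = settings$z))

  pairs <- .stage("pair", pair_resampled(s1, s2))
  tm <- .stage("transition", transition_matrix(pairs, th))
  vecs <- .stage("vectors", change_vectors(pairs, th))
  vsum <- .stage("vectors", summarize_change_vectors(
    vecs, n_boot = settings$n_boot, rao_n_rep = settings$rao_n_rep,
    seed = settings$seed))

  comm <- NULL; tests <- NULL; perm <- NULL; ord <- NULL
  if (!is.null(taxa)) {
    comm <- .stage("community", {
      merged <- merge_mesh_duplicates(taxa)
      zoo_order <- filter_rare_taxa(
        community_matrix(merged, "zooplankton", "order", "biomass"))
      kept_orders <- setdiff(names(zoo_order), "site_id")
      zoo_gen_all <- community_matrix(merged, "zooplankton", "genus",
                                      "biomass")
      taxonomy <- attr(zoo_gen_all, "taxonomy")
      in_kept <- taxonomy$genus[taxonomy$order %in% kept_orders]
      zoo_gen_all <- zoo_gen_all[, c("site_id",
                                     intersect(names(zoo_gen_all),
                                               in_kept))]
      attr(zoo_gen_all, "rank") <- "genus"
      attr(zoo_gen_all, "taxonomy") <- taxonomy
      zoo_genus <- filter_rare_taxa(zoo_gen_all)
      phyto <- filter_rare_taxa(
        community_matrix(merged, "phytoplankton", "order", "biomass"))
      list(zoo_genus = zoo_genus,
           zoo_order = aggregate_rank(zoo_genus),
           phyto_order = phyto,
           ratios = zp_ratios(aggregate_rank(zoo_genus), phyto))
    })
    site_class <- dplyr::select(s2, "site_id", "class")
    tests <- .stage("group_stats", {
      resp <- dplyr::inner_join(comm$ratios, site_class, by = "site_id")
      purrr::map_dfr(
        c("zoo_biomass", "phyto_biomass", "zp_ratio"),
        function(v) {
          kw <- kruskal_wallis(resp[[v]], resp$class)
          dplyr::mutate(kw, response = v, .before = 1)
        })
    })
    ord_mat <- comm$zoo_order
    if (nrow(ord_mat) > settings$nmds_max_sites) {
      old <- .Random.seed_save(); set.seed(settings$seed + 7)
      keep <- sort(sample.int(nrow(ord_mat), settings$nmds_max_sites))
      .Random.seed_restore(old)
      ord_mat <- ord_mat[keep, , drop = FALSE]
    }
    labels <- site_class$class[match(ord_mat$site_id,
                                     site_class$site_id)]
    usable <- !is.na(labels) & rowSums(.cm_values(ord_mat)) > 0
    d <- .stage("bray_curtis",
                bray_curtis(ord_mat[usable, , drop = FALSE]))
    perm <- .stage("permanova",
                   permanova(d, labels[usable], n_perm = settings$n_perm,
                             seed = settings$seed + 3))
    ord <- .stage("nmds", nmds(d, k = settings$k,
                               n_restarts = settings$n_restarts,
                               seed = settings$seed + 4))
  }

  out <- structure(
    list(
      estimates_t1 = est1, estimates_t2 = est2, change = chg,
      pairs = pairs, transition = tm,
      transition_summary = transition_summary(tm),
      vectors = vecs, vector_summary = vsum,
      community = comm, tests = tests, permanova = perm, nmds = ord,
      settings = settings, manifest = NULL
    ),
    class = "nc_run"
  )
  if (!is.null(settings$output_dir)) {
    out$manifest <- write_run_outputs(out, settings$output_dir)
  }
  out
}

#' Write a result bundle to disk with a manifest
#'
#' @param run An `nc_run` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return The manifest list (also written as `manifest.json`), listing
#'   every output file with its MD5 hash plus the settings used.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p, progress = FALSE)
    files <<- c(files, p)
  }
  wjson <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, p)
  }
  wcsv(run$estimates_t1, "estimates_t1.csv")
  wcsv(run$estimates_t2, "estimates_t2.csv")
  wcsv(run$change, "change.csv")
  wcsv(run$vectors, "vectors.csv")
  wcsv(run$vector_summary$rose, "rose_bins.csv")
  tm <- tibble::as_tibble(as.data.frame(unclass(run$transition)),
                          rownames = "origin")
  wcsv(tm, "transition_matrix.csv")
  vs <- run$vector_summary
  wjson(list(mean_direction = vs$mean_direction,
             rao = unclass(vs$rao),
             anova = vs$anova,
             n_vectors = vs$n_vectors, n_zero = vs$n_zero),
        "vector_summary.json")
  if (!is.null(run$community)) {
    wcsv(run$community$zoo_genus, "community_zoo_genus.csv")
    wcsv(run$community$zoo_order, "community_zoo_order.csv")
    wcsv(run$community$phyto_order, "community_phyto_order.csv")
    wcsv(run$community$ratios, "zp_ratios.csv")
    wcsv(run$tests, "group_tests.csv")
    wjson(unclass(run$permanova), "permanova.json")
    wcsv(run$nmds$points, "nmds_points.csv")
  }
  manifest <- list(
    settings = run$settings[setdiff(names(run$settings), "output_dir")],
    files = purrr::map(setNames(files, basename(files)),
                       function(p) list(md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.nc_run <- function(x, ...) {
  cat("Nutrient-color analysis run\n")
  ts <- x$transition_summary
  cat(sprintf("  %d paired lakes: %.1f%% unchanged, %.1f%% changed\n",
              ts$total, ts$unchanged_pct, ts$changed_pct))
  sig <- dplyr::filter(x$change, .data$scope == "national",
                       .data$significant)
  if (nrow(sig) > 0) {
    cat("  Significant national changes:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s: %+.1f points\n", sig$category[i], sig$delta[i]))
    }
  }
  invisible(x)
}
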