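small_config <- function(...) {
  synthetic_config(seed = 99, n_sample_per_stratum = 20,
                   n_population_per_stratum = 1000, ...)
}

test_that("a degenerate mixture yields a single class everywhere", {
  cfg <- small_config(class_mixture = c(blue = 1, green = 0, brown = 0,
                                        murky = 0))
  pop <- generate_population(cfg)
  expect_true(all(pop$true_class == "blue"))
  expect_true(all(nc_classify(pop$tp, pop$color) == "blue"))
})

test_that("generated TP and color recover the intended class labels", {
  cfg <- small_config()
  pop <- generate_population(cfg)
  expect_gte(mean(nc_classify(pop$tp, pop$color) == pop$true_class), 0.99)
  expect_true(all(pop$weight == 1000 / 20))
})

test_that("seeded generation is bit-reproducible", {
  cfg <- small_config()
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  d1 <- apply_drift(p1, cfg)
  d2 <- apply_drift(p2, cfg)
  expect_identical(d1$t2$tp, d2$t2$tp)
  c1 <- generate_communities(head(p1, 5), cfg)
  c2 <- generate_communities(head(p1, 5), cfg)
  expect_identical(c1, c2)
})

test_that("blue TP quartiles land near the calibration targets", {
  cfg <- synthetic_config(
    seed = 7, n_sample_per_stratum = 250,
    class_mixture = c(blue = 1, green = 0, brown = 0, murky = 0))
  pop <- generate_population(cfg)
  q <- quantile(pop$tp, c(0.25, 0.5, 0.75), names = FALSE)
  target <- c(10, 16.5, 24)
  expect_true(all(abs(q - target) / target < 0.15))
})

test_that("degenerate drift settings behave as limits", {
  cfg <- small_config(drift_theta0 = 45, drift_kappa = 1e8)
  pop <- generate_population(cfg)
  dr <- apply_drift(pop, cfg)
  v <- change_vectors(pair_resampled(dr$t1, dr$t2))
  expect_true(all(abs(v$angle_deg - 45) < 1))
  # zero magnitude: nothing moves, transition matrix is diagonal
  cfg0 <- small_config(drift_magnitude_meanlog = -Inf)
  pop0 <- generate_population(cfg0)
  dr0 <- apply_drift(pop0, cfg0)
  m <- unclass(transition_matrix(pair_resampled(dr0$t1, dr0$t2)))
  expect_equal(sum(m) - sum(diag(m)), 0)
})

test_that("drift recovers the configured mean direction", {
  cfg <- synthetic_config(seed = 11, n_sample_per_stratum = 45)
  pop <- generate_population(cfg)
  dr <- apply_drift(pop, cfg)
  v <- change_vectors(pair_resampled(dr$t1, dr$t2))
  cm <- circular_mean(v$angle_deg)
  dev <- abs(((cm$mean_angle - cfg$drift_model$theta0 + 180) %% 360) - 180)
  expect_lt(dev, 10)
})

test_that("revisit bookkeeping matches the configured fraction", {
  cfg <- small_config(revisit_fraction = 0.5)
  pop <- generate_population(cfg)
  dr <- apply_drift(pop, cfg)
  expect_equal(sum(dr$t1$resampled), round(0.5 * nrow(pop)))
  expect_equal(dr$t1$resampled, dr$t2$resampled)
  pairs <- pair_resampled(dplyr::filter(dr$t1, resampled),
                          dplyr::filter(dr$t2, resampled))
  expect_equal(nrow(pairs), sum(dr$t1$resampled))
})

test_that("synthetic communities reproduce the class biomass ordering", {
  cfg <- synthetic_config(seed = 13, n_sample_per_stratum = 112,
                          class_mixture = c(blue = 0.25, green = 0.25,
                                            brown = 0.25, murky = 0.25))
  pop <- generate_population(cfg)
  taxa <- generate_communities(pop, cfg)
  merged <- merge_mesh_duplicates(taxa)
  zoo <- community_matrix(merged, "zooplankton", "order", "biomass")
  tot <- tibble::tibble(site_id = zoo$site_id,
                        biomass = rowSums(as.matrix(zoo[, -1])))
  tot$class <- pop$true_class[match(tot$site_id, pop$site_id)]
  med <- tapply(tot$biomass, tot$class, median)
  expect_gt(med[["murky"]], med[["green"]])
  expect_gt(med[["green"]], med[["brown"]])
  expect_lt(abs(log(med[["brown"]] / med[["blue"]])), log(2.5))
})

test_that("murky lakes carry roughly twice the blue rotifer share", {
  cfg <- synthetic_config(seed = 17, n_sample_per_stratum = 56,
                          class_mixture = c(blue = 0.5, green = 0,
                                            brown = 0, murky = 0.5))
  pop <- generate_population(cfg)
  taxa <- generate_communities(pop, cfg)
  merged <- merge_mesh_duplicates(taxa)
  zoo <- community_matrix(merged, "zooplankton", "order", "biomass")
  shares <- as.matrix(zoo[, -1]) / rowSums(as.matrix(zoo[, -1]))
  rot <- rowSums(shares[, intersect(colnames(shares),
                                    zp_order_sets()$rotifer)])
  cls <- pop$true_class[match(zoo$site_id, pop$site_id)]
  ratio <- mean(rot[cls == "murky"]) / mean(rot[cls == "blue"])
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.8)
})

test_that("mesh-duplicated taxa merge to half their record count", {
  cfg <- small_config()
  pop <- generate_population(cfg)
  taxa <- generate_communities(head(pop, 10), cfg)
  dup_taxa <- unique(taxa$taxon_id[taxa$mesh == "coarse"])
  before <- sum(taxa$taxon_id %in% dup_taxa)
  merged <- merge_mesh_duplicates(taxa)
  after <- sum(merged$taxon_id %in% dup_taxa)
  expect_equal(after, before / 2)
})

test_that("calibration reproduces untruncated quartiles exactly", {
  # with no truncation the three quartiles determine the lognormal
  fit <- calibrate_truncated_lognormal(c(10, 20, 40), lo = 0, hi = Inf)
  q <- stats::qlnorm(c(0.25, 0.5, 0.75), fit$meanlog, fit$sdlog)
  expect_equal(q, c(10, 20, 40), tolerance = 1e-3)
})
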