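#' Convert phytoplankton biovolume to dry biomass
#'
#' Biovolume in um^3 per mL is converted to wet mass assuming unit cell
#' density (1 um^3 = 1e-6 ug), scaled from per-mL to per-L, and reduced to
#' dry weight with a 20% wet-to-dry fraction. The conversion is linear:
#' 1e6 um^3/mL corresponds to 1000 ug wet/L and 200 ug dry weight/L.
#'
#' @param biovolume Numeric vector, um^3/mL, non-negative.
#' @param dry_fraction Dry : wet mass ratio (default 0.20).
#' @return Dry biomass, ug dry weight/L.
#' @export
biovolume_to_dry_biomass <- function(biovolume, dry_fraction = 0.20) {
  if (any(biovolume < 0, na.rm = TRUE)) {
    abort("`biovolume` must be non-negative.")
  }
  biovolume * 1e-6 * 1000 * dry_fraction
}

#' Average zooplankton taxa counted in both mesh sizes
#'
#' Zooplankton can appear in both the fine (50 um) and coarse (150 um)
#' net samples. For each site and taxon counted in both meshes, density
#' and biomass are replaced by their arithmetic mean; taxa caught in a
#' single mesh pass through unchanged. Idempotent: merged records carry
#' mesh `"merged"` and are never averaged again. Phytoplankton records
#' pass through untouched.
#'
#' @param counts A taxon-count tibble (see [read_taxon_table()]).
#' @return The tibble with mesh duplicates collapsed.
#' @export
merge_mesh_duplicates <- function(counts) {
  counts <- tibble::as_tibble(counts)
  is_zoo <- counts$group == "zooplankton" &
    counts$mesh %in% c("fine", "coarse")
  zoo <- counts[is_zoo, , drop = FALSE]
  rest <- counts[!is_zoo, , drop = FALSE]
  if (nrow(zoo) == 0) return(counts)
  merged <- zoo |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      intersect(c("site_id", "group", "order_name", "genus_name",
                  "taxon_id"), names(zoo))))) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(c("density", "biomass", "biovolume")),
                    ~ mean(.x)),
      mesh = if (dplyr::n() > 1) "merged" else .data$mesh[1],
      .groups = "drop"
    )
  dplyr::bind_rows(rest, merged)
}

#' Build a sites-by-taxa community matrix
#'
#' Pivots a taxon-count table into a wide community tibble for one group
#' (zooplankton or phytoplankton) at a chosen taxonomic rank, summing the
#' chosen value over records of the same site and taxon. Phytoplankton
#' biovolume is converted to dry biomass when `value = "biomass"` and only
#' `biovolume` is present.
#'
#' @param counts A taxon-count tibble (mesh duplicates should be merged
#'   first; see [merge_mesh_duplicates()]).
#' @param group `"zooplankton"` or `"phytoplankton"`.
#' @param rank `"genus"` or `"order"`.
#' @param value `"biomass"` (ug dry weight/L) or `"density"` (per mL).
#' @return A tibble with a `site_id` column and one numeric column per
#'   taxon; attributes `rank`, `group`, `value`, and `taxonomy` (a tibble
#'   mapping genus to order, when rank is genus).
#' @export
community_matrix <- function(counts, group = c("zooplankton",
                                               "phytoplankton"),
                             rank = c("genus", "order"),
                             value = c("biomass", "density")) {
  group <- match.arg(group)
  rank <- match.arg(rank)
  value <- match.arg(value)
  d <- dplyr::filter(tibble::as_tibble(counts), .data$group == .env$group)
  if (nrow(d) == 0) abort(paste0("No ", group, " records."))
  if (value == "biomass" && (!"biomass" %in% names(d) ||
                             all(is.na(d$biomass)))) {
    if (group == "phytoplankton" && "biovolume" %in% names(d)) {
      d$biomass <- biovolume_to_dry_biomass(d$biovolume)
    } else {
      abort("No biomass column available.")
    }
  }
  taxon_col <- if (rank == "genus") "genus_name" else "order_name"
  if (!taxon_col %in% names(d) || all(is.na(d[[taxon_col]]))) {
    abort(paste0("No ", rank, " names in the table."))
  }
  d <- dplyr::filter(d, !is.na(.data[[taxon_col]]))
  taxonomy <- NULL
  if (rank == "genus") {
    taxonomy <- dplyr::distinct(d, genus = .data$genus_name,
                                order = .data$order_name)
    multi <- taxonomy$genus[duplicated(taxonomy$genus)]
    if (length(multi) > 0) {
      abort(paste0("Genus mapped to multiple orders: ",
                   paste(unique(multi), collapse = ", ")))
    }
  }
  wide <- d |>
    dplyr::group_by(.data$site_id, taxon = .data[[taxon_col]]) |>
    dplyr::summarise(v = sum(.data[[value]], na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "v",
                       values_fill = 0) |>
    dplyr::arrange(.data$site_id)
  structure(wide, rank = rank, group = group, value = value,
            taxonomy = taxonomy)
}

.cm_values <- function(matrix) {
  as.matrix(matrix[, setdiff(names(matrix), "site_id"), drop = FALSE])
}

#' Remove taxa that never reach a within-sample share threshold
#'
#' A taxon is retained only if it contributes at least `threshold` of the
#' site total in at least one site. Applied to rare-taxon screening at
#' order level first and then at genus level within retained orders (call
#' once per rank). Idempotent and never increases the number of taxa.
#'
#' @param matrix A community tibble from [community_matrix()].
#' @param threshold Minimum within-sample relative contribution (0.05 =
#'   5%).
#' @return The filtered community tibble (attributes preserved; dropped
#'   taxa recorded in attribute `dropped`).
#' @export
filter_rare_taxa <- function(matrix, threshold = 0.05) {
  vals <- .cm_values(matrix)
  totals <- rowSums(vals)
  shares <- vals / ifelse(totals > 0, totals, NA_real_)
  keep <- apply(shares, 2, function(s) any(s >= threshold, na.rm = TRUE))
  if (!any(keep)) {
    abort(paste0("No taxon reaches a ", threshold * 100,
                 "% share in any sample; lower the threshold."))
  }
  out <- matrix[, c("site_id", colnames(vals)[keep]), drop = FALSE]
  for (a in c("rank", "group", "value", "taxonomy")) {
    attr(out, a) <- attr(matrix, a)
  }
  attr(out, "dropped") <- colnames(vals)[!keep]
  out
}

#' Aggregate a genus-level matrix to order level
#'
#' Sums genus columns within each order; per-site totals are conserved
#' exactly.
#'
#' @param matrix A genus-rank community tibble from [community_matrix()].
#' @param taxonomy Optional tibble with `genus` and `order` columns;
#'   defaults to the matrix's `taxonomy` attribute.
#' @return An order-rank community tibble.
#' @export
aggregate_rank <- function(matrix, taxonomy = NULL) {
  if (!identical(attr(matrix, "rank"), "genus")) {
    abort("`matrix` must be a genus-rank community matrix.")
  }
  taxonomy <- taxonomy %||% attr(matrix, "taxonomy")
  if (is.null(taxonomy)) abort("No genus-to-order taxonomy available.")
  genera <- setdiff(names(matrix), "site_id")
  unknown <- setdiff(genera, taxonomy$genus)
  if (length(unknown) > 0) {
    abort(paste0("Genus with unknown order: ",
                 paste(unknown, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(matrix, -"site_id", names_to = "genus",
                              values_to = "v")
  out <- long |>
    dplyr::left_join(taxonomy, by = "genus") |>
    dplyr::group_by(.data$site_id, .data$order) |>
    dplyr::summarise(v = sum(.data$v), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "order", values_from = "v",
                       values_fill = 0) |>
    dplyr::arrange(.data$site_id)
  structure(out, rank = "order", group = attr(matrix, "group"),
            value = attr(matrix, "value"), taxonomy = NULL)
}

#' Rotifer and crustacean order sets
#'
#' Default zooplankton order groupings used for the biomass ratios:
#' rotifers are Ploima and Flosculariaceae; crustaceans are the copepod
#' orders (Calanoida, Cyclopoida) plus the cladoceran order Diplostraca.
#'
#' @return A list with character vectors `rotifer` and `crustacean`.
#' @export
zp_order_sets <- function() {
  list(
    rotifer = c("Ploima", "Flosculariaceae"),
    crustacean = c("Calanoida", "Cyclopoida", "Diplostraca")
  )
}

#' Zooplankton : phytoplankton biomass ratios per lake
#'
#' Totals each site's zooplankton and phytoplankton biomass and computes
#' the overall ratio plus crustacean-only and rotifer-only variants. Sites
#' with zero phytoplankton biomass keep their row with `NA` (undefined)
#' ratios.
#'
#' @param zoo An order-rank zooplankton community tibble (biomass values).
#' @param phyto A phytoplankton community tibble (biomass values).
#' @param order_sets Rotifer/crustacean order groupings, see
#'   [zp_order_sets()].
#' @return A tibble with `site_id`, `zoo_biomass`, `phyto_biomass`,
#'   `zp_ratio`, `crustacean_zp_ratio`, `rotifer_zp_ratio`.
#' @export
zp_ratios <- function(zoo, phyto, order_sets = zp_order_sets()) {
  zv <- .cm_values(zoo)
  pv <- .cm_values(phyto)
  ztot <- tibble::tibble(site_id = zoo$site_id, zoo_biomass = rowSums(zv))
  crust_cols <- intersect(colnames(zv), order_sets$crustacean)
  rot_cols <- intersect(colnames(zv), order_sets$rotifer)
  ztot$crust <- rowSums(zv[, crust_cols, drop = FALSE])
  ztot$rot <- rowSums(zv[, rot_cols, drop = FALSE])
  ptot <- tibble::tibble(site_id = phyto$site_id,
                         phyto_biomass = rowSums(pv))
  out <- dplyr::inner_join(ztot, ptot, by = "site_id")
  dplyr::transmute(
    out,
    site_id = .data$site_id,
    zoo_biomass = .data$zoo_biomass,
    phyto_biomass = .data$phyto_biomass,
    zp_ratio = ifelse(.data$phyto_biomass > 0,
                      .data$zoo_biomass / .data$phyto_biomass, NA_real_),
    crustacean_zp_ratio = ifelse(.data$phyto_biomass > 0,
                                 .data$crust / .data$phyto_biomass,
                                 NA_real_),
    rotifer_zp_ratio = ifelse(.data$phyto_biomass > 0,
                              .data$rot / .data$phyto_biomass, NA_real_)
  )
}
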