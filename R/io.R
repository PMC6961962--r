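#' Column dialects for survey tables
#'
#' A dialect maps the canonical column names used throughout the package to
#' the header names of a particular CSV export. Two built-in dialects cover
#' the column styles of the 2007-era and 2012-era national lake survey
#' exports; `"canonical"` is the identity mapping used by tables the package
#' writes itself.
#'
#' @param name One of `"canonical"`, `"nla2007"`, `"nla2012"`.
#' @return A named character vector: names are canonical fields, values are
#'   file column names. Mandatory fields are `site_id`, `year`, `weight`,
#'   `tp`, `color`; the rest are optional.
#' @export
survey_dialect <- function(name = c("canonical", "nla2007", "nla2012")) {
  name <- match.arg(name)
  switch(name,
    canonical = c(
      site_id = "site_id", year = "year", weight = "weight",
      ecoregion = "ecoregion", lat = "lat", lon = "lon",
      tp = "tp", color = "color", tp_below_detection = "tp_below_detection",
      area_ha = "area_ha"
    ),
    nla2007 = c(
      site_id = "SITE_ID", year = "YEAR", weight = "WGT_NLA",
      ecoregion = "WSA_ECO9", lat = "LAT_DD", lon = "LON_DD",
      tp = "PTL", color = "COLOR", tp_below_detection = "PTL_BELOW_DETECT",
      area_ha = "LAKEAREA_HA"
    ),
    nla2012 = c(
      site_id = "SITE_ID", year = "YEAR", weight = "WGT_ALL",
      ecoregion = "AGGR_ECO9_2015", lat = "LAT_DD83", lon = "LON_DD83",
      tp = "PTL_RESULT", color = "COLOR_RESULT",
      tp_below_detection = "PTL_BELOW_DETECT", area_ha = "AREA_HA"
    )
  )
}

.mandatory_survey_fields <- c("site_id", "year", "weight", "tp", "color")

.as_num <- function(x) suppressWarnings(as.numeric(x))

.as_flag <- function(x) {
  if (is.null(x)) return(FALSE)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y")
}

#' Read and validate a lake-survey CSV
#'
#' Reads one row per site-visit, renames columns through a dialect, coerces
#' units as declared (TP in ug/L, color in PCU, area in ha), and validates
#' row by row. Rows that cannot become a valid sample (non-numeric or
#' missing TP/color/weight, non-positive weight, duplicated site-year) are
#' dropped and reported in the `rejects` attribute with a reason; they are
#' never silently zero-filled.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect A named character vector mapping canonical fields to file
#'   columns; see [survey_dialect()].
#' @return A tibble of validated samples with canonical columns plus any
#'   extra file columns as covariates. Attributes: `rejects` (tibble with
#'   `row`, `site_id`, `reason`) and `n_rejected`.
#' @export
read_survey_table <- function(path, dialect = survey_dialect("canonical")) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(unname(dialect[.mandatory_survey_fields]),
                          names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Mandatory column(s) missing from ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  present <- dialect[dialect %in% names(raw)]
  out <- raw
  names(out)[match(unname(present), names(out))] <- names(present)

  n <- nrow(out)
  reason <- rep(NA_character_, n)
  num_fields <- intersect(c("year", "weight", "tp", "color", "lat", "lon",
                            "area_ha"), names(out))
  for (f in num_fields) out[[f]] <- .as_num(out[[f]])
  if ("tp_below_detection" %in% names(out)) {
    out$tp_below_detection <- .as_flag(out$tp_below_detection)
  } else {
    out$tp_below_detection <- FALSE
  }
  # extra covariate columns: numeric where they parse cleanly
  extra <- setdiff(names(out), c(names(dialect), "tp_below_detection"))
  for (f in extra) {
    v <- .as_num(out[[f]])
    if (!any(is.na(v) & !is.na(out[[f]]) & trimws(out[[f]]) != "" &
               toupper(trimws(out[[f]])) != "NA")) out[[f]] <- v
  }

  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason <<- ifelse(cond & is.na(reason), why, reason)
  }
  bad(is.na(out$site_id) | trimws(out$site_id) == "", "missing site_id")
  bad(is.na(out$year), "non-numeric or missing year")
  bad(is.na(out$weight), "non-numeric or missing weight")
  bad(!is.na(out$weight) & out$weight <= 0, "non-positive weight")
  bad(is.na(out$tp), "non-numeric or missing tp")
  bad(!is.na(out$tp) & out$tp < 0 & !out$tp_below_detection, "negative tp")
  bad(is.na(out$color), "non-numeric or missing color")
  bad(!is.na(out$color) & out$color < 0, "negative color")
  if ("area_ha" %in% names(out)) {
    bad(!is.na(out$area_ha) & out$area_ha <= 0, "non-positive area_ha")
  }
  key <- paste(out$site_id, out$year)
  bad(duplicated(key), "duplicate site-year")

  rejects <- tibble::tibble(
    row = which(!is.na(reason)),
    site_id = out$site_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  kept <- tibble::as_tibble(out[is.na(reason), , drop = FALSE])
  if (nrow(rejects) > 0) {
    inform(paste0("read_survey_table: rejected ", nrow(rejects), " of ", n,
                  " rows."))
  }
  attr(kept, "rejects") <- rejects
  attr(kept, "n_rejected") <- nrow(rejects)
  kept
}

#' Write a survey table as CSV
#'
#' Plain RFC-4180 CSV with a header; numeric columns are written with
#' round-trip precision so a write/read cycle reproduces values exactly.
#'
#' @param data A survey tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Rejected rows from a read
#'
#' @param data A tibble returned by [read_survey_table()] or
#'   [read_taxon_table()].
#' @return The `rejects` attribute (a tibble), or an empty tibble.
#' @export
rejected_rows <- function(data) {
  attr(data, "rejects") %||%
    tibble::tibble(row = integer(), site_id = character(),
                   reason = character())
}

#' Read a plankton count table
#'
#' Expects columns `site_id`, `group` (phytoplankton/zooplankton),
#' `order_name`, `taxon_id` and any of `genus_name`, `mesh` (none/fine/
#' coarse), `density` (individuals or cells per mL), `biovolume` (um^3/mL),
#' `biomass` (ug dry weight/L). Rows with negative or unparseable density,
#' biovolume or biomass are rejected with a reason.
#'
#' @param path Path to a CSV file.
#' @return A tibble of taxon counts; rejected rows in the `rejects`
#'   attribute.
#' @export
read_taxon_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  mandatory <- c("site_id", "group", "order_name", "taxon_id")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Mandatory column(s) missing from ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- raw
  for (f in intersect(c("density", "biovolume", "biomass"), names(out))) {
    out[[f]] <- .as_num(out[[f]])
  }
  if (!"mesh" %in% names(out)) out$mesh <- "none"
  if (!"genus_name" %in% names(out)) out$genus_name <- NA_character_
  reason <- rep(NA_character_, nrow(out))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason <<- ifelse(cond & is.na(reason), why, reason)
  }
  bad(!out$group %in% c("phytoplankton", "zooplankton"), "unknown group")
  bad(!out$mesh %in% c("none", "fine", "coarse"), "unknown mesh")
  if ("density" %in% names(out)) bad(out$density < 0, "negative density")
  if ("biovolume" %in% names(out)) bad(out$biovolume < 0, "negative biovolume")
  if ("biomass" %in% names(out)) bad(out$biomass < 0, "negative biomass")
  ok_rows <- is.na(reason)   # only rows still valid can violate this
  grp_per_taxon <- tapply(out$group[ok_rows], out$taxon_id[ok_rows],
                          function(g) length(unique(g)))
  mixed <- names(grp_per_taxon)[grp_per_taxon > 1]
  bad(out$taxon_id %in% mixed, "taxon_id in more than one group")
  rejects <- tibble::tibble(
    row = which(!is.na(reason)),
    site_id = out$site_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  kept <- tibble::as_tibble(out[is.na(reason), , drop = FALSE])
  attr(kept, "rejects") <- rejects
  attr(kept, "n_rejected") <- nrow(rejects)
  kept
}

#' Drop samples flagged below the TP detection limit
#'
#' Samples whose TP fell below the survey detection limit are flagged in
#' the exports rather than carrying a usable concentration; they are removed
#' before classification and the number removed is reported.
#'
#' @param data A survey tibble with a logical `tp_below_detection` column
#'   (absence means no sample is flagged).
#' @return The retained rows, with attribute `n_removed`.
#' @export
apply_detection_filter <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"tp_below_detection" %in% names(data) || nrow(data) == 0) {
    attr(data, "n_removed") <- 0L
    return(data)
  }
  flagged <- isTRUE_vec(data$tp_below_detection)
  out <- data[!flagged, , drop = FALSE]
  attr(out, "n_removed") <- sum(flagged)
  if (sum(flagged) > 0) {
    inform(paste0("apply_detection_filter: removed ", sum(flagged),
                  " sample(s) below the TP detection limit."))
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Pair lakes sampled in both surveys
#'
#' Matches sites appearing in two survey tables by `site_id` and returns one
#' row per resampled lake with the two visits side by side (suffixes `_t1`
#' and `_t2`, earlier year first). Pairs missing TP or color in either year
#' are excluded and logged; unmatched sites are listed in attributes.
#'
#' @param survey1,survey2 Validated survey tibbles (one row per site).
#' @return A tibble with `site_id`, and for every shared column `x` the pair
#'   `x_t1`, `x_t2`. Attributes: `unmatched_t1`, `unmatched_t2`, `excluded`
#'   (sites dropped for missing TP/color).
#' @export
pair_resampled <- function(survey1, survey2) {
  for (nm in c("survey1", "survey2")) {
    s <- get(nm)
    dup <- unique(s$site_id[duplicated(s$site_id)])
    if (length(dup) > 0) {
      abort(paste0("Duplicate site_id in ", nm, ": ",
                   paste(head(dup, 5), collapse = ", ")))
    }
  }
  shared_cols <- setdiff(intersect(names(survey1), names(survey2)), "site_id")
  j <- dplyr::inner_join(
    tibble::as_tibble(survey1), tibble::as_tibble(survey2),
    by = "site_id", suffix = c("_t1", "_t2")
  )
  # order visits so that _t1 is the earlier year
  if (all(c("year_t1", "year_t2") %in% names(j)) && nrow(j) > 0) {
    flip <- !is.na(j$year_t1) & !is.na(j$year_t2) & j$year_t1 > j$year_t2
    if (any(flip)) {
      for (x in shared_cols) {
        a <- paste0(x, "_t1"); b <- paste0(x, "_t2")
        tmp <- j[[a]][flip]; j[[a]][flip] <- j[[b]][flip]; j[[b]][flip] <- tmp
      }
    }
  }
  usable <- !is.na(j$tp_t1) & !is.na(j$color_t1) &
    !is.na(j$tp_t2) & !is.na(j$color_t2)
  excluded <- j$site_id[!usable]
  out <- j[usable, , drop = FALSE]
  attr(out, "unmatched_t1") <- setdiff(survey1$site_id, survey2$site_id)
  attr(out, "unmatched_t2") <- setdiff(survey2$site_id, survey1$site_id)
  attr(out, "excluded") <- excluded
  if (length(excluded) > 0) {
    inform(paste0("pair_resampled: excluded ", length(excluded),
                  " pair(s) with missing TP or color."))
  }
  out
}
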