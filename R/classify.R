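#' Nutrient-color class labels
#'
#' The four classes crossing trophic state (total phosphorus) with true
#' water color: blue (low TP, low color), green (high TP, low color),
#' brown (low TP, high color) and murky (high TP, high color).
#'
#' @return Character vector of the four labels in canonical order.
#' @export
nc_classes <- function() c("blue", "green", "brown", "murky")

#' Classification thresholds
#'
#' Default benchmarks splitting the (TP, color) plane: 30 ug/L total
#' phosphorus and 20 PCU true color. Values at or below a threshold fall on
#' the blue/brown side.
#'
#' @param tp Total phosphorus threshold, ug/L.
#' @param color True color threshold, PCU.
#' @return A named list with elements `tp` and `color`.
#' @export
nc_thresholds <- function(tp = 30, color = 20) {
  stopifnot(is.numeric(tp), length(tp) == 1, tp > 0,
            is.numeric(color), length(color) == 1, color > 0)
  list(tp = tp, color = color)
}

#' Assign nutrient-color classes from TP and color
#'
#' Vectorised four-way classification. A lake is blue if TP <= 30 ug/L and
#' color <= 20 PCU, green if TP > 30 and color <= 20, brown if TP <= 30 and
#' color > 20, and murky if TP > 30 and color > 20. The four rules partition
#' the non-negative quadrant: every (tp, color) pair receives exactly one
#' label.
#'
#' @param tp Numeric vector of total phosphorus, ug/L. Must be >= 0.
#' @param color Numeric vector of true color, PCU. Must be >= 0.
#' @param thresholds A list from [nc_thresholds()].
#' @return A factor with levels `blue`, `green`, `brown`, `murky`. `NA`
#'   inputs yield `NA` labels.
#' @examples
#' nc_classify(c(16.5, 65, 20, 110), c(11, 15, 30, 30))
#' @export
nc_classify <- function(tp, color, thresholds = nc_thresholds()) {
  if (length(tp) != length(color)) {
    abort("`tp` and `color` must have the same length.")
  }
  if (any(tp < 0, na.rm = TRUE) || any(color < 0, na.rm = TRUE)) {
    abort("`tp` and `color` must be non-negative.")
  }
  hi_tp <- tp > thresholds$tp
  hi_col <- color > thresholds$color
  lab <- dplyr::case_when(
    !hi_tp & !hi_col ~ "blue",
    hi_tp & !hi_col ~ "green",
    !hi_tp & hi_col ~ "brown",
    hi_tp & hi_col ~ "murky"
  )
  factor(lab, levels = nc_classes())
}

#' Classify a survey table
#'
#' Appends a `class` column to a lake-survey data frame using
#' [nc_classify()]. Rows with missing TP or color get `NA` and are counted
#' in the attached attribute `n_unclassified`.
#'
#' @param data A data frame with numeric `tp` and `color` columns.
#' @param thresholds A list from [nc_thresholds()].
#' @return The input as a tibble with a `class` factor column.
#' @export
classify_lakes <- function(data, thresholds = nc_thresholds()) {
  stopifnot(is.data.frame(data), all(c("tp", "color") %in% names(data)))
  out <- dplyr::mutate(tibble::as_tibble(data),
                       class = nc_classify(.data$tp, .data$color, thresholds))
  attr(out, "n_unclassified") <- sum(is.na(out$class))
  out
}

#' Per-class quartile bounds for "extreme" lakes
#'
#' Computes, within each nutrient-color class, the first and third quartiles
#' (type-7 linear interpolation) of TP and color, and records which bound
#' defines an extreme lake of that class: blue lakes are extreme below the
#' first quartile of both TP and color; green below the color first quartile
#' and above the TP third quartile; brown above the color third quartile and
#' below the TP first quartile; murky above the third quartile of both.
#'
#' @param data A classified survey tibble (see [classify_lakes()]) with
#'   `class`, `tp` and `color` columns.
#' @param min_n Minimum class size needed to compute quartiles.
#' @return A tibble with one row per class: `class`, `tp_bound`,
#'   `tp_direction` ("below_q1"/"above_q3"), `color_bound`,
#'   `color_direction`, `n`.
#' @export
extreme_thresholds <- function(data, min_n = 4) {
  stopifnot(all(c("class", "tp", "color") %in% names(data)))
  data <- dplyr::filter(data, !is.na(.data$class))
  counts <- dplyr::count(data, .data$class, .drop = FALSE)
  short <- counts$class[counts$n < min_n]
  if (length(short) > 0) {
    abort(paste0("Classes with fewer than ", min_n, " lakes: ",
                 paste(short, collapse = ", ")))
  }
  dirs <- tibble::tibble(
    class = factor(nc_classes(), levels = nc_classes()),
    tp_direction = c("below_q1", "above_q3", "below_q1", "above_q3"),
    color_direction = c("below_q1", "below_q1", "above_q3", "above_q3")
  )
  q <- data |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      tp_q1 = quantile(.data$tp, 0.25, type = 7, names = FALSE),
      tp_q3 = quantile(.data$tp, 0.75, type = 7, names = FALSE),
      color_q1 = quantile(.data$color, 0.25, type = 7, names = FALSE),
      color_q3 = quantile(.data$color, 0.75, type = 7, names = FALSE),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(dirs, by = "class") |>
    dplyr::mutate(
      tp_bound = ifelse(.data$tp_direction == "below_q1",
                        .data$tp_q1, .data$tp_q3),
      color_bound = ifelse(.data$color_direction == "below_q1",
                           .data$color_q1, .data$color_q3)
    )
  dplyr::select(q, "class", "tp_bound", "tp_direction",
                "color_bound", "color_direction", "n")
}

#' Flag extreme lakes
#'
#' Marks lakes whose TP and color are both strictly beyond their class's
#' extreme bounds (strictly below the first quartile or strictly above the
#' third, per the class-specific directions from [extreme_thresholds()]).
#'
#' @param data A classified survey tibble.
#' @param thresholds Optional result of [extreme_thresholds()]; computed
#'   from `data` when omitted.
#' @return `data` with a logical `extreme` column (`NA` for unclassified
#'   rows).
#' @export
flag_extreme <- function(data, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- extreme_thresholds(data)
  joined <- dplyr::left_join(tibble::as_tibble(data), thresholds, by = "class")
  beyond <- function(x, bound, direction) {
    ifelse(direction == "below_q1", x < bound, x > bound)
  }
  out <- dplyr::mutate(
    joined,
    extreme = beyond(.data$tp, .data$tp_bound, .data$tp_direction) &
      beyond(.data$color, .data$color_bound, .data$color_direction)
  )
  dplyr::select(out, -"tp_bound", -"tp_direction", -"color_bound",
                -"color_direction", -dplyr::any_of("n"))
}

#' Class-transition matrix for resampled lakes
#'
#' Cross-tabulates origin (first survey) against destination (second survey)
#' nutrient-color class for paired lakes. Row sums equal the origin-class
#' counts and the grand total equals the number of pairs.
#'
#' @param pairs A paired-lake tibble (see [pair_resampled()]) with columns
#'   `tp_t1`, `color_t1`, `tp_t2`, `color_t2`, or precomputed `class_t1` and
#'   `class_t2` factor columns.
#' @param thresholds A list from [nc_thresholds()].
#' @return A 4x4 integer matrix with origin classes as rows and destination
#'   classes as columns, of class `nc_transition`.
#' @export
transition_matrix <- function(pairs, thresholds = nc_thresholds()) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0) abort("`pairs` must be non-empty.")
  if (!all(c("class_t1", "class_t2") %in% names(pairs))) {
    pairs <- dplyr::mutate(
      pairs,
      class_t1 = nc_classify(.data$tp_t1, .data$color_t1, thresholds),
      class_t2 = nc_classify(.data$tp_t2, .data$color_t2, thresholds)
    )
  }
  m <- table(origin = pairs$class_t1, destination = pairs$class_t2)
  m <- unclass(m)[nc_classes(), nc_classes()]
  storage.mode(m) <- "integer"
  structure(m, class = c("nc_transition", "matrix"))
}

#' Summarise a class-transition matrix
#'
#' Reports the share of lakes that stayed in their origin class
#' (trace / total), the share that changed, and per-origin counts of
#' off-diagonal shifts.
#'
#' @param matrix A 4x4 transition matrix from [transition_matrix()] (or any
#'   square matrix with class labels on both margins).
#' @return A list with `unchanged_pct`, `changed_pct`, `total`, and a tibble
#'   `by_origin` with columns `origin`, `n`, `shifted`, plus a `shifts`
#'   tibble of the off-diagonal counts (`origin`, `destination`, `n`).
#' @export
transition_summary <- function(matrix) {
  m <- unclass(matrix)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  total <- sum(m)
  if (total <= 0) abort("Transition matrix total must be positive.")
  unchanged <- sum(diag(m)) / total
  by_origin <- tibble::tibble(
    origin = factor(rownames(m), levels = rownames(m)),
    n = as.integer(rowSums(m)),
    shifted = as.integer(rowSums(m) - diag(m))
  )
  shifts <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(shifts) <- c("origin", "destination", "n")
  shifts <- dplyr::filter(shifts, .data$origin != .data$destination)
  list(
    unchanged_pct = 100 * unchanged,
    changed_pct = 100 * (1 - unchanged),
    total = total,
    by_origin = by_origin,
    shifts = dplyr::mutate(shifts, n = as.integer(.data$n))
  )
}
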