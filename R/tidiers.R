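#' @rdname nutrientcolor-tidiers
#' @param x A result object.
#' @param ... Unused.
#' @name nutrientcolor-tidiers
#' @title Broom-style tidiers for result objects
#' @description `tidy()` returns a one-row-per-term tibble and `glance()`
#'   a one-row model summary, following broom conventions.
NULL

#' @rdname nutrientcolor-tidiers
#' @exportS3Method generics::tidy
tidy.nc_rao <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, lambda = x$lambda,
                 p.value = x$p_value, n = x$n, n.rep = x$n_rep)
}

#' @rdname nutrientcolor-tidiers
#' @exportS3Method generics::tidy
tidy.nc_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    statistic = c(x$pseudo_F, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' @rdname nutrientcolor-tidiers
#' @exportS3Method generics::glance
glance.nc_permanova <- function(x, ...) {
  tibble::tibble(pseudo.F = x$pseudo_F, r.squared = x$r_squared,
                 p.value = x$p_value, n = x$n, n.perm = x$n_perm)
}

#' @rdname nutrientcolor-tidiers
#' @exportS3Method generics::tidy
tidy.nc_nmds <- function(x, ...) x$points

#' @rdname nutrientcolor-tidiers
#' @exportS3Method generics::glance
glance.nc_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, converged = x$converged,
                 k = x$k, n = nrow(x$points), n.restarts = x$n_restarts)
}

#' @rdname nutrientcolor-tidiers
#' @exportS3Method generics::tidy
tidy.nc_transition <- function(x, ...) {
  out <- tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal")
  names(out) <- c("origin", "destination", "n")
  dplyr::mutate(out, n = as.integer(.data$n))
}

#' @rdname nutrientcolor-tidiers
#' @exportS3Method generics::tidy
tidy.nc_vector_summary <- function(x, ...) x$anova

#' @rdname nutrientcolor-tidiers
#' @exportS3Method generics::glance
glance.nc_vector_summary <- function(x, ...) {
  md <- x$mean_direction
  tibble::tibble(
    mean.angle = md$mean_angle, ci.low = md$ci_low, ci.high = md$ci_high,
    resultant.length = md$resultant_length,
    rao.statistic = x$rao$statistic, rao.p.value = x$rao$p_value,
    n = md$n
  )
}
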