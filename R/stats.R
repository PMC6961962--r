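#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H comparing a numeric response across
#' groups. H is computed from mid-ranks as
#' H = (12 / (N(N+1))) * sum n_i Rbar_i^2 - 3(N+1), divided by the tie
#' correction 1 - sum(t^3 - t) / (N^3 - N). The p-value uses the
#' chi-squared approximation with df = groups - 1 by default; a seeded
#' permutation p-value (random reassignments of group labels) is available
#' for small samples. The statistic is invariant to any strictly monotone
#' transform of the pooled values.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @param p_method `"chisq"` or `"permutation"`.
#' @param n_perm Permutation count when `p_method = "permutation"`.
#' @param seed Integer seed for the permutation p-value.
#' @return A one-row tibble: `test`, `statistic` (H), `df`, `p_value`, `n`,
#'   `n_groups`.
#' @export
kruskal_wallis <- function(values, groups, p_method = c("chisq",
                                                        "permutation"),
                           n_perm = 9999, seed = 1) {
  p_method <- match.arg(p_method)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) abort("Need at least 2 groups.")
  if (length(values) < 5) abort("Need a total sample size of at least 5.")
  H <- .kw_statistic(values, groups)
  df <- nlevels(groups) - 1
  if (p_method == "chisq") {
    p <- pchisq(H, df, lower.tail = FALSE)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    Hs <- replicate(n_perm, .kw_statistic(values, sample(groups)))
    p <- (1 + sum(Hs >= H - 1e-12)) / (n_perm + 1)
  }
  tibble::tibble(test = "kruskal_wallis", statistic = H, df = df,
                 p_value = p, n = length(values),
                 n_groups = nlevels(groups))
}

.kw_statistic <- function(values, groups) {
  r <- rank(values)
  N <- length(r)
  Rbar <- tapply(r, groups, mean)
  n_i <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(n_i * Rbar^2) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)  # all values identical
  H / C
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise mean-rank comparisons following a Kruskal-Wallis test. For each
#' pair of groups, z = (Rbar_k - Rbar_l) / SE with the tie-corrected
#' standard error SE = sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_k + 1/n_l)). Two-sided p-values are adjusted over all reported
#' pairs (Bonferroni by default, capped at 1). With exactly two groups,
#' z^2 equals the tie-corrected Kruskal-Wallis H.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param adjustment Multiplicity adjustment passed to [stats::p.adjust()].
#' @return A tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, adjustment = "bonferroni") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) abort("Need at least 2 non-empty groups.")
  r <- rank(values)
  N <- length(r)
  Rbar <- tapply(r, groups, mean)
  n_i <- tabulate(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    i1 <- match(g1, levels(groups)); i2 <- match(g2, levels(groups))
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / n_i[i1] + 1 / n_i[i2]))
    z <- (Rbar[[g1]] - Rbar[[g2]]) / se
    tibble::tibble(group1 = g1, group2 = g2, z = z,
                   p_value = 2 * pnorm(-abs(z)))
  })
  dplyr::mutate(res,
                p_adjusted = p.adjust(.data$p_value, method = adjustment))
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise significance level.
#' @param n_tests Number of tests in the family.
#' @return `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests = 14) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  alpha / n_tests
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) between site rows, after an
#' optional square-root transformation of the values (the default,
#' matching common practice for biomass data). Values lie in [0, 1], the
#' matrix is symmetric with a zero diagonal, and the measure is a
#' semi-metric (the triangle inequality can fail). A pair of all-zero
#' sites has an undefined dissimilarity, returned as `NA` and counted in
#' the `n_undefined` attribute.
#'
#' @param matrix A community tibble from [community_matrix()] (site_id
#'   column plus taxa) or a plain numeric matrix with sites as rows.
#' @param transform `"sqrt"` or `"none"`.
#' @return A symmetric numeric matrix with site ids as dimnames, class
#'   `nc_dist`.
#' @export
bray_curtis <- function(matrix, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  if (is.data.frame(matrix)) {
    ids <- if ("site_id" %in% names(matrix)) matrix$site_id
           else as.character(seq_len(nrow(matrix)))
    x <- .cm_values(matrix)
  } else {
    x <- as.matrix(matrix)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  if (any(x < 0)) abort("Community values must be non-negative.")
  if (all(x == 0)) abort("All-zero community matrix.")
  if (transform == "sqrt") x <- sqrt(x)
  n <- nrow(x)
  d <- base::matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <-
        if (denom > 0) sum(abs(x[i, ] - x[j, ])) / denom else NA_real_
    }
  }
  structure(d, class = c("nc_dist", "matrix"),
            n_undefined = sum(is.na(d[upper.tri(d)])))
}

#' Permutational multivariate analysis of variance
#'
#' Single-factor PERMANOVA on a dissimilarity matrix. The total sum of
#' squares is sum of squared dissimilarities over all pairs divided by n;
#' the within-group term uses within-group pairs divided by group size;
#' pseudo-F = (SS_between / (a - 1)) / (SS_within / (n - a)). The p-value
#' comes from seeded free permutations of the group labels:
#' p = (1 + #{permuted F >= observed F}) / (n_perm + 1).
#'
#' @param dist A dissimilarity matrix ([bray_curtis()] output, a `dist`,
#'   or a symmetric matrix).
#' @param labels Group labels, one per site.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return An object of class `nc_permanova`: list with `pseudo_F`,
#'   `df_between`, `df_within`, `r_squared`, `p_value`, `n_perm`, `seed`,
#'   `n`.
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = 1) {
  d <- if (inherits(dist, "dist")) as.matrix(dist) else unclass(dist)
  labels <- droplevels(factor(labels))
  n <- nrow(d)
  stopifnot(length(labels) == n)
  if (nlevels(labels) < 2) abort("Need at least 2 groups.")
  if (any(table(labels) < 2)) abort("Every group needs at least 2 sites.")
  if (any(is.na(d))) abort("Dissimilarity matrix contains undefined pairs.")
  d2 <- d^2
  a <- nlevels(labels)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_stat <- function(g) {
    ss_w <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) /
        length(idx)
    }
    ss_b <- ss_total - ss_w
    (ss_b / (a - 1)) / (ss_w / (n - a))
  }
  F_obs <- f_stat(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  F_perm <- replicate(n_perm, f_stat(labels[sample.int(n)]))
  r2 <- (F_obs * (a - 1)) / (F_obs * (a - 1) + (n - a))
  structure(
    list(pseudo_F = F_obs, df_between = a - 1, df_within = n - a,
         r_squared = r2,
         p_value = (1 + sum(F_perm >= F_obs - 1e-12)) / (n_perm + 1),
         n_perm = n_perm, seed = seed, n = n),
    class = "nc_permanova"
  )
}

#' @export
print.nc_permanova <- function(x, ...) {
  cat("PERMANOVA (single factor, free permutations)\n")
  cat(sprintf("  pseudo-F = %.3f, df = %d/%d, R2 = %.3f\n",
              x$pseudo_F, x$df_between, x$df_within, x$r_squared))
  cat(sprintf("  p = %.4g (%d permutations)\n", x$p_value, x$n_perm))
  invisible(x)
}

#' Non-metric multidimensional scaling
#'
#' Ordination minimising Kruskal stress-1 between the rank order of the
#' input dissimilarities and configuration distances. Each restart
#' alternates isotonic regression (monotone disparities in dissimilarity
#' order) with a Guttman-transform configuration update; a step-halving
#' line search guarantees the stress never increases within a restart.
#' The first start is the classical (metric) scaling solution; further
#' restarts are random. The best restart is returned.
#'
#' @param dist A dissimilarity matrix or `dist`.
#' @param k Target dimensionality.
#' @param n_restarts Number of starts (1 metric + `n_restarts - 1` random).
#' @param seed Integer seed for the random starts.
#' @param maxit Maximum iterations per restart.
#' @param tol Convergence: stress change below `tol` across a 10-iteration
#'   window.
#' @return An object of class `nc_nmds`: list with `points` (tibble:
#'   `site_id`, `dim1` ... `dimk`), `stress` (Kruskal stress-1),
#'   `converged`, `n_restarts`, `seed`, `stress_trace` (per-iteration
#'   stress of the winning restart).
#' @export
nmds <- function(dist, k = 2, n_restarts = 20, seed = 1, maxit = 200,
                 tol = 1e-6) {
  d <- if (inherits(dist, "dist")) as.matrix(dist) else unclass(dist)
  n <- nrow(d)
  if (n < k + 2) abort("Need at least k + 2 sites.")
  if (any(is.na(d))) abort("Dissimilarity matrix contains undefined pairs.")
  ids <- rownames(d) %||% as.character(seq_len(n))
  low <- which(lower.tri(d))
  delta <- d[low]
  ord <- order(delta)

  stress_of <- function(dc, dhat) sqrt(sum((dc - dhat)^2) / sum(dc^2))
  fit_disparities <- function(dc) {
    yf <- isoreg(x = seq_along(ord), y = dc[ord])$yf
    dhat <- numeric(length(dc))
    dhat[ord] <- yf
    dhat
  }
  run_restart <- function(X) {
    X <- scale(X, center = TRUE, scale = FALSE)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(maxit)) {
      dc <- as.matrix(stats::dist(X))[low]
      dhat <- fit_disparities(dc)
      s <- stress_of(dc, dhat)
      # Guttman update using the disparities
      Dm <- base::matrix(0, n, n); Dm[low] <- dc; Dm <- Dm + t(Dm)
      Hm <- base::matrix(0, n, n); Hm[low] <- dhat; Hm <- Hm + t(Hm)
      B <- ifelse(Dm > 0, -Hm / pmax(Dm, 1e-12), 0)
      diag(B) <- -rowSums(B)
      X_new <- B %*% X / n
      # step-halving so stress is monotone non-increasing
      step <- 1
      repeat {
        Xc <- X + step * (X_new - X)
        dc2 <- as.matrix(stats::dist(Xc))[low]
        s2 <- stress_of(dc2, fit_disparities(dc2))
        if (s2 <= s + 1e-12 || step < 1e-4) break
        step <- step / 2
      }
      if (s2 <= s + 1e-12) { X <- Xc; s <- min(s, s2) }
      trace <- c(trace, s)
      if (it >= 10 && (trace[it - 9] - s) < tol) { converged <- TRUE; break }
      if (s < 1e-9) { converged <- TRUE; break }
    }
    list(X = X, stress = trace[length(trace)], trace = trace,
         converged = converged)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  starts <- vector("list", n_restarts)
  cm <- tryCatch(cmdscale(stats::as.dist(d), k = k),
                 error = function(e) NULL)
  starts[[1]] <- if (!is.null(cm) && ncol(cm) == k) cm
                 else base::matrix(rnorm(n * k), n, k)
  if (n_restarts > 1) {
    for (r in 2:n_restarts) {
      starts[[r]] <- base::matrix(rnorm(n * k), n, k)
    }
  }
  fits <- lapply(starts, run_restart)
  best <- fits[[which.min(vapply(fits, function(f) f$stress, 0))]]
  pts <- tibble::as_tibble(best$X, .name_repair = ~ paste0("dim",
                                                           seq_len(k)))
  pts <- dplyr::bind_cols(tibble::tibble(site_id = ids), pts)
  structure(
    list(points = pts, stress = best$stress, converged = best$converged,
         n_restarts = n_restarts, seed = seed,
         stress_trace = best$trace, k = k),
    class = "nc_nmds"
  )
}

#' @export
print.nc_nmds <- function(x, ...) {
  cat(sprintf(
    "NMDS ordination: %d sites in %d dimensions\n  stress-1 = %.4f (%s, best of %d restarts)\n",
    nrow(x$points), x$k, x$stress,
    if (x$converged) "converged" else "not converged", x$n_restarts))
  invisible(x)
}
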