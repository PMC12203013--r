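# Species-richness rarefaction and extrapolation (Hill order q = 0).
#
# Interpolation is the exact combinatorial expectation of richness in a
# random subsample; extrapolation uses the Chao1 (abundance) / Chao2
# (incidence) unseen-species estimate. Binomial coefficients are evaluated
# through lchoose() so large samples do not overflow; C(a, b) = 0 for a < b.

# ratio C(a, m) / C(n, m) in log space, 0 when a < m
choose_ratio <- function(a, m, n) {
  out <- numeric(length(a))
  ok <- a >= m
  out[ok] <- exp(lchoose(a[ok], m) - lchoose(n, m))
  out
}

as_abundance <- function(x) {
  x <- x[!is.na(x) & x > 0]
  if (length(x) == 0) abort("abundance vector has no positive entries")
  if (any(x != floor(x))) abort("abundances must be integer counts")
  x
}

#' Rarefied (interpolated) species richness, abundance data
#'
#' Expected number of species in a random subsample of m of the n observed
#' individuals: S(m) = S_obs - sum_i C(n - x_i, m) / C(n, m).
#'
#' @param x Vector of per-taxon individual counts.
#' @param m Subsample size, 1 <= m <= n (extrapolation beyond n is
#'   [extrapolate_abundance()]'s job).
#' @return Expected richness.
#' @export
rarefy_abundance <- function(x, m) {
  x <- as_abundance(x)
  n <- sum(x)
  if (m < 1 || m > n) abort("m must satisfy 1 <= m <= n; use extrapolate_abundance() beyond n")
  length(x) - sum(choose_ratio(n - x, m, n))
}

#' Chao1 asymptotic species richness
#'
#' S_obs + ((n-1)/n) f1^2 / (2 f2) from the singleton/doubleton counts;
#' when there are no doubletons the bias-corrected form
#' S_obs + ((n-1)/n) f1 (f1 - 1) / 2 is used.
#'
#' @param x Vector of per-taxon individual counts.
#' @return Asymptotic richness estimate (>= observed richness).
#' @export
chao1 <- function(x) {
  x <- as_abundance(x)
  n <- sum(x)
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(s_obs)
  if (f2 > 0) s_obs + (n - 1) / n * f1^2 / (2 * f2)
  else s_obs + (n - 1) / n * f1 * (f1 - 1) / 2
}

#' Extrapolated species richness, abundance data
#'
#' Richness expected after m_star additional individuals:
#' S_obs + f0_hat (1 - (1 - f1 / (n f0_hat + f1))^m_star), with
#' f0_hat = Chao1 - S_obs. With no singletons the curve has flattened and
#' S_obs is returned.
#'
#' @param x Vector of per-taxon individual counts.
#' @param m_star Additional individuals beyond the sample (>= 0).
#' @return Expected richness at n + m_star.
#' @export
extrapolate_abundance <- function(x, m_star) {
  if (any(m_star < 0)) abort("m_star must be >= 0")
  x <- as_abundance(x)
  n <- sum(x)
  s_obs <- length(x)
  f1 <- sum(x == 1)
  if (f1 == 0) return(rep(s_obs, length(m_star)))
  f0 <- chao1(x) - s_obs
  s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^m_star)
}

as_incidence <- function(y, n_units) {
  y <- y[!is.na(y) & y > 0]
  if (length(y) == 0) abort("incidence vector has no positive entries")
  if (any(y != floor(y))) abort("incidences must be integer counts")
  if (any(y > n_units)) abort("incidence cannot exceed the number of sampling units")
  y
}

#' Rarefied species richness, incidence data
#'
#' Sampling unit is the pellet: S(t) = S_obs - sum_i C(T - Y_i, t)/C(T, t)
#' where Y_i is the number of units containing taxon i and T the units
#' examined.
#'
#' @param y Vector of per-taxon incidence counts.
#' @param t_units Subsample of units, 1 <= t <= T.
#' @param n_units Total sampling units T.
#' @return Expected richness.
#' @export
rarefy_incidence <- function(y, t_units, n_units) {
  y <- as_incidence(y, n_units)
  if (t_units < 1 || t_units > n_units) {
    abort("t_units must satisfy 1 <= t <= T; use extrapolate_incidence() beyond T")
  }
  length(y) - sum(choose_ratio(n_units - y, t_units, n_units))
}

#' Chao2 asymptotic species richness (incidence data)
#'
#' S_obs + ((T-1)/T) Q1^2 / (2 Q2) from the unique/duplicate counts, with
#' the bias-corrected analogue when Q2 = 0.
#'
#' @inheritParams rarefy_incidence
#' @return Asymptotic richness estimate.
#' @export
chao2 <- function(y, n_units) {
  y <- as_incidence(y, n_units)
  s_obs <- length(y)
  q1 <- sum(y == 1)
  q2 <- sum(y == 2)
  if (q1 == 0) return(s_obs)
  if (q2 > 0) s_obs + (n_units - 1) / n_units * q1^2 / (2 * q2)
  else s_obs + (n_units - 1) / n_units * q1 * (q1 - 1) / 2
}

#' Extrapolated species richness, incidence data
#'
#' Mirrors the abundance form with Q1 and T:
#' S_obs + q0_hat (1 - (1 - Q1 / (T q0_hat + Q1))^t_star).
#'
#' @inheritParams rarefy_incidence
#' @param t_star Additional sampling units beyond T (>= 0).
#' @return Expected richness at T + t_star.
#' @export
extrapolate_incidence <- function(y, t_star, n_units) {
  if (any(t_star < 0)) abort("t_star must be >= 0")
  y <- as_incidence(y, n_units)
  s_obs <- length(y)
  q1 <- sum(y == 1)
  if (q1 == 0) return(rep(s_obs, length(t_star)))
  q0 <- chao2(y, n_units) - s_obs
  s_obs + q0 * (1 - (1 - q1 / (n_units * q0 + q1))^t_star)
}

#' Rarefaction/extrapolation curve for one site
#'
#' Builds the interpolated curve up to the observed sample size and the
#' extrapolated curve beyond it (default out to 200, the usual plotting
#' range for these pellet studies), in either abundance mode (sample size =
#' individuals, asymptote = Chao1) or incidence mode (sample size =
#' pellets, asymptote = Chao2). Restricted to mammal taxa by default, the
#' community these curves are typically drawn for.
#'
#' @param asm Single-site assemblage tibble from [site_assemblage()].
#' @param mode `"incidence"` (default) or `"abundance"`.
#' @param size_max Largest sample size on the grid (default 200).
#' @param groups Prey groups to include (default `"mammal"`).
#' @return A `rarefaction_curve` object; see [tidy.rarefaction_curve()],
#'   [glance.rarefaction_curve()] and [autoplot.rarefaction_curve()].
#' @export
rarefaction_curve <- function(asm, mode = c("incidence", "abundance"),
                              size_max = 200, groups = "mammal") {
  mode <- match.arg(mode)
  sub <- dplyr::filter(asm, .data$group %in% groups)
  if (nrow(sub) == 0) abort("no taxa in the requested groups")
  if (mode == "abundance") {
    x <- sub$abundance_mni
    n <- sum(x)
    asym <- chao1(x)
    sizes <- seq_len(min(n, size_max))
    est <- vapply(sizes, function(m) rarefy_abundance(x, m), numeric(1))
    if (size_max > n) {
      extra <- (n + 1):size_max
      est <- c(est, extrapolate_abundance(x, extra - n))
      sizes <- c(sizes, extra)
    }
    observed_size <- n
  } else {
    y <- sub$incidence
    t_tot <- sub$n_pellets[1]
    asym <- chao2(y, t_tot)
    sizes <- seq_len(min(t_tot, size_max))
    est <- vapply(sizes, function(t) rarefy_incidence(y, t, t_tot), numeric(1))
    if (size_max > t_tot) {
      extra <- (t_tot + 1):size_max
      est <- c(est, extrapolate_incidence(y, extra - t_tot, t_tot))
      sizes <- c(sizes, extra)
    }
    observed_size <- t_tot
  }
  structure(
    list(
      site_id = sub$site_id[1], mode = mode,
      observed_richness = nrow(sub), observed_size = observed_size,
      asymptote = asym,
      curve = tibble::tibble(size = sizes, estimate = est,
                             is_extrapolated = sizes > observed_size)
    ),
    class = "rarefaction_curve"
  )
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("Rarefaction curve (", x$mode, "), site ", x$site_id, "\n", sep = "")
  cat("  observed richness", x$observed_richness, "at size",
      x$observed_size, "\n")
  cat("  Chao asymptote", format(x$asymptote, digits = 4), "\n")
  invisible(x)
}
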