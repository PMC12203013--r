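# Pairwise Fisher exact tests of composition.
#
# Each pair of sites is compared as a 2 x k contingency table (rows =
# sites, columns = mammal taxa or habitat categories). The exact p-value
# conditions on both margins: every admissible table is enumerated, its
# probability under the multivariate hypergeometric computed, and
# probabilities no larger than the observed table's (within a small
# relative tie tolerance) are summed. A Monte-Carlo route samples tables
# with the same margins for cases where enumeration would be too large.

FISHER_TIE_TOL <- 1e-7

# all first-row vectors a with 0 <= a_j <= col_totals[j] and sum = r1
enumerate_first_rows <- function(col_totals, r1, max_tables = 1e6) {
  k <- length(col_totals)
  suffix_max <- rev(cumsum(rev(col_totals)))
  rows <- list(integer(0))
  sums <- 0L
  for (j in seq_len(k)) {
    rest <- if (j < k) suffix_max[j + 1] else 0L
    new_rows <- list()
    new_sums <- integer(0)
    for (i in seq_along(rows)) {
      lo <- max(0L, r1 - sums[i] - rest)
      hi <- min(col_totals[j], r1 - sums[i])
      if (hi < lo) next
      for (a in lo:hi) {
        new_rows[[length(new_rows) + 1L]] <- c(rows[[i]], a)
        new_sums <- c(new_sums, sums[i] + a)
      }
      if (length(new_rows) > max_tables) {
        abort(paste0("exact enumeration exceeds ", max_tables,
                     " tables; use method = \"montecarlo\""),
              class = "pelletdiet_enumeration_error")
      }
    }
    rows <- new_rows
    sums <- new_sums
  }
  do.call(rbind, rows)
}

# log multivariate-hypergeometric probability of first row(s) a given margins
log_table_prob <- function(a, col_totals, n, r1) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  tot <- matrix(col_totals, nrow(a), length(col_totals), byrow = TRUE)
  rowSums(matrix(lchoose(tot, a), nrow = nrow(a))) - lchoose(n, r1)
}

#' Fisher's exact test for a 2 x k contingency table
#'
#' @param table A 2-row matrix of non-negative integer counts.
#' @param method `"auto"` (exact unless the enumeration would exceed
#'   `max_tables`), `"exact"`, or `"montecarlo"`.
#' @param seed Seed for the Monte-Carlo route.
#' @param n_mc Monte-Carlo replicates (default 1e4); the p-value is
#'   (1 + #extreme) / (1 + n_mc), never exactly 0.
#' @param max_tables Enumeration budget for the exact route.
#' @return A list with `p_value`, `method` (`exact`/`montecarlo`), and
#'   `n_tables` (tables enumerated) or `n_mc`.
#' @export
fisher_exact <- function(table, method = c("auto", "exact", "montecarlo"),
                         seed = 1, n_mc = 1e4, max_tables = 1e6) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (nrow(table) != 2 || ncol(table) < 2) {
    abort("fisher_exact() expects a 2 x k table with k >= 2")
  }
  if (any(table < 0) || any(table != floor(table))) {
    abort("table cells must be non-negative integers")
  }
  n <- sum(table)
  if (n < 1) abort("table must contain at least one count")
  col_totals <- colSums(table)
  r1 <- sum(table[1, ])
  lp_obs <- log_table_prob(table[1, ], col_totals, n, r1)
  cutoff <- lp_obs + log1p(FISHER_TIE_TOL)
  if (method == "auto") {
    approx_size <- prod(pmin(col_totals, r1) + 1)
    method <- if (approx_size <= max_tables) "exact" else "montecarlo"
  }
  if (method == "exact") {
    rows <- enumerate_first_rows(col_totals, r1, max_tables)
    lp <- log_table_prob(rows, col_totals, n, r1)
    p <- sum(exp(lp[lp <= cutoff]))
    list(p_value = min(p, 1), method = "exact", n_tables = nrow(rows))
  } else {
    lp_mc <- with_local_seed(seed, {
      draws <- stats::r2dtable(n_mc, c(r1, n - r1), col_totals)
      vapply(draws, function(tb) log_table_prob(tb[1, ], col_totals, n, r1),
             numeric(1))
    })
    p <- (1 + sum(lp_mc <= cutoff)) / (1 + n_mc)
    list(p_value = p, method = "montecarlo", n_mc = n_mc)
  }
}

#' Pairwise exact tests between all site pairs of a composition matrix
#'
#' One Fisher exact test per unordered pair of rows (sites); Bonferroni
#' adjustment multiplies each raw p by the number of pairs actually tested
#' in the family (capped at 1).
#'
#' @param mat Sites x categories matrix of non-negative integer counts
#'   (e.g. from [mammal_matrix()] or [habitat_matrix()]).
#' @param alpha Family significance level used for the `significant` flag.
#' @param method,seed,n_mc,max_tables Passed to [fisher_exact()].
#' @return A tibble `site_a,site_b,p_raw,p_adjusted,method,n_comparisons,
#'   significant`.
#' @export
pairwise_tests <- function(mat, alpha = 0.05,
                           method = c("auto", "exact", "montecarlo"),
                           seed = 1, n_mc = 1e4, max_tables = 1e6) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) abort("need at least two sites to compare")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("site", seq_len(nrow(mat)))
  pairs <- utils::combn(rownames(mat), 2)
  n_comp <- ncol(pairs)
  res <- purrr::map(seq_len(n_comp), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tab <- mat[c(a, b), , drop = FALSE]
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      # both sites hold the same single category: compositions identical
      ft <- list(p_value = 1, method = "exact")
    } else {
      ft <- fisher_exact(tab, method = method,
                         seed = site_seed(seed, paste(a, b)), n_mc = n_mc,
                         max_tables = max_tables)
    }
    tibble::tibble(site_a = a, site_b = b, p_raw = ft$p_value,
                   method = ft$method)
  })
  dplyr::bind_rows(res) %>%
    dplyr::mutate(
      p_adjusted = pmin(1, .data$p_raw * n_comp),
      n_comparisons = n_comp,
      significant = .data$p_adjusted < alpha,
      .after = "p_raw"
    )
}

#' Mammal community composition matrix
#'
#' Rows are sites, columns mammal taxa, cells MNI. Non-mammal taxa are
#' dropped first; sites left with no mammal individuals are excluded with a
#' warning.
#'
#' @param asm Assemblage tibble covering the sites to compare.
#' @return An integer matrix with site row names.
#' @export
mammal_matrix <- function(asm) {
  mam <- dplyr::filter(asm, .data$group == "mammal")
  all_sites <- unique(asm$site_id)
  kept <- unique(mam$site_id)
  dropped <- setdiff(all_sites, kept)
  if (length(dropped) > 0) {
    warn(paste0("excluding site(s) with no mammal individuals: ",
                paste(dropped, collapse = ", ")))
  }
  wide <- mam %>%
    dplyr::select(dplyr::all_of(c("site_id", "taxon", "abundance_mni"))) %>%
    tidyr::pivot_wider(names_from = "taxon", values_from = "abundance_mni",
                       values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$site_id
  m
}

#' Discretised habitat composition matrix
#'
#' Fisher's exact test needs integer counts, so continuous habitat areas
#' are binned to whole units of `resolution_km2` (default 1 km^2) before
#' testing. The resolution is recorded as an attribute so results can state
#' it.
#'
#' @param habitat Habitat areas tibble (`site_id,category,area_km2`).
#' @param resolution_km2 Discretisation unit.
#' @return An integer matrix sites x categories with attribute
#'   `resolution_km2`.
#' @export
habitat_matrix <- function(habitat, resolution_km2 = 1) {
  if (resolution_km2 <= 0) abort("resolution_km2 must be positive")
  wide <- habitat %>%
    dplyr::mutate(units = as.integer(round(.data$area_km2 /
                                             .env$resolution_km2))) %>%
    dplyr::select(dplyr::all_of(c("site_id", "category", "units"))) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "units",
                       values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$site_id
  attr(m, "resolution_km2") <- resolution_km2
  m
}
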