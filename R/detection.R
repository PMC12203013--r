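# Binomial detection-effort model. The trial is the pellet: p is the
# probability a single pellet contains the target taxon, estimated as the
# taxon's pellet incidence over pellets examined. The chance of at least one
# detection in n pellets is then 1 - (1 - p)^n, and the minimum effort for a
# confident single detection is the smallest n exceeding the chosen
# confidence (strictly: pn > c).

#' Per-pellet presence probability of a taxon
#'
#' p_hat = incidence / n_pellets from a site assemblage. A taxon absent
#' from the site but present in `taxon_pool` gets p_hat = 0; a taxon in
#' neither is an error (guards against typos in species names).
#'
#' @param asm Single-site assemblage tibble.
#' @param taxon Target taxon name.
#' @param taxon_pool Optional character vector of taxa known to the study;
#'   defaults to the taxa in `asm`.
#' @return p_hat in [0, 1].
#' @export
estimate_presence_rate <- function(asm, taxon, taxon_pool = NULL) {
  pool <- unique(c(asm$taxon, taxon_pool))
  if (!taxon %in% pool) {
    abort(paste0("taxon not in the study's taxon list: ", taxon))
  }
  row <- dplyr::filter(asm, .data$taxon == .env$taxon)
  if (nrow(row) == 0) return(0)
  row$incidence[1] / row$n_pellets[1]
}

#' Probability of at least one detection in n pellets
#'
#' @param p_hat Per-pellet presence probability in [0, 1].
#' @param n Non-negative integer pellet count (vectorised).
#' @return 1 - (1 - p_hat)^n.
#' @export
prob_detect <- function(p_hat, n) {
  if (any(p_hat < 0) || any(p_hat > 1)) abort("p_hat must be in [0, 1]")
  if (any(n < 0) || any(n != floor(n))) {
    abort("n must be a non-negative integer")
  }
  1 - (1 - p_hat)^n
}

#' Minimum pellets for a confident single detection
#'
#' Smallest integer n with 1 - (1 - p)^n strictly greater than the
#' confidence level (the "> c" convention, e.g. pn > 0.99).
#'
#' @param p_hat Per-pellet presence probability in (0, 1].
#' @param confidence Required detection probability in (0, 1).
#' @return Integer pellet count.
#' @export
min_pellets <- function(p_hat, confidence = 0.99) {
  if (confidence <= 0 || confidence >= 1) {
    abort("confidence must be in (0, 1)")
  }
  if (p_hat <= 0 || p_hat > 1) {
    abort("p_hat must be in (0, 1]: the confidence is unreachable at p_hat = 0")
  }
  if (p_hat == 1) return(1L)
  n <- ceiling(log1p(-confidence) / log1p(-p_hat))
  # guard the strict inequality at the boundary
  while (prob_detect(p_hat, n) <= confidence) n <- n + 1
  while (n > 1 && prob_detect(p_hat, n - 1) > confidence) n <- n - 1
  as.integer(n)
}

#' Detection-probability curve for a target taxon at one site
#'
#' Evaluates P(>= 1 detection) over pellet efforts 0..n_max and the minimum
#' efforts n* at each requested confidence level. When the taxon was never
#' found (p_hat = 0) the curve is flat zero and n* is `NA`.
#'
#' @param asm Single-site assemblage tibble.
#' @param taxon Target taxon.
#' @param n_max Largest pellet effort on the grid (default 200, matching the
#'   usual extrapolation range for these curves).
#' @param confidence Confidence levels for n* (default 0.95 and 0.99).
#' @param taxon_pool Passed to [estimate_presence_rate()].
#' @return A `detection_curve` object; see [tidy.detection_curve()],
#'   [glance.detection_curve()] and [autoplot.detection_curve()].
#' @export
detection_curve <- function(asm, taxon, n_max = 200,
                            confidence = c(0.95, 0.99), taxon_pool = NULL) {
  if (n_max < 1) abort("n_max must be >= 1")
  p_hat <- estimate_presence_rate(asm, taxon, taxon_pool)
  grid <- 0:n_max
  n_star <- vapply(confidence, function(c) {
    if (p_hat > 0) min_pellets(p_hat, c) else NA_integer_
  }, integer(1))
  structure(
    list(
      site_id = asm$site_id[1], taxon = taxon, p_hat = p_hat,
      curve = tibble::tibble(n = grid, prob = prob_detect(p_hat, grid)),
      n_star = tibble::tibble(confidence = confidence, n_star = n_star)
    ),
    class = "detection_curve"
  )
}

#' @export
print.detection_curve <- function(x, ...) {
  cat("Detection curve:", x$taxon, "at", x$site_id, "\n")
  cat("  per-pellet presence p_hat =", format(x$p_hat, digits = 4), "\n")
  for (i in seq_len(nrow(x$n_star))) {
    cat(sprintf("  n* (p_n > %.2f) = %s pellets\n",
                x$n_star$confidence[i],
                ifelse(is.na(x$n_star$n_star[i]), "unreachable",
                       x$n_star$n_star[i])))
  }
  invisible(x)
}
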