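#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a detection curve
#'
#' @param x A [detection_curve()] object.
#' @param ... Unused.
#' @return A tibble `site_id,taxon,n,prob`, one row per pellet effort.
#' @method tidy detection_curve
#' @export
tidy.detection_curve <- function(x, ...) {
  dplyr::mutate(x$curve, site_id = x$site_id, taxon = x$taxon, .before = 1)
}

#' One-row summary of a detection curve
#'
#' @inheritParams tidy.detection_curve
#' @return A tibble with `p_hat` and one `n_star_*` column per confidence
#'   level.
#' @method glance detection_curve
#' @export
glance.detection_curve <- function(x, ...) {
  ns <- stats::setNames(
    as.list(x$n_star$n_star),
    paste0("n_star_", sub("^0\\.", "", format(x$n_star$confidence)))
  )
  tibble::as_tibble(c(list(site_id = x$site_id, taxon = x$taxon,
                           p_hat = x$p_hat), ns))
}

#' Tidy a rarefaction curve
#'
#' @param x A [rarefaction_curve()] object.
#' @param ... Unused.
#' @return A tibble `site_id,mode,size,estimate,is_extrapolated`.
#' @method tidy rarefaction_curve
#' @export
tidy.rarefaction_curve <- function(x, ...) {
  dplyr::mutate(x$curve, site_id = x$site_id, mode = x$mode, .before = 1)
}

#' One-row summary of a rarefaction curve
#'
#' @inheritParams tidy.rarefaction_curve
#' @return A tibble with observed richness/size and the Chao asymptote.
#' @method glance rarefaction_curve
#' @export
glance.rarefaction_curve <- function(x, ...) {
  tibble::tibble(site_id = x$site_id, mode = x$mode,
                 observed_richness = x$observed_richness,
                 observed_size = x$observed_size,
                 asymptote = x$asymptote)
}
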