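# Habitat composition within the assumed hunting range, and likelihood
# classification of sites against a habitat distribution model. The model's
# zones: category two, "species or species habitat is likely to occur"
# (high); category one, "species or species habitat may occur" (medium);
# outside both, low.

#' Habitat-category proportions of the hunting range
#'
#' Converts per-category areas (pre-clipped to the assumed hunting-radius
#' circle upstream) into proportions of each site's total mapped area.
#'
#' @param habitat Habitat areas tibble (`site_id,category,area_km2`).
#' @return A tibble `site_id,category,proportion,total_area_km2`; the
#'   proportions of each site sum to 1.
#' @export
habitat_proportions <- function(habitat) {
  required_cols(habitat, c("site_id", "category", "area_km2"),
                "habitat table")
  zero <- habitat %>%
    dplyr::summarise(total = sum(.data$area_km2), .by = "site_id") %>%
    dplyr::filter(.data$total <= 0)
  if (nrow(zero) > 0) {
    abort(paste0("all-zero habitat areas at site(s): ",
                 paste(zero$site_id, collapse = ", ")))
  }
  habitat %>%
    dplyr::mutate(
      total_area_km2 = sum(.data$area_km2),
      proportion = .data$area_km2 / .data$total_area_km2,
      .by = "site_id"
    ) %>%
    dplyr::select(dplyr::all_of(c("site_id", "category", "proportion",
                                  "total_area_km2")))
}

#' Likelihood class from habitat-model membership flags
#'
#' Category two ("likely to occur") maps to high regardless of category
#' one; category one alone to medium; outside both to low. Historical
#' records do not enter the rule — they are study metadata, not part of the
#' classification.
#'
#' @param in_category_two,in_category_one Logical flags (vectorised):
#'   whether the site falls in the model's category-two / category-one
#'   zone.
#' @return A character vector in `high`/`medium`/`low`.
#' @export
classify_likelihood <- function(in_category_two, in_category_one) {
  if (any(is.na(in_category_two)) || any(is.na(in_category_one))) {
    abort("likelihood flags must be TRUE/FALSE, not NA")
  }
  dplyr::case_when(
    in_category_two ~ "high",
    in_category_one ~ "medium",
    .default = "low"
  )
}
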