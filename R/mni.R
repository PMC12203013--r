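# MNI: the smallest number of individuals consistent with the recovered
# paired elements. One left and two right dentaries of a mammal imply two
# individuals; one beak and two skulls of a bird likewise. Juvenile and
# adult material is pooled per taxon upstream of this module.

#' Minimum number of individuals from paired element counts
#'
#' The MNI rule: the larger of the two paired-element counts. For mammals
#' the pair is left/right dentaries, for birds beaks/skulls; the arithmetic
#' is identical, so [pellet_mni_mammal()] and [pellet_mni_bird()] are thin
#' named wrappers kept for clarity at call sites.
#'
#' @param a,b Non-negative integer counts of the two paired elements
#'   (vectorised).
#' @return Integer MNI, `pmax(a, b)`.
#' @export
pellet_mni <- function(a, b) {
  if (any(is.na(a)) || any(is.na(b)) || any(a < 0) || any(b < 0)) {
    abort("element counts must be non-negative")
  }
  as.integer(pmax(a, b))
}

#' @rdname pellet_mni
#' @param left_dentaries,right_dentaries Dentary counts.
#' @export
pellet_mni_mammal <- function(left_dentaries, right_dentaries) {
  pellet_mni(left_dentaries, right_dentaries)
}

#' @rdname pellet_mni
#' @param beaks,skulls Beak and skull counts.
#' @export
pellet_mni_bird <- function(beaks, skulls) {
  pellet_mni(beaks, skulls)
}

# per-pellet, per-taxon MNI from long element records
pellet_taxon_mni <- function(records) {
  records %>%
    tidyr::pivot_wider(
      id_cols = c("site_id", "pellet_id", "taxon", "group"),
      names_from = "element", values_from = "count",
      values_fn = sum, values_fill = 0L
    ) %>%
    dplyr::mutate(
      mni = pellet_mni(
        do.call(pmax, c(dplyr::pick(dplyr::any_of(c("left_dentary", "beak"))),
                        0L)),
        do.call(pmax, c(dplyr::pick(dplyr::any_of(c("right_dentary", "skull"))),
                        0L))
      )
    ) %>%
    dplyr::select(dplyr::all_of(c("site_id", "pellet_id", "taxon", "group",
                                  "mni")))
}

#' Aggregate one site's pellet records into a site assemblage
#'
#' Per-taxon MNI is computed within each pellet (max of the paired-element
#' counts), then summed over pellets into the site abundance; incidence is
#' the number of pellets in which the taxon's MNI is at least 1. Taxa whose
#' elements never yield MNI >= 1 are dropped.
#'
#' @param records Pellet records for a single site.
#' @return A tibble `site_id,taxon,group,abundance_mni,incidence,n_pellets`.
#' @export
site_assemblage <- function(records) {
  records <- check_pellet_records(records)
  if (dplyr::n_distinct(records$site_id) > 1) {
    abort("site_assemblage() expects records from a single site; use assemblage() for a whole study")
  }
  n_pellets <- dplyr::n_distinct(records$pellet_id)
  pellet_taxon_mni(records) %>%
    dplyr::filter(.data$mni >= 1) %>%
    dplyr::summarise(
      abundance_mni = sum(.data$mni),
      incidence = dplyr::n(),
      .by = c("site_id", "taxon", "group")
    ) %>%
    dplyr::mutate(n_pellets = n_pellets) %>%
    dplyr::arrange(dplyr::desc(.data$abundance_mni), .data$taxon)
}

#' Site assemblages for a whole study
#'
#' @param records Pellet records covering one or more sites.
#' @return Row-bound [site_assemblage()] tibbles, one block per site.
#' @export
assemblage <- function(records) {
  records <- check_pellet_records(records)
  records %>%
    dplyr::group_split(.data$site_id) %>%
    purrr::map(site_assemblage) %>%
    dplyr::bind_rows()
}
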