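# Diet ranking and community diversity.
#
# IRI = (N% + V%) x FO%: numerical share of individuals, biomass share
# (MNI x mean adult mass standing in for volume), and frequency of
# occurrence across pellets. Only taxa identifiable to species — mammals
# and birds — enter the IRI and the diversity indices; order-level
# herpetofauna and unidentified material are excluded.

iri_included <- function(asm) {
  dplyr::filter(asm, .data$group %in% c("mammal", "bird"))
}

#' Numerical percentage of each prey taxon
#'
#' 100 * n_i / sum(n_j) over the included (mammal and bird) taxa of one
#' site's assemblage.
#'
#' @param asm A single-site assemblage tibble from [site_assemblage()].
#' @return A tibble `taxon,n_pct`.
#' @export
numerical_pct <- function(asm) {
  inc <- iri_included(asm)
  if (nrow(inc) == 0 || sum(inc$abundance_mni) <= 0) {
    abort("no mammal/bird individuals in assemblage")
  }
  dplyr::transmute(inc, taxon = .data$taxon,
                   n_pct = 100 * .data$abundance_mni / sum(.data$abundance_mni))
}

#' Volumetric percentage of each prey taxon
#'
#' Biomass share 100 * n_i m_i / sum(n_j m_j), with m_i the taxon's mean
#' adult body mass. Any included taxon without a mass is refused by name.
#'
#' @param asm A single-site assemblage tibble.
#' @param masses Mass table (`taxon,mean_mass_g`), e.g. from
#'   [read_mass_table()] or [default_mass_table()].
#' @return A tibble `taxon,v_pct`.
#' @export
volumetric_pct <- function(asm, masses) {
  inc <- iri_included(asm)
  if (nrow(inc) == 0) abort("no mammal/bird individuals in assemblage")
  inc <- dplyr::left_join(inc, dplyr::select(masses, "taxon", "mean_mass_g"),
                          by = "taxon")
  missing <- inc$taxon[is.na(inc$mean_mass_g)]
  if (length(missing) > 0) {
    abort(paste0("no body mass for included taxon: ",
                 paste(missing, collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  dplyr::transmute(
    inc, taxon = .data$taxon,
    v_pct = 100 * .data$abundance_mni * .data$mean_mass_g /
      sum(.data$abundance_mni * .data$mean_mass_g)
  )
}

#' Frequency of occurrence percentage
#'
#' 100 * (pellets containing the taxon) / (pellets examined).
#'
#' @param asm A single-site assemblage tibble.
#' @return A tibble `taxon,fo_pct`.
#' @export
freq_occurrence_pct <- function(asm) {
  inc <- iri_included(asm)
  if (nrow(inc) == 0) abort("no mammal/bird individuals in assemblage")
  dplyr::transmute(inc, taxon = .data$taxon,
                   fo_pct = 100 * .data$incidence / .data$n_pellets)
}

#' Index of Relative Importance table for one site
#'
#' Combines the three components into iri_i = (N%_i + V%_i) * FO%_i and the
#' normalised share iri_pct_i = 100 * iri_i / sum(iri_j); taxa are ranked by
#' raw IRI, descending.
#'
#' @inheritParams volumetric_pct
#' @return A tibble
#'   `site_id,taxon,group,n_pct,v_pct,fo_pct,iri,iri_pct,rank`.
#' @export
iri_table <- function(asm, masses) {
  inc <- iri_included(asm)
  out <- inc %>%
    dplyr::select(dplyr::all_of(c("site_id", "taxon", "group"))) %>%
    dplyr::left_join(numerical_pct(asm), by = "taxon") %>%
    dplyr::left_join(volumetric_pct(asm, masses), by = "taxon") %>%
    dplyr::left_join(freq_occurrence_pct(asm), by = "taxon") %>%
    dplyr::mutate(iri = (.data$n_pct + .data$v_pct) * .data$fo_pct,
                  iri_pct = 100 * .data$iri / sum(.data$iri)) %>%
    dplyr::arrange(dplyr::desc(.data$iri))
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Shannon's diversity index (natural log)
#'
#' H = -sum(p_i log p_i) with p_i = n_i / sum(n_j); zero counts contribute
#' nothing (0 log 0 := 0).
#'
#' @param abundances Numeric vector of taxon abundances (MNI).
#' @return H in nats.
#' @export
shannon_h <- function(abundances) {
  abundances <- abundances[!is.na(abundances) & abundances > 0]
  if (length(abundances) == 0) abort("no positive abundances")
  p <- abundances / sum(abundances)
  -sum(p * log(p))
}

#' Pielou's evenness J = H / ln(S)
#'
#' Undefined for a single-taxon community (ln S = 0): returns `NA` with a
#' warning rather than forcing 0.
#'
#' @inheritParams shannon_h
#' @return Evenness in (0, 1], or `NA` when richness is 1.
#' @export
evenness <- function(abundances) {
  abundances <- abundances[!is.na(abundances) & abundances > 0]
  s <- length(abundances)
  if (s == 0) abort("no positive abundances")
  if (s < 2) {
    warn("evenness is undefined for a single-taxon community; returning NA")
    return(NA_real_)
  }
  shannon_h(abundances) / log(s)
}

#' Per-site diversity summaries
#'
#' Shannon H, Pielou evenness, richness and total individuals per site, for
#' the community of all identifiable species (mammals and birds) and for
#' mammals only — the two reporting scopes used for owl-pellet diet tables.
#'
#' @param asm Assemblage tibble (one or many sites) from [assemblage()].
#' @return A tibble
#'   `site_id,scope,shannon_h,evenness,richness,individuals` with
#'   `scope` in `all`/`mammals`.
#' @export
diversity_summary <- function(asm) {
  one_scope <- function(df, scope) {
    df %>%
      dplyr::summarise(
        shannon_h = shannon_h(.data$abundance_mni),
        evenness = if (dplyr::n() >= 2)
          shannon_h(.data$abundance_mni) / log(dplyr::n()) else NA_real_,
        richness = dplyr::n(),
        individuals = sum(.data$abundance_mni),
        .by = "site_id"
      ) %>%
      dplyr::mutate(scope = scope, .after = "site_id")
  }
  dplyr::bind_rows(
    one_scope(iri_included(asm), "all"),
    one_scope(dplyr::filter(asm, .data$group == "mammal"), "mammals")
  ) %>%
    dplyr::arrange(.data$site_id, .data$scope)
}
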