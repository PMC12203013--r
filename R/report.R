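# End-to-end orchestration: validate the inputs, aggregate assemblages,
# and assemble the per-site and study-level reports. Every number in the
# report is taken from one upstream module's output, never recomputed here.

#' Run the full pellet-diet pipeline
#'
#' Validates the inputs, builds site assemblages, IRI tables, diversity
#' summaries, detection curves and effort thresholds for the target taxon,
#' rarefaction curves, pairwise mammal-composition tests, habitat
#' proportions (and habitat-composition tests when habitat data are given),
#' and a per-site summary supporting the presence-by-likelihood headline.
#'
#' @param pellets Pellet records tibble (e.g. [read_pellet_csv()] or a
#'   generated study's `records`).
#' @param masses Body-mass table.
#' @param sites Sites tibble with `site_id`, `likelihood`, `n_pellets`.
#' @param habitat Optional habitat areas tibble.
#' @param target_taxon Taxon whose presence/absence and detection effort are
#'   reported (default the threatened dunnart the pipeline was built for).
#' @param confidence Confidence levels for detection effort.
#' @param n_max Extrapolation limit for detection and rarefaction curves.
#' @param seed Seed for any Monte-Carlo fallback in the exact tests.
#' @param out_dir If non-`NULL`, every result table is also written there as
#'   CSV (deterministic byte-for-byte given identical inputs and seed).
#' @return A `pellet_report` list of tibbles: `validation`, `assemblage`,
#'   `iri`, `diversity`, `detection`, `effort`, `rarefaction`,
#'   `pairwise_mammal`, `habitat_proportions`, `pairwise_habitat`,
#'   `site_reports`, `presence_by_likelihood`.
#' @export
run_pipeline <- function(pellets, masses, sites, habitat = NULL,
                         target_taxon = "Sminthopsis douglasi",
                         confidence = c(0.95, 0.99), n_max = 200,
                         seed = 1, out_dir = NULL) {
  issues <- validate_study(pellets, sites, masses)
  if (nrow(issues) > 0) {
    abort(paste0(
      "study inputs failed validation:\n",
      paste(utils::capture.output(print(as.data.frame(issues))),
            collapse = "\n")
    ), class = "pelletdiet_validation_error")
  }
  asm <- assemblage(pellets)
  by_site <- split(asm, asm$site_id)

  iri <- purrr::map(by_site, iri_table, masses = masses) %>% dplyr::bind_rows()
  diversity <- diversity_summary(asm)

  det <- purrr::map(by_site, function(a) {
    dc <- detection_curve(a, target_taxon, n_max = n_max,
                          confidence = confidence,
                          taxon_pool = unique(pellets$taxon))
    list(
      curve = dplyr::mutate(dc$curve, site_id = a$site_id[1],
                            taxon = target_taxon, p_hat = dc$p_hat,
                            .before = 1),
      effort = dplyr::mutate(dc$n_star, site_id = a$site_id[1],
                             taxon = target_taxon, .before = 1)
    )
  })
  detection <- purrr::map(det, "curve") %>% dplyr::bind_rows()
  effort <- purrr::map(det, "effort") %>% dplyr::bind_rows()

  rarefaction <- purrr::map(by_site, function(a) {
    purrr::map(c("incidence", "abundance"), function(mode) {
      rc <- rarefaction_curve(a, mode = mode, size_max = n_max)
      dplyr::mutate(rc$curve, site_id = rc$site_id, mode = rc$mode,
                    asymptote = rc$asymptote, .before = 1)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()

  mam <- mammal_matrix(asm)
  pairwise_mammal <- pairwise_tests(mam, seed = seed)

  habitat_props <- NULL
  pairwise_habitat <- NULL
  if (!is.null(habitat)) {
    habitat_props <- habitat_proportions(habitat)
    pairwise_habitat <- pairwise_tests(habitat_matrix(habitat), seed = seed)
  }

  target_rows <- asm %>%
    dplyr::filter(.data$taxon == .env$target_taxon) %>%
    dplyr::select(dplyr::all_of(c("site_id", "abundance_mni", "incidence")))
  top_iri <- iri %>%
    dplyr::filter(.data$rank == 1) %>%
    dplyr::select(dplyr::all_of(c("site_id", "taxon", "iri_pct"))) %>%
    dplyr::rename(top_taxon = "taxon", top_iri_pct = "iri_pct")
  div_wide <- diversity %>%
    tidyr::pivot_wider(id_cols = "site_id", names_from = "scope",
                       values_from = c("shannon_h", "evenness", "richness"))
  eff_wide <- effort %>%
    dplyr::mutate(level = paste0("n_star_", sub("^0\\.", "", format(.data$confidence)))) %>%
    tidyr::pivot_wider(id_cols = "site_id", names_from = "level",
                       values_from = "n_star")

  site_reports <- sites %>%
    dplyr::select(dplyr::all_of(c("site_id", "likelihood", "n_pellets"))) %>%
    dplyr::left_join(target_rows, by = "site_id") %>%
    dplyr::mutate(
      target_taxon = target_taxon,
      target_mni = dplyr::coalesce(.data$abundance_mni, 0L),
      target_pellet_incidence = dplyr::coalesce(.data$incidence, 0L),
      target_present = .data$target_mni >= 1L
    ) %>%
    dplyr::select(-dplyr::any_of(c("abundance_mni", "incidence"))) %>%
    dplyr::left_join(div_wide, by = "site_id") %>%
    dplyr::left_join(top_iri, by = "site_id") %>%
    dplyr::left_join(eff_wide, by = "site_id")

  report <- structure(list(
    validation = issues,
    assemblage = asm,
    iri = iri,
    diversity = diversity,
    detection = detection,
    effort = effort,
    rarefaction = rarefaction,
    pairwise_mammal = pairwise_mammal,
    habitat_proportions = habitat_props,
    pairwise_habitat = pairwise_habitat,
    site_reports = site_reports,
    presence_by_likelihood = presence_by_likelihood(site_reports)
  ), class = "pellet_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report)) {
      if (!is.null(report[[nm]]) && is.data.frame(report[[nm]])) {
        readr::write_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")))
      }
    }
  }
  report
}

#' Presence tallies by habitat-model likelihood class
#'
#' @param site_reports The `site_reports` tibble of a [run_pipeline()]
#'   result (needs `likelihood` and `target_present`).
#' @return A tibble `likelihood,present,total` ordered high/medium/low.
#' @export
presence_by_likelihood <- function(site_reports) {
  if (nrow(site_reports) < 1) abort("need at least one site report")
  site_reports %>%
    dplyr::summarise(
      present = sum(.data$target_present),
      total = dplyr::n(),
      .by = "likelihood"
    ) %>%
    dplyr::arrange(match(.data$likelihood, LIKELIHOOD_LEVELS))
}

#' @export
print.pellet_report <- function(x, ...) {
  cat("Pellet-diet study report\n")
  cat("  sites:", nrow(x$site_reports), " pellets:",
      sum(x$site_reports$n_pellets), "\n")
  tgt <- unique(x$site_reports$target_taxon)
  cat("  target taxon:", tgt, "present at",
      sum(x$site_reports$target_present), "site(s)\n")
  cat("  presence by likelihood class:\n")
  pb <- x$presence_by_likelihood
  for (i in seq_len(nrow(pb))) {
    cat(sprintf("    %-6s %d/%d\n", pb$likelihood[i], pb$present[i],
                pb$total[i]))
  }
  invisible(x)
}
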