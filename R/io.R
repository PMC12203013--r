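#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

PREY_GROUPS <- c("mammal", "bird", "reptile", "amphibian", "unidentified")
PELLET_ELEMENTS <- c("left_dentary", "right_dentary", "beak", "skull")
HABITAT_CATEGORIES <- c("grassland", "herbland", "shrubland", "woodland", "other")
LIKELIHOOD_LEVELS <- c("high", "medium", "low")

# Paired-element vocabulary per prey group. Mammals are counted from
# left/right dentaries, birds from beaks/skulls; herpetofauna identified only
# to order may carry dentary counts (they are excluded from IRI/diversity
# downstream, but MNI is still defined for them).
elements_for_group <- function(group) {
  switch(group,
    mammal = c("left_dentary", "right_dentary"),
    bird = c("beak", "skull"),
    reptile = ,
    amphibian = ,
    unidentified = PELLET_ELEMENTS,
    abort(paste0("unknown prey group: ", group))
  )
}

required_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ), class = "pelletdiet_schema_error")
  }
  invisible(df)
}

#' Validate a long table of pellet element counts
#'
#' Checks column presence, group and element vocabularies, non-negative
#' integer counts, and that each group only carries its own paired elements
#' (mammals: dentaries; birds: beaks/skulls). Rows with count zero are legal
#' and ignored downstream.
#'
#' @param records A data frame with columns `site_id`, `pellet_id`, `taxon`,
#'   `group`, `element`, `count` (and optionally `collection_date`,
#'   `collection_number`).
#' @return The records as a tibble, invisibly validated.
#' @export
check_pellet_records <- function(records) {
  required_cols(records, c("site_id", "pellet_id", "taxon", "group",
                           "element", "count"), "pellet records")
  records <- tibble::as_tibble(records)
  bad_group <- !records$group %in% PREY_GROUPS
  if (any(bad_group)) {
    abort(paste0("unknown group value(s): ",
                 paste(unique(records$group[bad_group]), collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  bad_elem <- !records$element %in% PELLET_ELEMENTS
  if (any(bad_elem)) {
    abort(paste0("unknown element label(s): ",
                 paste(unique(records$element[bad_elem]), collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  cnt <- records$count
  bad_count <- is.na(cnt) | cnt < 0 | cnt != floor(cnt)
  if (any(bad_count)) {
    abort(paste0("counts must be non-negative integers; offending row(s): ",
                 paste(utils::head(which(bad_count), 5), collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  mismatch <- vapply(seq_len(nrow(records)), function(i) {
    !records$element[i] %in% elements_for_group(records$group[i])
  }, logical(1))
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    abort(paste0("element '", records$element[i], "' is not valid for group '",
                 records$group[i], "' (row ", i, ")"),
          class = "pelletdiet_validation_error")
  }
  # a taxon must keep one group throughout a study
  grp <- dplyr::distinct(records, .data$taxon, .data$group) %>%
    dplyr::count(.data$taxon) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(grp) > 0) {
    abort(paste0("taxon assigned to multiple groups: ",
                 paste(grp$taxon, collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  records
}

#' Read pellet prey-remains records from CSV
#'
#' Expects the long interchange format: one row per
#' site/pellet/taxon/element with columns
#' `site_id,pellet_id,collection_date,collection_number,taxon,group,element,count`.
#' Dates are ISO-8601.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of pellet records.
#' @export
read_pellet_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          site_id = readr::col_character(),
                          pellet_id = readr::col_character(),
                          taxon = readr::col_character(),
                          group = readr::col_character(),
                          element = readr::col_character(),
                          count = readr::col_double(),
                          .default = readr::col_guess()
                        ))
  check_pellet_records(df)
}

#' Write pellet records to CSV
#'
#' @param records Pellet records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pellet_csv <- function(records, path) {
  records <- check_pellet_records(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' Read a prey body-mass reference table
#'
#' Columns `taxon,group,mean_mass_g` (a `source` column is carried through if
#' present). Masses are mean adult body mass in grams and are required
#' downstream for every mammal and bird entering the IRI; missing masses are
#' kept as `NA` here and flagged by [validate_study()].
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per taxon.
#' @export
read_mass_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  required_cols(df, c("taxon", "group", "mean_mass_g"), "mass table")
  if (anyDuplicated(df$taxon) > 0) {
    abort(paste0("duplicate taxon in mass table: ",
                 paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  bad <- !is.na(df$mean_mass_g) & df$mean_mass_g <= 0
  if (any(bad)) {
    abort(paste0("non-positive mass for taxon: ",
                 paste(df$taxon[bad], collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  tibble::as_tibble(df)
}

#' Read the site metadata table
#'
#' Columns `site_id,name,latitude,longitude,bioregion,likelihood,n_pellets`.
#' Coordinates may be blank for confidential sites. `likelihood` is the
#' habitat-model class: high / medium / low.
#'
#' @param path Path to a CSV file.
#' @return A tibble of sites.
#' @export
read_sites_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  required_cols(df, c("site_id", "likelihood", "n_pellets"), "sites table")
  bad <- !df$likelihood %in% LIKELIHOOD_LEVELS
  if (any(bad)) {
    abort(paste0("likelihood must be one of high/medium/low; got: ",
                 paste(unique(df$likelihood[bad]), collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  if (any(df$n_pellets < 1)) {
    abort("n_pellets must be >= 1 for every site",
          class = "pelletdiet_validation_error")
  }
  if (anyDuplicated(df$site_id) > 0) {
    abort("duplicate site_id in sites table",
          class = "pelletdiet_validation_error")
  }
  tibble::as_tibble(df)
}

#' Read the per-site habitat area table
#'
#' Columns `site_id,category,area_km2`: pre-computed areas of each simplified
#' habitat category (grassland, herbland, shrubland, woodland, other) within
#' the assumed hunting radius around each roost. GIS clipping happens
#' upstream; this package consumes the resulting area table.
#'
#' @param path Path to a CSV file.
#' @param radius_km Assumed hunting radius (default 10 km); per-site totals
#'   exceeding the circle area by more than 1% raise an error.
#' @return A tibble of habitat areas.
#' @export
read_habitat_csv <- function(path, radius_km = 10) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  required_cols(df, c("site_id", "category", "area_km2"), "habitat table")
  bad <- !df$category %in% HABITAT_CATEGORIES
  if (any(bad)) {
    abort(paste0("unknown habitat category: ",
                 paste(unique(df$category[bad]), collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  if (any(df$area_km2 < 0)) {
    abort("habitat areas must be non-negative",
          class = "pelletdiet_validation_error")
  }
  circle <- pi * radius_km^2
  tot <- df %>%
    dplyr::summarise(total = sum(.data$area_km2), .by = "site_id") %>%
    dplyr::filter(.data$total > circle * 1.01)
  if (nrow(tot) > 0) {
    abort(paste0("habitat areas exceed the ", radius_km,
                 " km hunting-radius circle at site(s): ",
                 paste(tot$site_id, collapse = ", ")),
          class = "pelletdiet_validation_error")
  }
  tibble::as_tibble(df)
}

#' Cross-check a study's inputs for internal consistency
#'
#' Report-only validation: compares pellets actually present per site against
#' each site's declared `n_pellets`, and lists mammal or bird taxa without a
#' body mass (which the IRI will refuse). An empty report means the study is
#' clean.
#'
#' @param records Pellet records tibble.
#' @param sites Sites tibble (may be `NULL` to skip the pellet-count check).
#' @param masses Mass table tibble (may be `NULL` to skip the mass check).
#' @return A tibble with columns `issue`, `site_id`, `taxon`, `detail`;
#'   zero rows when everything is consistent.
#' @export
validate_study <- function(records, sites = NULL, masses = NULL) {
  records <- check_pellet_records(records)
  issues <- list()
  if (!is.null(sites)) {
    observed <- records %>%
      dplyr::summarise(n_obs = dplyr::n_distinct(.data$pellet_id),
                       .by = "site_id")
    cmp <- dplyr::left_join(sites, observed, by = "site_id") %>%
      dplyr::mutate(n_obs = dplyr::coalesce(.data$n_obs, 0L)) %>%
      dplyr::filter(.data$n_obs != .data$n_pellets)
    if (nrow(cmp) > 0) {
      issues$pellet_count <- tibble::tibble(
        issue = "pellet_count_mismatch",
        site_id = cmp$site_id,
        taxon = NA_character_,
        detail = paste0("declared ", cmp$n_pellets, " pellets, found ",
                        cmp$n_obs)
      )
    }
  }
  if (!is.null(masses)) {
    need_mass <- records %>%
      dplyr::filter(.data$group %in% c("mammal", "bird")) %>%
      dplyr::distinct(.data$taxon)
    have_mass <- masses$taxon[!is.na(masses$mean_mass_g)]
    missing <- setdiff(need_mass$taxon, have_mass)
    if (length(missing) > 0) {
      issues$mass <- tibble::tibble(
        issue = "missing_mass",
        site_id = NA_character_,
        taxon = missing,
        detail = "mammal/bird taxon with no body mass; IRI will refuse it"
      )
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(issue = character(), site_id = character(),
                          taxon = character(), detail = character()))
  }
  dplyr::bind_rows(issues)
}
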