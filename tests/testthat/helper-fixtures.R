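# Fixtures are built in code; oracles are deliberately brute-force and
# independent of the implementation paths they check.

# one row of the long pellet-record format
prec <- function(site, pellet, taxon, group, element, count) {
  tibble::tibble(
    site_id = site, pellet_id = pellet,
    collection_date = as.Date("2024-04-20"), collection_number = 1L,
    taxon = taxon, group = group, element = element, count = as.integer(count)
  )
}

# a tiny two-site hand-built study: known MNI by inspection
tiny_study <- function() {
  dplyr::bind_rows(
    prec("s1", "s1_p1", "Rattus villosissimus", "mammal", "left_dentary", 1),
    prec("s1", "s1_p1", "Rattus villosissimus", "mammal", "right_dentary", 2),
    prec("s1", "s1_p1", "Sminthopsis douglasi", "mammal", "left_dentary", 1),
    prec("s1", "s1_p2", "Rattus villosissimus", "mammal", "right_dentary", 1),
    prec("s1", "s1_p2", "Melopsittacus undulatus", "bird", "beak", 1),
    prec("s1", "s1_p2", "Melopsittacus undulatus", "bird", "skull", 2),
    prec("s2", "s2_p1", "Rattus villosissimus", "mammal", "left_dentary", 3),
    prec("s2", "s2_p1", "Sminthopsis macroura", "mammal", "left_dentary", 1),
    prec("s2", "s2_p2", "Sminthopsis macroura", "mammal", "right_dentary", 1)
  )
}

tiny_sites <- function() {
  tibble::tibble(
    site_id = c("s1", "s2"), name = c("Site 1", "Site 2"),
    latitude = NA_real_, longitude = NA_real_, bioregion = NA_character_,
    likelihood = c("high", "low"), n_pellets = c(2L, 2L)
  )
}

# exact expected richness of an m-individual subsample, by enumerating
# every subset of the expanded individual list (n <= 12)
oracle_rarefy_abundance <- function(x, m) {
  ind <- rep(seq_along(x), x)
  subsets <- utils::combn(length(ind), m)
  mean(apply(subsets, 2, function(idx) length(unique(ind[idx]))))
}

# exact expected richness of a t-unit subsample: materialise one
# arrangement of species over units (expectation depends only on the
# per-species unit counts) and enumerate all unit subsets
oracle_rarefy_incidence <- function(y, t_units, n_units, seed = 42) {
  occ <- matrix(FALSE, nrow = length(y), ncol = n_units)
  set.seed(seed)
  for (i in seq_along(y)) occ[i, sample(n_units, y[i])] <- TRUE
  subsets <- utils::combn(n_units, t_units)
  mean(apply(subsets, 2, function(idx) {
    sum(rowSums(occ[, idx, drop = FALSE]) > 0)
  }))
}
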