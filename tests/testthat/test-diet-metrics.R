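asm_from_counts <- function(counts, masses_present = TRUE, n_pellets = 31L,
                            incidence = NULL, group = "mammal") {
  tibble::tibble(
    site_id = "s", taxon = names(counts), group = group,
    abundance_mni = as.integer(counts),
    incidence = as.integer(if (is.null(incidence)) pmin(counts, n_pellets)
                           else incidence),
    n_pellets = n_pellets
  )
}

test_that("numerical percentage is the share of individuals", {
  asm <- asm_from_counts(c(A = 40, B = 1))
  np <- numerical_pct(asm)
  expect_equal(np$n_pct, 100 * c(40, 1) / 41, tolerance = 1e-12)
  expect_equal(round(np$n_pct, 3), c(97.561, 2.439))
  expect_equal(numerical_pct(asm_from_counts(c(A = 7)))$n_pct, 100)
  expect_equal(numerical_pct(asm_from_counts(c(A = 10, B = 10)))$n_pct,
               c(50, 50))
})

test_that("volumetric percentage is the biomass share and refuses missing mass", {
  asm <- asm_from_counts(c(A = 1, B = 1))
  masses <- tibble::tibble(taxon = c("A", "B"), group = "mammal",
                           mean_mass_g = c(100, 50))
  vp <- volumetric_pct(asm, masses)
  expect_equal(round(vp$v_pct, 3), c(66.667, 33.333))
  # equal masses: volumetric collapses to numerical
  eqm <- dplyr::mutate(masses, mean_mass_g = 80)
  asm2 <- asm_from_counts(c(A = 12, B = 5))
  expect_equal(volumetric_pct(asm2, eqm)$v_pct, numerical_pct(asm2)$n_pct)
  expect_error(volumetric_pct(asm, masses[1, ]), "B",
               class = "pelletdiet_validation_error")
})

test_that("frequency of occurrence uses pellet incidence over pellets examined", {
  asm <- asm_from_counts(c(A = 5), n_pellets = 31L, incidence = 1L)
  expect_equal(round(freq_occurrence_pct(asm)$fo_pct, 4), 3.2258)
  all_p <- asm_from_counts(c(A = 40), n_pellets = 10L, incidence = 10L)
  expect_equal(freq_occurrence_pct(all_p)$fo_pct, 100)
})

test_that("IRI matches a direct recomputation and its invariants hold", {
  set.seed(71)
  for (rep in 1:5) {
    k <- 4
    counts <- stats::setNames(sample(1:40, k), paste0("t", 1:k))
    inc <- pmin(counts, sample(5:20, k))
    n_pel <- 25L
    asm <- asm_from_counts(counts, n_pellets = n_pel, incidence = inc)
    masses <- tibble::tibble(taxon = names(counts), group = "mammal",
                             mean_mass_g = stats::runif(k, 5, 200))
    tab <- iri_table(asm, masses)

    # independent direct evaluation of (N% + V%) x FO%
    ord <- match(tab$taxon, names(counts))
    n_pct <- 100 * counts[ord] / sum(counts)
    v_pct <- 100 * (counts * masses$mean_mass_g)[ord] /
      sum(counts * masses$mean_mass_g)
    fo_pct <- 100 * inc[ord] / n_pel
    iri <- (n_pct + v_pct) * fo_pct
    expect_equal(tab$iri, unname(iri), tolerance = 1e-12)
    expect_equal(tab$iri_pct, unname(100 * iri / sum(iri)), tolerance = 1e-12)

    # percentage vectors each sum to 100; ranking descends
    expect_equal(sum(tab$n_pct), 100, tolerance = 1e-9)
    expect_equal(sum(tab$v_pct), 100, tolerance = 1e-9)
    expect_equal(sum(tab$iri_pct), 100, tolerance = 1e-9)
    expect_true(all(diff(tab$iri) <= 1e-12))
    expect_true(all(tab$fo_pct <= 100))

    # scaling all masses leaves V% and IRI unchanged
    tab2 <- iri_table(asm, dplyr::mutate(masses, mean_mass_g = mean_mass_g * 7))
    expect_equal(tab2$iri, tab$iri, tolerance = 1e-9)
  }
})

test_that("single-taxon and symmetric IRI degenerate cases", {
  one <- asm_from_counts(c(A = 3), n_pellets = 10L, incidence = 2L)
  m <- tibble::tibble(taxon = "A", group = "mammal", mean_mass_g = 50)
  expect_equal(iri_table(one, m)$iri_pct, 100)
  two <- asm_from_counts(c(A = 5, B = 5), n_pellets = 10L,
                         incidence = c(4L, 4L))
  m2 <- tibble::tibble(taxon = c("A", "B"), group = "mammal",
                       mean_mass_g = c(30, 30))
  expect_equal(iri_table(two, m2)$iri_pct, c(50, 50))
})

test_that("only mammals and birds enter the IRI", {
  asm <- dplyr::bind_rows(
    asm_from_counts(c(A = 10)),
    asm_from_counts(c(lizards = 5), group = "reptile"),
    asm_from_counts(c(unknown = 2), group = "unidentified")
  )
  m <- tibble::tibble(taxon = "A", group = "mammal", mean_mass_g = 50)
  expect_identical(iri_table(asm, m)$taxon, "A")
})

test_that("Shannon H matches known communities and vegan's computation", {
  expect_equal(signif(shannon_h(c(105, 1)), 3), 0.0534)
  expect_equal(round(shannon_h(c(40, 1)), 3), 0.115)
  expect_equal(shannon_h(c(7)), 0)
  expect_equal(shannon_h(rep(13, 6)), log(6))
  expect_equal(shannon_h(c(3, 0, 5)), shannon_h(c(3, 5)))
  set.seed(8)
  for (rep in 1:5) {
    x <- sample(1:50, sample(2:8, 1))
    expect_equal(shannon_h(x), as.numeric(vegan::diversity(x)),
                 tolerance = 1e-12)
    # permutation invariance; merging two taxa never increases H
    expect_equal(shannon_h(sample(x)), shannon_h(x))
    merged <- c(x[-(1:2)], x[1] + x[2])
    expect_lte(shannon_h(merged), shannon_h(x) + 1e-12)
    # uniform maximum
    expect_lte(shannon_h(x), log(length(x)) + 1e-12)
  }
})

test_that("Pielou evenness is H/ln(S), NA for a single taxon", {
  expect_equal(round(evenness(c(105, 1)), 3), 0.077)
  expect_equal(round(evenness(c(40, 1)), 3), 0.165)
  expect_equal(evenness(rep(4, 9)), 1)
  expect_warning(e1 <- evenness(c(10)), "undefined")
  expect_true(is.na(e1))
  set.seed(9)
  for (rep in 1:5) {
    x <- sample(1:50, sample(2:8, 1))
    e <- evenness(x)
    expect_gt(e, 0)
    expect_lte(e, 1)
  }
})

test_that("diversity_summary reports both scopes per site", {
  asm <- dplyr::bind_rows(
    asm_from_counts(c(A = 105, B = 1)),
    asm_from_counts(c(C = 12), group = "bird")
  )
  d <- diversity_summary(asm)
  expect_setequal(d$scope, c("all", "mammals"))
  mam <- dplyr::filter(d, scope == "mammals")
  expect_identical(mam$richness, 2L)
  expect_equal(mam$shannon_h, shannon_h(c(105, 1)))
  expect_equal(mam$evenness, evenness(c(105, 1)))
  all_sc <- dplyr::filter(d, scope == "all")
  expect_identical(all_sc$richness, 3L)
  expect_identical(all_sc$individuals, 118L)
})
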