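test_that("exact p-values match stats::fisher.test on all small 2x2 tables", {
  # full sweep of 2x2 tables with total count <= 20
  for (total in 1:20) {
    for (a in 0:total) for (b in 0:(total - a)) for (c in 0:(total - a - b)) {
      d <- total - a - b - c
      tab <- matrix(c(a, c, b, d), nrow = 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      p_ours <- fisher_exact(tab, method = "exact")$p_value
      p_ref <- stats::fisher.test(tab)$p.value
      expect_equal(p_ours, p_ref, tolerance = 1e-7)
    }
  }
})

test_that("worked 2x2 examples and the modal-table case", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
               tolerance = 1e-12)
})

test_that("2xk exact p agrees with stats::fisher.test and is invariant", {
  set.seed(55)
  for (rep in 1:8) {
    k <- sample(3:4, 1)
    tab <- matrix(sample(0:6, 2 * k, replace = TRUE), nrow = 2)
    if (any(rowSums(tab) == 0)) tab <- tab + 1
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) next
    p_ours <- fisher_exact(tab, method = "exact")$p_value
    expect_equal(p_ours, stats::fisher.test(tab)$p.value, tolerance = 1e-6)
    # invariant under column permutation and row swap
    perm <- sample(ncol(tab))
    expect_equal(fisher_exact(tab[, perm], method = "exact")$p_value, p_ours,
                 tolerance = 1e-12)
    expect_equal(fisher_exact(tab[2:1, ], method = "exact")$p_value, p_ours,
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p converges to the enumerated p", {
  set.seed(7)
  for (rep in 1:4) {
    tab <- matrix(sample(1:8, 6, replace = TRUE), nrow = 2)
    p_exact <- fisher_exact(tab, method = "exact")$p_value
    mc <- fisher_exact(tab, method = "montecarlo", seed = rep, n_mc = 20000)
    expect_identical(mc$method, "montecarlo")
    se <- sqrt(p_exact * (1 - p_exact) / 20000)
    expect_lt(abs(mc$p_value - p_exact), 3 * se + 1e-4)
    expect_gt(mc$p_value, 0)
  }
})

test_that("enumeration budget errors point at the Monte-Carlo route", {
  tab <- matrix(rep(40L, 12), nrow = 2)
  expect_error(fisher_exact(tab, method = "exact", max_tables = 1000),
               "montecarlo", class = "pelletdiet_enumeration_error")
  # auto falls back instead of failing
  res <- fisher_exact(tab, method = "auto", max_tables = 1000, n_mc = 2000)
  expect_identical(res$method, "montecarlo")
})

test_that("pairwise_tests runs every unordered pair with Bonferroni", {
  set.seed(12)
  mat <- matrix(sample(0:15, 9 * 4, replace = TRUE), nrow = 9,
                dimnames = list(paste0("site", 1:9), paste0("t", 1:4)))
  mat[1, ] <- mat[2, ]  # an identical pair
  res <- pairwise_tests(mat)
  expect_identical(nrow(res), 36L)  # C(9, 2)
  expect_true(all(res$n_comparisons == 36L))
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 36))
  expect_true(all(res$p_adjusted >= res$p_raw))
  same <- dplyr::filter(res, site_a == "site1", site_b == "site2")
  expect_equal(same$p_raw, 1)
  expect_false(same$significant)
  # raw p 0.01 against 36 comparisons adjusts to 0.36
  expect_equal(min(1, 0.01 * unique(res$n_comparisons)), 0.36)
})

test_that("mammal_matrix keeps mammals and excludes mammal-free sites", {
  asm <- dplyr::bind_rows(
    tibble::tibble(site_id = "s1", taxon = c("A", "B"), group = "mammal",
                   abundance_mni = c(10L, 2L), incidence = c(5L, 2L),
                   n_pellets = 10L),
    tibble::tibble(site_id = "s2", taxon = c("A", "C"),
                   group = c("mammal", "bird"),
                   abundance_mni = c(4L, 6L), incidence = c(3L, 4L),
                   n_pellets = 10L),
    tibble::tibble(site_id = "s3", taxon = "C", group = "bird",
                   abundance_mni = 9L, incidence = 6L, n_pellets = 10L)
  )
  expect_warning(m <- mammal_matrix(asm), "s3")
  expect_identical(rownames(m), c("s1", "s2"))
  expect_identical(colnames(m), c("A", "B"))
  expect_identical(unname(rowSums(m)), c(12, 4))
})

test_that("mammal matrix row sums equal per-site mammal MNI on synthetic data", {
  st <- generate_study(default_study_scenarios()[c("toorak", "nelia")],
                       seed = 3)
  asm <- assemblage(st$records)
  m <- mammal_matrix(asm)
  per_site <- asm %>%
    dplyr::filter(group == "mammal") %>%
    dplyr::summarise(total = sum(abundance_mni), .by = "site_id")
  expect_equal(unname(rowSums(m)[per_site$site_id]),
               as.numeric(per_site$total))
})

test_that("habitat_matrix discretises areas at the stated resolution", {
  hab <- tibble::tibble(
    site_id = rep(c("x", "y"), each = 2),
    category = rep(c("grassland", "woodland"), 2),
    area_km2 = c(200.4, 99.6, 310.2, 3.9)
  )
  m <- habitat_matrix(hab, resolution_km2 = 1)
  expect_identical(attr(m, "resolution_km2"), 1)
  expect_identical(unname(m["x", ]), c(200L, 100L))
  m5 <- habitat_matrix(hab, resolution_km2 = 5)
  expect_identical(unname(m5["y", ]), c(62L, 1L))
})
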