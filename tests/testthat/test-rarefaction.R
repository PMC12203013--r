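test_that("abundance interpolation equals exhaustive subset enumeration", {
  expect_equal(rarefy_abundance(c(A = 2, B = 1), 2), 5 / 3,
               tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:6) {
    k <- sample(2:4, 1)
    x <- sample(1:4, k, replace = TRUE)
    while (sum(x) > 12) x <- sample(1:4, k, replace = TRUE)
    for (m in seq_len(sum(x))) {
      expect_equal(rarefy_abundance(x, m), oracle_rarefy_abundance(x, m),
                   tolerance = 1e-9)
    }
  }
  # vegan implements the same interpolation; check at a larger, non-
  # enumerable size too
  x_big <- c(55, 21, 13, 8, 3, 2, 1, 1)
  for (m in c(1, 10, 50, sum(x_big))) {
    expect_equal(rarefy_abundance(x_big, m),
                 unname(c(vegan::rarefy(x_big, m))), tolerance = 1e-9)
  }
})

test_that("abundance interpolation boundary cases", {
  x <- c(A = 5, B = 3, C = 1)
  expect_equal(rarefy_abundance(x, sum(x)), 3)
  expect_equal(rarefy_abundance(x, 1), 1)
  expect_error(rarefy_abundance(x, sum(x) + 1), "extrapolate")
  # non-decreasing and concave over the interpolation range
  est <- vapply(1:9, function(m) rarefy_abundance(x, m), numeric(1))
  expect_true(all(diff(est) >= -1e-12))
  expect_true(all(diff(diff(est)) <= 1e-12))
})

test_that("Chao1 from singletons and doubletons, bias-corrected when f2 = 0", {
  expect_equal(chao1(c(3, 4, 5)), 3)                        # f1 = 0
  expect_equal(chao1(c(1, 1)), 2.5)                         # f2 = 0 corrected
  expect_equal(chao1(c(1, 2)), 2 + (2 / 3) * (1 / 2))       # classic form
  set.seed(4)
  for (rep in 1:5) {
    x <- sample(1:6, 8, replace = TRUE)
    # never below observed richness; unseen estimate grows with singletons
    expect_gte(chao1(x), length(x))
    expect_gte(chao1(c(x, 1, 1)), chao1(c(x, 1)) - 1e-9)
  }
})

test_that("abundance extrapolation joins the curve and approaches Chao1", {
  x <- c(A = 1, B = 1)
  expect_equal(extrapolate_abundance(x, 0), 2)
  # one algebraic step of S_obs + f0(1 - (1 - f1/(n f0 + f1))^m*)
  expect_equal(extrapolate_abundance(x, 2), 2 + 0.5 * (1 - (1 - 2 / 3)^2),
               tolerance = 1e-12)
  expect_equal(extrapolate_abundance(x, 1e6), chao1(x), tolerance = 1e-6)
  x2 <- c(A = 1, B = 2, C = 2, D = 5)
  grid <- extrapolate_abundance(x2, 0:50)
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid <= chao1(x2) + 1e-9))
  # continuity of slope at the observed size: the first extrapolated step
  # matches the last interpolated step closely
  n <- sum(x2)
  slope_in <- rarefy_abundance(x2, n) - rarefy_abundance(x2, n - 1)
  slope_out <- extrapolate_abundance(x2, 1) - length(x2)
  expect_lt(abs(slope_in - slope_out), 0.05)
})

test_that("incidence interpolation equals enumeration over unit subsets", {
  expect_equal(rarefy_incidence(c(A = 2, B = 1), 1, 3), 1, tolerance = 1e-12)
  set.seed(23)
  for (rep in 1:5) {
    t_tot <- sample(4:8, 1)
    y <- sample(1:t_tot, sample(2:4, 1), replace = TRUE)
    for (t in seq_len(t_tot)) {
      expect_equal(rarefy_incidence(y, t, t_tot),
                   oracle_rarefy_incidence(y, t, t_tot),
                   tolerance = 1e-9)
    }
  }
})

test_that("incidence boundary cases and Chao2", {
  expect_equal(rarefy_incidence(c(A = 6), 3, 6), 1)  # one ubiquitous taxon
  expect_equal(rarefy_incidence(c(A = 4, B = 2), 6, 6), 2)
  expect_error(rarefy_incidence(c(A = 2), 4, 3), "1 <= t")
  expect_equal(chao2(c(1, 1), 2), 2.5)
  expect_equal(chao2(c(3, 4), 5), 2)                 # Q1 = 0
  expect_equal(extrapolate_incidence(c(1, 1), 0, 2), 2)
  expect_equal(extrapolate_incidence(c(1, 1), 1e6, 2), chao2(c(1, 1), 2),
               tolerance = 1e-6)
})

test_that("rarefaction_curve assembles interpolation, extrapolation, asymptote", {
  sc <- site_scenario("rc", 40, c(A = 0.4, B = 0.3, C = 0.2, D = 0.1),
                      prey_per_pellet_mean = 2, element_retention = 1)
  asm <- site_assemblage(generate_site(sc, seed = 12)$records)
  for (mode in c("incidence", "abundance")) {
    rc <- rarefaction_curve(asm, mode = mode, size_max = 200)
    expect_identical(nrow(rc$curve), 200L)
    expect_true(all(diff(rc$curve$estimate) >= -1e-9))
    expect_lte(max(rc$curve$estimate), rc$asymptote + 1e-9)
    # value at the observed size equals observed richness
    at_obs <- rc$curve$estimate[rc$curve$size == rc$observed_size]
    expect_equal(at_obs, rc$observed_richness, tolerance = 1e-9)
    expect_identical(sum(!rc$curve$is_extrapolated), rc$observed_size)
  }
})

test_that("with all taxa common the curve plateaus at the true richness", {
  sc <- site_scenario("plateau", 100, c(A = 0.4, B = 0.35, C = 0.25),
                      prey_per_pellet_mean = 2, element_retention = 1)
  asm <- site_assemblage(generate_site(sc, seed = 2)$records)
  rc <- rarefaction_curve(asm, mode = "abundance", size_max = 200)
  expect_identical(rc$observed_richness, 3L)
  expect_lt(rc$asymptote - 3, 0.5)
  expect_equal(max(rc$curve$estimate), rc$asymptote, tolerance = 0.51)
  td <- tidy(rc)
  expect_named(td, c("site_id", "mode", "size", "estimate",
                     "is_extrapolated"))
  expect_identical(nrow(glance(rc)), 1L)
  expect_s3_class(ggplot2::autoplot(rc), "ggplot")
})
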