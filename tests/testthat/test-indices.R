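test_that("geoaccumulation index matches closed form and is monotone", {
  expect_equal(geoaccumulation_index(1.5 * 20, 20), 0)
  expect_equal(geoaccumulation_index(3 * 20, 20), 1)
  expect_equal(geoaccumulation_index(96, 16), 2)
  expect_error(geoaccumulation_index(0, 10), "positive")
  expect_error(geoaccumulation_index(10, 0), "positive")

  set.seed(42)
  for (i in 1:20) {
    cn <- runif(1, 1, 500)
    bn <- runif(1, 1, 100)
    eps <- runif(1, 0.1, 10)
    expect_gt(geoaccumulation_index(cn + eps, bn), geoaccumulation_index(cn, bn))
    expect_lt(geoaccumulation_index(cn, bn + eps), geoaccumulation_index(cn, bn))
  }
})

test_that("corrected concentration applies the fraction toxicity weights", {
  expect_equal(corrected_concentration(10, 5, 5, 10), 32)
  # unit weights collapse to the plain fraction sum
  f <- c(3.2, 1.1, 0.4, 9.3)
  expect_equal(corrected_concentration(f[1], f[2], f[3], f[4], theta = c(3, 2, 1) / 2),
               (3 * f[1] + 2 * (f[2] + f[3]) + f[4]) / 2)
  expect_equal(corrected_concentration(0, 0, 0, 0), 0)
  expect_error(corrected_concentration(-1, 0, 0, 0), "non-negative")
  # vectorized over sites
  expect_equal(corrected_concentration(c(10, 0), c(5, 0), c(5, 0), c(10, 0)),
               c(32, 0))
})

test_that("secondary correction folds at the background and never drops below it", {
  expect_equal(secondary_correction(50, 67), 84)
  expect_equal(secondary_correction(100, 67), 100)
  expect_equal(secondary_correction(67, 67), 67)
  expect_error(secondary_correction(10, 0), "positive")
  set.seed(7)
  cri <- runif(200, 0, 300)
  c0 <- runif(200, 1, 100)
  expect_true(all(secondary_correction(cri, c0) >= c0))
})

test_that("contamination factor, single and comprehensive indices are the plain ratios and sums", {
  expect_equal(contamination_factor(67, 67), 1)
  expect_equal(contamination_factor(84, 67), 84 / 67)
  expect_equal(contamination_factor(0, 67), 0)
  expect_equal(single_hazard_index(1, 10), 10)
  expect_equal(single_hazard_index(84 / 67, 5), 5 * 84 / 67)
  expect_equal(comprehensive_index(c(10, 10, 10)), 30)
  expect_equal(comprehensive_index(0), 0)
  expect_error(comprehensive_index(numeric()), "at least one")
  expect_error(comprehensive_index(c(1, NA)), "finite")
})

test_that("Er grading scheme derives from the maximum toxicity coefficient and doubles", {
  sch <- derive_er_scheme(default_toxicity())
  expect_equal(sch$boundaries, c(10, 20, 40, 80))
  expect_equal(sch$labels, c("low", "moderate", "considerable", "high", "very high"))
  # published class placements are consistent with the derived boundaries
  expect_equal(as.character(classify(21.45, sch)), "considerable")
  expect_equal(as.character(classify(9.08, sch)), "low")
  expect_equal(as.character(classify(36.25, sch)), "considerable")
  expect_equal(as.character(classify(1440.21, sch)), "very high")

  unit <- default_toxicity(tr = c(A = 1, B = 1))
  expect_equal(derive_er_scheme(unit)$boundaries, c(1, 2, 4, 8))
  expect_equal(derive_er_scheme(default_toxicity(), n_classes = 2)$boundaries, 10)
})

test_that("RI grading scheme derives via the unit toxicity coefficient", {
  sch <- derive_ri_scheme(default_toxicity())
  expect_equal(sch$boundaries, c(30, 60, 120, 240))
  # intermediate product 150/133 * 28 = 31.58 rounds to the nearest ten
  expect_equal(round(150 / 133 * 28 / 10) * 10, 30)
  # linear in the coefficient sum before rounding
  doubled <- default_toxicity(tr = 2 * default_toxicity()$tr)
  expect_equal(derive_ri_scheme(doubled)$boundaries[1],
               round(150 / 133 * 56 / 10) * 10)
})

test_that("classic mode reproduces total/background factors; background-level totals give RI 28", {
  bg <- default_backgrounds("shaanxi")
  sites <- tibble::tibble(site_id = "S1")
  for (m in STUDY_METALS) sites[[paste0(m, "_total")]] <- bg[[m]]
  a <- assess_sites(sites, "classic")
  expect_equal(a$cf, rep(1, 6))
  expect_equal(unique(a$ri), 28)
  expect_true(all(is.na(a$cri)))
})

test_that("assessment matches an independent scalar-arithmetic oracle on random sites", {
  set.seed(101)
  n <- 100
  bg <- default_backgrounds("shaanxi")
  tox <- default_toxicity()
  sites <- tibble::tibble(site_id = paste0("R", 1:n))
  for (m in STUDY_METALS) {
    sites[[paste0(m, "_total")]] <- runif(n, 0.2, 4) * bg[[m]]
    for (k in 1:4) sites[[paste0(m, "_F", k)]] <- runif(n, 0, bg[[m]])
  }

  for (mode in c("classic", "modified")) {
    a <- assess_sites(sites, mode)
    for (i in sample(n, 25)) {
      ers <- numeric(0)
      for (m in STUDY_METALS) {
        if (mode == "classic") {
          cf <- sites[[paste0(m, "_total")]][i] / bg[[m]]
        } else {
          f <- vapply(1:4, function(k) sites[[paste0(m, "_F", k)]][i], numeric(1))
          cri <- 1.6 * f[1] + 1.0 * (f[2] + f[3]) + 0.6 * f[4]
          cf <- (abs(cri - bg[[m]]) + bg[[m]]) / bg[[m]]
        }
        er <- tox$tr[[m]] * cf
        ers <- c(ers, er)
        row <- a[a$site_id == sites$site_id[i] & a$metal == m, ]
        expect_identical(row$er, er)
      }
      ri <- a$ri[a$site_id == sites$site_id[i]]
      expect_identical(unique(ri), sum(ers))
    }
  }
})

test_that("modified mode guarantees Cf >= 1 and Er >= Tr for any valid fractions", {
  set.seed(202)
  tox <- default_toxicity()
  for (rep in 1:10) {
    sites <- tibble::tibble(site_id = paste0("S", 1:8))
    for (m in STUDY_METALS) {
      for (k in 1:4) sites[[paste0(m, "_F", k)]] <- rexp(8, rate = 1 / 20)
    }
    a <- assess_sites(sites, "modified")
    expect_true(all(a$cf >= 1))
    for (m in STUDY_METALS) {
      expect_true(all(a$er[a$metal == m] >= tox$tr[[m]]))
    }
    expect_equal(summarize_ri(a)$ri,
                 tapply(a$er, a$site_id, sum)[summarize_ri(a)$site_id],
                 ignore_attr = TRUE)
  }
})

test_that("class assignment is invariant under metal column reordering", {
  sites <- fixture_sites()
  shuffled <- sites[, c("site_id", sample(setdiff(names(sites), "site_id")))]
  a1 <- assess_sites(sites, "modified")
  a2 <- assess_sites(shuffled, "modified")
  key1 <- a1[order(a1$site_id, a1$metal), c("site_id", "metal", "er", "er_class", "ri_class")]
  key2 <- a2[order(a2$site_id, a2$metal), c("site_id", "metal", "er", "er_class", "ri_class")]
  expect_equal(key1, key2)
})

test_that("modes refuse sites missing their required concentrations", {
  sites <- fixture_sites()
  no_totals <- sites[, !grepl("_total$", names(sites))]
  expect_error(assess_sites(no_totals, "classic"), "total|assessable")
  expect_silent(assess_sites(no_totals, "modified"))
  no_fr <- sites[, !grepl("_F[1-4]$", names(sites))]
  expect_error(assess_sites(no_fr, "modified"), "fraction|assessable")
  # a metal without background is rejected by name
  expect_error(assess_sites(sites, "modified", backgrounds = c(Cr = 67), metals = c("Cr", "Cd")),
               "Cd")
})

test_that("geoaccumulation assessment classes the fixture like the published means", {
  sites <- fixture_sites()
  ig <- assess_igeo(sites)
  mean_ig <- tapply(ig$igeo, ig$metal, mean)
  # As is extremely polluted on average; Cr and Ni unpolluted
  expect_gt(mean_ig[["As"]], 5)
  expect_lt(mean_ig[["Cr"]], 0)
  expect_lt(mean_ig[["Ni"]], 0)
  expect_equal(as.character(classify(mean_ig[["As"]], igeo_scheme())),
               "Extremely polluted")
})
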