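test_that("boxplot screening matches a brute-force quartile computation", {
  set.seed(44)
  for (i in 1:15) {
    xs <- c(rnorm(15, 10, 1), if (i %% 2) 1000 else numeric())
    sc <- screen_outliers(xs)
    q1 <- quantile(xs, 0.25, names = FALSE)
    q3 <- quantile(xs, 0.75, names = FALSE)
    fence <- c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1))
    expect_equal(sc$retained, xs[xs >= fence[1] & xs <= fence[2]])
    expect_equal(sc$flagged, xs[xs < fence[1] | xs > fence[2]])
  }
  # the gross outlier is flagged and labelled
  xs <- c(rnorm(15, 10, 1), 1000)
  sc <- screen_outliers(xs, labels = paste0("S", 1:16))
  expect_true(1000 %in% sc$flagged)
  expect_true("S16" %in% sc$flagged_labels)
  expect_false(1000 %in% sc$retained)
})

test_that("screening keeps equal values and clean normal samples mostly intact", {
  expect_equal(screen_outliers(rep(3, 10))$flagged, numeric())
  expect_warning(sc <- screen_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(sc$retained, c(1, 2, 3))
  # clean normal n = 16: flag rate stays near the boxplot expectation
  set.seed(45)
  flags <- replicate(200, length(screen_outliers(rnorm(16))$flagged))
  expect_lt(mean(flags) / 16, 0.08)
})

test_that("fit_distribution recovers generating parameters within 2% at n = 10,000", {
  set.seed(55)
  x <- rnorm(10000, 50, 5)
  fit <- fit_distribution(x)
  expect_equal(fit$family, "normal")
  expect_lt(abs(fit$location - 50) / 50, 0.02)
  expect_lt(abs(fit$scale - 5) / 5, 0.02)

  y <- rlnorm(10000, meanlog = 2, sdlog = 0.5)
  fit <- fit_distribution(y)
  expect_equal(fit$family, "lognormal")
  expect_lt(abs(fit$location - 2) / 2, 0.02)
  expect_lt(abs(fit$scale - 0.5) / 0.5, 0.02)
})

test_that("fit_distribution rejects degenerate or tiny samples and flags poor fits", {
  expect_error(fit_distribution(rep(5, 20)), "degenerate")
  expect_error(fit_distribution(rnorm(5)), "at least 8")
  # a bimodal sample passes neither family
  set.seed(56)
  x <- c(rnorm(300, 5, 0.2), rnorm(300, 50, 0.2))
  expect_warning(fit <- fit_distribution(x), "neither")
  expect_true(fit$neither_passed)
})

test_that("propagation is a fixed point at the background and replays under its seed", {
  tox <- one_metal_tox("As", 10)
  spec <- tibble::tibble(metal = "As", family = "normal",
                         location = 14.10, scale = 0)
  mc <- mc_propagate(spec, backgrounds = c(As = 14.10), toxicity = tox,
                     n_draws = 1000, seed = 3)
  expect_true(all(mc$er_samples[, "As"] == 10))

  specs <- fit_site_distributions(fixture_sites())
  mc1 <- mc_propagate(specs, n_draws = 2000, seed = 9)
  mc2 <- mc_propagate(specs, n_draws = 2000, seed = 9)
  expect_identical(mc1$er_samples, mc2$er_samples)
  expect_identical(mc1$class_probs, mc2$class_probs)
  mc3 <- mc_propagate(specs, n_draws = 2000, seed = 10)
  expect_false(identical(mc1$ri_samples, mc3$ri_samples))
})

test_that("Monte Carlo class probabilities match the analytic folded-lognormal CDF", {
  n <- 50000
  tox <- one_metal_tox("As", 10)
  er_scheme <- derive_er_scheme(default_toxicity())
  c0 <- 14.10
  # location both above and below background, so the fold is exercised
  cases <- list(c(meanlog = log(30), sdlog = 0.8),
                c(meanlog = log(10), sdlog = 0.6))
  for (cs in cases) {
    spec <- tibble::tibble(metal = "As", family = "lognormal",
                           location = cs[["meanlog"]], scale = cs[["sdlog"]])
    mc <- mc_propagate(spec, backgrounds = c(As = c0), toxicity = tox,
                       er_scheme = er_scheme, n_draws = n, seed = 12)
    emp <- mc$class_probs$probability[mc$class_probs$variable == "As"]
    ana <- folded_lnorm_class_probs(er_scheme, cs[["meanlog"]], cs[["sdlog"]],
                                    c0, 10)
    tol <- 3 * sqrt(ana * (1 - ana) / n) + 1e-12
    expect_true(all(abs(emp - ana) <= tol),
                info = paste("meanlog", cs[["meanlog"]]))
    expect_equal(sum(emp), 1, tolerance = 1e-9)
  }
})

test_that("propagation redraws negative normal draws and keeps concentrations non-negative", {
  tox <- one_metal_tox("X", 5)
  spec <- tibble::tibble(metal = "X", family = "normal",
                         location = 5, scale = 10) # heavy negative mass
  mc <- mc_propagate(spec, backgrounds = c(X = 20), toxicity = tox,
                     n_draws = 5000, seed = 2)
  expect_gt(mc$rejected[["X"]], 0)
  # Er >= Tr always (fold) and finite
  expect_true(all(mc$er_samples >= 5))
})

test_that("mean Er and RI respond monotonically to a location shift", {
  tox <- default_toxicity(tr = c(A = 5, B = 5))
  bg <- c(A = 20, B = 20)
  base <- tibble::tibble(metal = c("A", "B"), family = "lognormal",
                         location = log(c(25, 25)), scale = 0.4)
  up <- base
  up$location[1] <- log(60)
  mc0 <- mc_propagate(base, bg, tox, n_draws = 20000, seed = 5)
  mc1 <- mc_propagate(up, bg, tox, n_draws = 20000, seed = 5)
  expect_gt(mean(mc1$er_samples[, "A"]), mean(mc0$er_samples[, "A"]))
  expect_gt(mean(mc1$ri_samples), mean(mc0$ri_samples))
  expect_equal(mean(mc1$er_samples[, "B"]), mean(mc0$er_samples[, "B"]),
               tolerance = 1e-9)
})

test_that("class probabilities respect the half-open convention and analytic shares", {
  sch <- risk_scheme("er", c("lo", "hi"), 10)
  p <- class_probabilities(c(1, 2, 3), sch)
  expect_equal(p$probability, c(1, 0))
  # samples exactly on the boundary go to the upper class
  p <- class_probabilities(c(10, 10, 5, 15), sch)
  expect_equal(p$probability, c(0.25, 0.75))
  # uniform over (0, 2 * b1) splits evenly
  set.seed(66)
  u <- runif(50000, 0, 20)
  p <- class_probabilities(u, sch)
  expect_equal(p$probability[1], 0.5, tolerance = 0.02)
  expect_equal(sum(p$probability), 1, tolerance = 1e-12)
})

test_that("cumulative curve is a right-continuous ECDF consistent with the percentiles", {
  cc <- cumulative_curve(7)
  expect_equal(cc$value, 7)
  expect_equal(cc$cumulative, 1)
  set.seed(67)
  x <- rlnorm(500)
  cc <- cumulative_curve(x)
  expect_equal(max(cc$cumulative), 1)
  expect_true(!is.unsorted(cc$value) && !is.unsorted(cc$cumulative))

  specs <- fit_site_distributions(fixture_sites())
  mc <- mc_propagate(specs, n_draws = 4000, seed = 21)
  cc <- cumulative_curve(mc$ri_samples)
  med_curve <- cc$value[which(cc$cumulative >= 0.5)[1]]
  med_reported <- mc$percentiles$median[mc$percentiles$variable == "RI"]
  expect_equal(med_curve, med_reported, tolerance = 0.01)
})

test_that("sensitivity contributions isolate variance sources and sum to 100", {
  tox <- default_toxicity(tr = c(A = 5, B = 5, C = 5))
  bg <- c(A = 20, B = 20, C = 20)
  specs <- tibble::tibble(
    metal = c("A", "B", "C"), family = "lognormal",
    location = log(c(40, 30, 30)), scale = c(0.6, 0, 0)
  )
  mc <- mc_propagate(specs, bg, tox, n_draws = 5000, seed = 8)
  expect_equal(mc$sensitivity$contribution[mc$sensitivity$metal == "A"], 100,
               tolerance = 1e-9)
  expect_equal(sum(mc$sensitivity$contribution), 100, tolerance = 1e-9)

  # six i.i.d. equal-variance inputs contribute ~1/6 each
  tox6 <- default_toxicity(tr = setNames(rep(5, 6), LETTERS[1:6]))
  bg6 <- setNames(rep(20, 6), LETTERS[1:6])
  specs6 <- tibble::tibble(metal = LETTERS[1:6], family = "lognormal",
                           location = log(40), scale = 0.5)
  mc6 <- mc_propagate(specs6, bg6, tox6, n_draws = 30000, seed = 13)
  expect_equal(mc6$sensitivity$contribution, rep(100 / 6, 6), tolerance = 0.12)
  expect_equal(sum(mc6$sensitivity$contribution), 100, tolerance = 1e-9)

  # contribution order tracks the per-metal Er variances for independent inputs
  specs_v <- tibble::tibble(metal = c("A", "B", "C"), family = "normal",
                            location = c(60, 60, 60), scale = c(15, 8, 3))
  mc_v <- mc_propagate(specs_v, bg, tox, n_draws = 30000, seed = 14)
  vars <- apply(mc_v$er_samples, 2, var)
  expect_equal(mc_v$sensitivity$metal, names(sort(vars, decreasing = TRUE)))
})

test_that("per-metal distribution fitting records screening and covers the fixture", {
  specs <- fit_site_distributions(fixture_sites())
  expect_setequal(specs$metal, STUDY_METALS)
  expect_true(all(specs$family %in% c("normal", "lognormal")))
  expect_true(all(specs$scale > 0))
  expect_true(all(specs$n_used + lengths(specs$outliers) == 16))
  # spiking one site's As fractions flags that site as an outlier
  sites <- fixture_sites()
  sites$As_F2[4] <- sites$As_F2[4] * 80
  spiked <- fit_site_distributions(sites, metals = "As")
  expect_true(as.character(sites$site_id[4]) %in% spiked$outliers[[1]])
})
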