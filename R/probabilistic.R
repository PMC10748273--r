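#' Boxplot outlier screening
#'
#' Flags observations outside the Tukey fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles of type 7, R's default).
#' With fewer than four observations no screening is done and a warning is
#' issued. Retained values preserve input order.
#'
#' @param xs Numeric vector.
#' @param labels Optional labels (e.g. site ids) parallel to `xs`.
#' @return List with `retained`, `flagged` (values), `flagged_labels`, and
#'   the fences `lower`/`upper`.
#' @export
screen_outliers <- function(xs, labels = NULL) {
  stopifnot(is.numeric(xs))
  if (is.null(labels)) labels <- as.character(seq_along(xs))
  stopifnot(length(labels) == length(xs))
  if (length(xs) < 4) {
    warning("fewer than 4 observations; outlier screening skipped", call. = FALSE)
    return(list(retained = xs, flagged = numeric(), flagged_labels = character(),
                lower = -Inf, upper = Inf))
  }
  q <- stats::quantile(xs, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  out <- xs < lower | xs > upper
  list(retained = xs[!out], flagged = xs[out],
       flagged_labels = labels[out], lower = lower, upper = upper)
}

#' Fit a normal or lognormal distribution with Shapiro-Wilk selection
#'
#' Selection mirrors common practice for environmental concentration data:
#' the Shapiro-Wilk test is run on the raw values; if it does not reject at
#' `alpha` the normal family is kept (sample mean and sd). Otherwise the
#' test is rerun on the log values; if those pass, a lognormal fit (mean and
#' sd of logs) is returned. If neither passes, the family with the larger
#' p-value is kept and a warning is attached.
#'
#' For `n > 5000` (beyond the implemented range of [stats::shapiro.test()])
#' the test statistic is computed on 5000 evenly spaced order statistics, a
#' deterministic thinning that preserves the shape of the empirical
#' distribution.
#'
#' @param xs Numeric vector, `n >= 8` after `NA` removal.
#' @param alpha Significance level for the normality decision, default 0.05.
#' @return Object of class `"dist_spec"`: list with `family`
#'   (`"normal"`/`"lognormal"`), `location`, `scale` (on the family's
#'   natural scale: mean/sd of the values, or of their logs), `sw_p_raw`,
#'   `sw_p_log`, `n`, `neither_passed`.
#' @export
fit_distribution <- function(xs, alpha = 0.05) {
  xs <- xs[!is.na(xs)]
  if (length(xs) < 8) stop("need at least 8 observations to fit", call. = FALSE)
  if (stats::sd(xs) == 0) stop("degenerate (constant) sample", call. = FALSE)

  p_raw <- sw_pvalue(xs)
  p_log <- if (all(xs > 0)) sw_pvalue(log(xs)) else NA_real_

  neither <- FALSE
  if (p_raw >= alpha) {
    family <- "normal"
  } else if (!is.na(p_log) && p_log >= alpha) {
    family <- "lognormal"
  } else {
    if (is.na(p_log)) {
      if (any(xs <= 0)) {
        family <- "normal"
      } else {
        stop("no admissible family for the sample", call. = FALSE)
      }
    } else {
      family <- if (p_log > p_raw) "lognormal" else "normal"
    }
    neither <- TRUE
    warning("neither normal nor lognormal passed Shapiro-Wilk at alpha = ",
            alpha, "; keeping the better-fitting family (", family, ")",
            call. = FALSE)
  }

  if (family == "normal") {
    location <- mean(xs)
    scale <- stats::sd(xs)
  } else {
    lx <- log(xs)
    location <- mean(lx)
    scale <- stats::sd(lx)
  }
  structure(
    list(family = family, location = location, scale = scale,
         sw_p_raw = p_raw, sw_p_log = p_log, n = length(xs),
         neither_passed = neither),
    class = "dist_spec"
  )
}

sw_pvalue <- function(x) {
  if (length(x) > 5000) {
    idx <- unique(round(seq(1, length(x), length.out = 5000)))
    x <- sort(x)[idx]
  }
  stats::shapiro.test(x)$p.value
}

#' Fit per-metal distributions to corrected concentrations
#'
#' For each metal: compute the fraction-weighted corrected concentration
#' `Cr` at every site, screen boxplot outliers, and fit a normal or
#' lognormal distribution ([fit_distribution()]). These per-metal specs are
#' the random variables of the Monte Carlo stage.
#'
#' @param sites Site table with `<metal>_F1` ... `_F4` columns.
#' @param toxicity A [default_toxicity()] bundle (supplies `theta`).
#' @param metals Metals to fit; default: all with fraction columns.
#' @param alpha Normality significance level.
#' @param screen Apply boxplot outlier screening before fitting (default
#'   `TRUE`).
#' @return Tibble of class `"dist_spec_tbl"`: one row per metal with
#'   `family`, `location`, `scale`, `sw_p_raw`, `sw_p_log`, `n_used`,
#'   `outliers` (list column of flagged site ids).
#' @export
fit_site_distributions <- function(sites, toxicity = default_toxicity(),
                                   metals = NULL, alpha = 0.05, screen = TRUE) {
  stopifnot(is.data.frame(sites), "site_id" %in% names(sites))
  if (is.null(metals)) {
    metals <- sub("_F1$", "", grep("_F1$", names(sites), value = TRUE))
    if (all(metals %in% STUDY_METALS)) metals <- intersect(STUDY_METALS, metals)
  }
  rows <- purrr::map(metals, function(m) {
    fcols <- paste0(m, "_", FRACTIONS)
    miss <- setdiff(fcols, names(sites))
    if (length(miss)) {
      stop("missing fraction columns: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    cri <- corrected_concentration(sites[[fcols[1]]], sites[[fcols[2]]],
                                   sites[[fcols[3]]], sites[[fcols[4]]],
                                   theta = toxicity$theta)
    if (screen) {
      sc <- screen_outliers(cri, labels = as.character(sites$site_id))
      kept <- sc$retained
      flagged <- sc$flagged_labels
    } else {
      kept <- cri
      flagged <- character()
    }
    spec <- fit_distribution(kept, alpha = alpha)
    tibble::tibble(
      metal = m, family = spec$family,
      location = spec$location, scale = spec$scale,
      sw_p_raw = spec$sw_p_raw, sw_p_log = spec$sw_p_log,
      n_used = spec$n, outliers = list(flagged)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dist_spec_tbl", class(out))
  out
}

#' Monte Carlo propagation to the hazard indices
#'
#' The modified Hakanson-Monte Carlo model: each metal's corrected
#' concentration is a random variable (normal or lognormal, from a
#' `dist_spec_tbl`); per draw the secondary correction
#' `Cr' = |Cr - C0| + C0` folds the draw at background, then
#' `Er = Tr * Cr' / C0`, and `RI` is the sum across metals of the same
#' draw. Metals are sampled independently. Negative draws from a normal
#' family are rejected and redrawn (concentrations are non-negative); the
#' rejection count is retained.
#'
#' @param specs A `dist_spec_tbl` from [fit_site_distributions()], or any
#'   tibble with columns `metal`, `family`, `location`, `scale`. A zero
#'   `scale` is treated as a point mass.
#' @param backgrounds Named background vector `C0`, mg/kg.
#' @param toxicity A [default_toxicity()] bundle.
#' @param er_scheme,ri_scheme Grading schemes for the class-probability
#'   tables.
#' @param n_draws Number of Monte Carlo samplings, `>= 1000`; default
#'   50,000.
#' @param seed Integer seed; the result records it for exact replay.
#' @return Object of class `"mc_risk"`: list with `er_samples` (matrix,
#'   draws x metals), `ri_samples`, `n_draws`, `seed`, `rejected` (redrawn
#'   negatives per metal), `percentiles` (2.5/50/97.5 per metal and RI),
#'   `class_probs`, `sensitivity`, and the two schemes.
#' @export
mc_propagate <- function(specs, backgrounds = default_backgrounds("shaanxi"),
                         toxicity = default_toxicity(),
                         er_scheme = derive_er_scheme(toxicity),
                         ri_scheme = derive_ri_scheme(toxicity),
                         n_draws = 50000, seed = 1L) {
  stopifnot(is.data.frame(specs),
            all(c("metal", "family", "location", "scale") %in% names(specs)))
  if (n_draws < 1000) stop("`n_draws` must be at least 1000", call. = FALSE)
  metals <- specs$metal
  miss_bg <- setdiff(metals, names(backgrounds))
  if (length(miss_bg)) {
    stop("no background value for: ", paste(miss_bg, collapse = ", "), call. = FALSE)
  }
  miss_tr <- setdiff(metals, names(toxicity$tr))
  if (length(miss_tr)) {
    stop("no toxicity coefficient for: ", paste(miss_tr, collapse = ", "),
         call. = FALSE)
  }

  set.seed(as.integer(seed))
  rejected <- stats::setNames(integer(length(metals)), metals)
  er_samples <- matrix(NA_real_, nrow = n_draws, ncol = length(metals),
                       dimnames = list(NULL, metals))
  for (j in seq_along(metals)) {
    m <- metals[j]
    draws <- draw_nonnegative(specs$family[j], specs$location[j], specs$scale[j],
                              n_draws)
    rejected[m] <- attr(draws, "rejected")
    cri_prime <- secondary_correction(draws, backgrounds[[m]])
    er_samples[, j] <- single_hazard_index(
      contamination_factor(cri_prime, backgrounds[[m]]), toxicity$tr[[m]]
    )
  }
  ri_samples <- rowSums(er_samples)

  probs <- c(0.025, 0.5, 0.975)
  percentiles <- dplyr::bind_rows(
    purrr::map(metals, function(m) {
      q <- stats::quantile(er_samples[, m], probs, names = FALSE)
      tibble::tibble(variable = m, p2.5 = q[1], median = q[2], p97.5 = q[3],
                     mean = mean(er_samples[, m]))
    }),
    {
      q <- stats::quantile(ri_samples, probs, names = FALSE)
      tibble::tibble(variable = "RI", p2.5 = q[1], median = q[2], p97.5 = q[3],
                     mean = mean(ri_samples))
    }
  )

  class_probs <- dplyr::bind_rows(
    purrr::map(metals, function(m) {
      class_probabilities(er_samples[, m], er_scheme) |>
        dplyr::mutate(variable = m, .before = 1)
    }),
    class_probabilities(ri_samples, ri_scheme) |>
      dplyr::mutate(variable = "RI", .before = 1)
  )

  result <- structure(
    list(er_samples = er_samples, ri_samples = ri_samples,
         n_draws = n_draws, seed = as.integer(seed), rejected = rejected,
         specs = tibble::as_tibble(specs[, c("metal", "family", "location", "scale")]),
         percentiles = percentiles, class_probs = class_probs,
         er_scheme = er_scheme, ri_scheme = ri_scheme),
    class = "mc_risk"
  )
  # a pure point-mass model has no variance to attribute
  result$sensitivity <- if (stats::sd(ri_samples) > 0) {
    sensitivity_contributions(result)
  } else {
    NULL
  }
  result
}

draw_nonnegative <- function(family, location, scale, n) {
  if (scale == 0) {
    # point mass
    x <- rep(if (family == "lognormal") exp(location) else location, n)
    attr(x, "rejected") <- 0L
    return(x)
  }
  if (family == "lognormal") {
    x <- stats::rlnorm(n, meanlog = location, sdlog = scale)
    attr(x, "rejected") <- 0L
    return(x)
  }
  x <- stats::rnorm(n, location, scale)
  rejected <- 0L
  bad <- which(x < 0)
  while (length(bad)) {
    rejected <- rejected + length(bad)
    x[bad] <- stats::rnorm(length(bad), location, scale)
    bad <- bad[x[bad] < 0]
  }
  attr(x, "rejected") <- rejected
  x
}

#' Empirical risk-class probabilities
#'
#' Frequency of samples in each half-open class interval of a scheme.
#' Samples exactly on a boundary count toward the class above it.
#'
#' @param samples Non-empty numeric vector.
#' @param scheme A [risk_scheme()].
#' @return Tibble `class` (ordered factor), `probability`; probabilities
#'   sum to 1.
#' @export
class_probabilities <- function(samples, scheme) {
  stopifnot(length(samples) > 0, inherits(scheme, "risk_scheme"))
  cls <- classify(samples, scheme)
  tab <- table(cls) / length(samples)
  tibble::tibble(
    class = factor(scheme$labels, levels = scheme$labels, ordered = TRUE),
    probability = as.numeric(tab[scheme$labels])
  )
}

#' Empirical cumulative distribution of a sample
#'
#' Right-continuous empirical CDF over the sorted unique sample values.
#'
#' @param samples Non-empty numeric vector.
#' @return Tibble `value`, `cumulative` (reaching 1 at the maximum).
#' @export
cumulative_curve <- function(samples) {
  stopifnot(length(samples) > 0)
  v <- sort(unique(samples))
  f <- stats::ecdf(samples)
  tibble::tibble(value = v, cumulative = f(v))
}

#' Contribution-to-variance sensitivity
#'
#' Ranks the metals by their influence on the comprehensive index:
#' the squared Spearman rank correlation between each metal's Er samples
#' and the RI samples of the same draws, normalized to sum to 100%.
#' Point-mass inputs (zero variance) contribute 0.
#'
#' @param result An `"mc_risk"` object, or a list with `er_samples` (matrix)
#'   and `ri_samples`.
#' @return Tibble `metal`, `contribution` (percent, descending), summing to
#'   100.
#' @export
sensitivity_contributions <- function(result) {
  er <- result$er_samples
  ri <- result$ri_samples
  stopifnot(is.matrix(er), length(ri) == nrow(er))
  if (stats::sd(ri) == 0) {
    stop("RI samples have zero variance; sensitivity undefined", call. = FALSE)
  }
  rho2 <- apply(er, 2, function(x) {
    if (stats::sd(x) == 0) return(0)
    stats::cor(x, ri, method = "spearman")^2
  })
  tibble::tibble(metal = colnames(er),
                 contribution = as.numeric(100 * rho2 / sum(rho2))) |>
    dplyr::arrange(dplyr::desc(.data$contribution))
}

#' @export
print.mc_risk <- function(x, ...) {
  cat("<mc_risk> ", x$n_draws, " draws, seed ", x$seed, ", metals: ",
      paste(colnames(x$er_samples), collapse = ", "), "\n", sep = "")
  cat("RI mean ", format(mean(x$ri_samples), digits = 5), ", 95% band [",
      format(x$percentiles$p2.5[x$percentiles$variable == "RI"], digits = 5), ", ",
      format(x$percentiles$p97.5[x$percentiles$variable == "RI"], digits = 5),
      "]\n", sep = "")
  invisible(x)
}

#' Tidy a Monte Carlo risk result
#'
#' `tidy()` returns the class-probability table (one row per variable and
#' risk class); `glance()` returns a one-row summary of the run.
#'
#' @param x An `"mc_risk"` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mc_risk
#' @export
tidy.mc_risk <- function(x, ...) {
  x$class_probs
}

#' @rdname tidy.mc_risk
#' @method glance mc_risk
#' @export
glance.mc_risk <- function(x, ...) {
  ri <- x$percentiles[x$percentiles$variable == "RI", ]
  tibble::tibble(
    n_draws = x$n_draws, seed = x$seed,
    n_metals = ncol(x$er_samples),
    ri_mean = ri$mean, ri_median = ri$median,
    ri_p2.5 = ri$p2.5, ri_p97.5 = ri$p97.5,
    ri_modal_class = x$class_probs$class[
      x$class_probs$variable == "RI"
    ][which.max(x$class_probs$probability[x$class_probs$variable == "RI"])],
    rejected_draws = sum(x$rejected)
  )
}

#' Cumulative hazard-index curves
#'
#' Empirical cumulative distributions of each metal's Er and of RI, with
#' the class boundaries overlaid.
#'
#' @param object An `"mc_risk"` object.
#' @param ... Unused.
#' @return A ggplot object, one facet per variable (free x scales).
#' @method autoplot mc_risk
#' @export
autoplot.mc_risk <- function(object, ...) {
  metals <- colnames(object$er_samples)
  curves <- dplyr::bind_rows(
    purrr::map(metals, function(m) {
      cumulative_curve(object$er_samples[, m]) |>
        dplyr::mutate(variable = m)
    }),
    cumulative_curve(object$ri_samples) |> dplyr::mutate(variable = "RI")
  ) |>
    dplyr::mutate(variable = factor(.data$variable, levels = c(metals, "RI")))
  bounds <- dplyr::bind_rows(
    tidyr::expand_grid(variable = metals, boundary = object$er_scheme$boundaries),
    tibble::tibble(variable = "RI", boundary = object$ri_scheme$boundaries)
  ) |>
    dplyr::mutate(variable = factor(.data$variable, levels = c(metals, "RI")))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$value, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(data = bounds,
                        ggplot2::aes(xintercept = .data$boundary),
                        linetype = "dashed", color = "grey60") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = "hazard index", y = "cumulative probability") +
    ggplot2::theme_minimal()
}
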