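#' Geoaccumulation index
#'
#' `Igeo = log2(Cn / (1.5 * Bn))`, the base-2 log of the measured
#' concentration over 1.5 times the geochemical background. The factor 1.5
#' absorbs natural background fluctuation.
#'
#' @param cn Measured concentration, mg/kg, positive.
#' @param bn Background concentration, mg/kg, positive. Recycled against
#'   `cn`.
#' @return Numeric vector of index values.
#' @examples
#' geoaccumulation_index(96, 16) # log2(96 / 24) = 2
#' @export
geoaccumulation_index <- function(cn, bn) {
  if (any(!is.finite(cn)) || any(cn <= 0)) {
    stop("`cn` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(bn)) || any(bn <= 0)) {
    stop("`bn` must be finite and positive", call. = FALSE)
  }
  log2(cn / (1.5 * bn))
}

#' Fraction-weighted corrected concentration
#'
#' Collapses the four BCR fractions of a metal into a single
#' toxicity-weighted concentration:
#' `Cr = theta1*F1 + theta2*(F2 + F3) + theta3*F4`. The acid/water-soluble
#' fraction is weighted above unity, the reducible and oxidizable fractions
#' at unity, and the inert residual fraction below unity.
#'
#' @param f1,f2,f3,f4 Fraction concentrations, mg/kg, non-negative. Vectors
#'   are recycled to a common length.
#' @param theta Length-3 weights `(theta1, theta2, theta3)`; default from
#'   [default_toxicity()].
#' @return Corrected concentration(s), mg/kg.
#' @examples
#' corrected_concentration(10, 5, 5, 10) # 16 + 10 + 6 = 32
#' @export
corrected_concentration <- function(f1, f2, f3, f4,
                                    theta = default_toxicity()$theta) {
  fr <- cbind(f1, f2, f3, f4)
  if (any(!is.finite(fr)) || any(fr < 0)) {
    stop("fraction concentrations must be finite and non-negative", call. = FALSE)
  }
  stopifnot(length(theta) == 3)
  unname(theta[1] * fr[, 1] + theta[2] * (fr[, 2] + fr[, 3]) + theta[3] * fr[, 4])
}

#' Secondary correction of a corrected concentration
#'
#' Folds the corrected concentration at the background value:
#' `Cr' = |Cr - C0| + C0`. Sites whose fraction-weighted concentration falls
#' below background are reflected above it, so the downstream contamination
#' factor is always at least 1, as the Hakanson grading assumes.
#'
#' @param cri Corrected concentration, mg/kg, non-negative.
#' @param c0 Background reference, mg/kg, positive.
#' @return Concentration(s) `>= c0`.
#' @examples
#' secondary_correction(50, 67) # |50 - 67| + 67 = 84
#' @export
secondary_correction <- function(cri, c0) {
  if (any(!is.finite(cri)) || any(cri < 0)) {
    stop("`cri` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(c0)) || any(c0 <= 0)) {
    stop("`c0` must be finite and positive", call. = FALSE)
  }
  abs(cri - c0) + c0
}

#' Contamination factor
#'
#' Ratio of a (possibly fraction-corrected) concentration to its background
#' reference.
#'
#' @param conc Concentration, mg/kg, non-negative.
#' @param c0 Background reference, mg/kg, positive.
#' @return Dimensionless factor(s).
#' @export
contamination_factor <- function(conc, c0) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(c0)) || any(c0 <= 0)) {
    stop("`c0` must be finite and positive", call. = FALSE)
  }
  conc / c0
}

#' Single potential ecological hazard index
#'
#' `Er = Tr * Cf`: the contamination factor scaled by the metal's toxicity
#' response coefficient.
#'
#' @param cf Contamination factor(s), non-negative.
#' @param tr Toxicity response coefficient(s), positive.
#' @return Hazard index value(s).
#' @export
single_hazard_index <- function(cf, tr) {
  if (any(!is.finite(cf)) || any(cf < 0)) {
    stop("`cf` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(tr)) || any(tr <= 0)) {
    stop("`tr` must be finite and positive", call. = FALSE)
  }
  tr * cf
}

#' Comprehensive potential ecological hazard index
#'
#' `RI = sum(Er)` over the assessed metals of one site.
#'
#' @param ers Non-empty numeric vector of finite single hazard indices.
#' @return The exact sum.
#' @export
comprehensive_index <- function(ers) {
  if (length(ers) == 0) {
    stop("`ers` must contain at least one hazard index", call. = FALSE)
  }
  if (any(!is.finite(ers))) {
    stop("`ers` must be finite", call. = FALSE)
  }
  sum(ers)
}

#' Derive the single-index (Er) grading scheme
#'
#' Re-derives the Er risk classes for an arbitrary metal set: with no
#' contamination (`Cf = 1`) the largest possible Er equals the maximum
#' toxicity response coefficient, so that maximum is the lowest class limit;
#' successive limits double, the Hakanson convention.
#'
#' @param toxicity A [default_toxicity()] bundle (or any list with a `tr`
#'   vector).
#' @param n_classes Number of risk classes, `>= 2`; default 5
#'   (low ... very high).
#' @return A [risk_scheme()] of kind `"er"`.
#' @examples
#' derive_er_scheme(default_toxicity())$boundaries # 10 20 40 80
#' @export
derive_er_scheme <- function(toxicity = default_toxicity(), n_classes = 5) {
  tr <- toxicity$tr
  if (is.null(tr) || length(tr) == 0) {
    stop("`toxicity` carries no toxicity response coefficients", call. = FALSE)
  }
  stopifnot(n_classes >= 2)
  b1 <- max(tr)
  risk_scheme("er", risk_labels(n_classes), b1 * 2^(0:(n_classes - 2)))
}

#' Derive the comprehensive-index (RI) grading scheme
#'
#' Rescales the original eight-pollutant RI grading to the assessed metal
#' set: the unit toxicity coefficient (original lowest RI limit over the
#' original toxicity-coefficient total) is multiplied by the current
#' coefficient sum and rounded to the nearest multiple of ten to give the
#' lowest class limit; successive limits double.
#'
#' @inheritParams derive_er_scheme
#' @param constants A [hakanson_constants()] bundle.
#' @return A [risk_scheme()] of kind `"ri"`.
#' @examples
#' derive_ri_scheme(default_toxicity())$boundaries # 30 60 120 240
#' @export
derive_ri_scheme <- function(toxicity = default_toxicity(),
                             constants = hakanson_constants(),
                             n_classes = 5) {
  tr_sum <- sum(toxicity$tr)
  if (!is.finite(tr_sum) || tr_sum <= 0) {
    stop("toxicity coefficients must sum to a positive value", call. = FALSE)
  }
  stopifnot(n_classes >= 2)
  u <- constants$original_ri_lowest_limit / constants$original_toxicity_sum
  b1 <- round(u * tr_sum / 10) * 10
  risk_scheme("ri", risk_labels(n_classes), b1 * 2^(0:(n_classes - 2)))
}

#' Geoaccumulation assessment of a site table
#'
#' Computes the geoaccumulation index and pollution degree for every metal
#' at every site.
#'
#' @param sites Site table in the wide layout (see [read_sites()]): a
#'   `site_id` column plus `<metal>_total` columns.
#' @param backgrounds Named background vector, mg/kg (reference `Bn`).
#' @param scheme Pollution-degree scheme; default [igeo_scheme()].
#' @param metals Metals to assess; default: every metal with a total column
#'   covered by `backgrounds`.
#' @return Tibble with columns `site_id`, `metal`, `total`, `igeo`,
#'   `degree`.
#' @export
assess_igeo <- function(sites, backgrounds = default_backgrounds("shaanxi"),
                        scheme = igeo_scheme(), metals = NULL) {
  long <- sites_totals_long(sites, metals, names(backgrounds))
  long |>
    dplyr::mutate(
      igeo = geoaccumulation_index(.data$total, backgrounds[.data$metal]),
      degree = classify(.data$igeo, scheme)
    )
}

#' Hakanson risk assessment of a site table
#'
#' Runs the potential ecological risk index in one of two modes:
#'
#' * `"classic"` — the contamination factor is the measured total over
#'   background, `Cf = total / C0`; fractions are not used and no secondary
#'   correction is applied.
#' * `"modified"` — the four BCR fractions are collapsed to the
#'   toxicity-weighted corrected concentration, folded at background
#'   (`Cr' = |Cr - C0| + C0`), then `Cf = Cr' / C0`. Every `Cf` is then
#'   `>= 1` and every `Er >= Tr` by construction.
#'
#' Each metal's `Er = Tr * Cf` is classed against `er_scheme`; the per-site
#' `RI = sum(Er)` is classed against `ri_scheme` and repeated on each of the
#' site's rows.
#'
#' @param sites Site table in the wide layout; classic mode needs
#'   `<metal>_total` columns, modified mode needs `<metal>_F1` ... `_F4`.
#' @param mode `"modified"` or `"classic"`.
#' @param backgrounds Named background vector `C0`, mg/kg.
#' @param toxicity A [default_toxicity()] bundle.
#' @param er_scheme,ri_scheme Grading schemes; defaults derived from
#'   `toxicity` via [derive_er_scheme()] and [derive_ri_scheme()].
#' @param metals Metals to assess; default: all metals covered by both the
#'   site table and `backgrounds`.
#' @return Tibble with one row per site and metal: `site_id`, `metal`,
#'   `mode`, `total`, `cri`, `cri_prime` (both `NA` in classic mode), `cf`,
#'   `er`, `er_class`, `ri`, `ri_class`.
#' @export
assess_sites <- function(sites, mode = c("modified", "classic"),
                         backgrounds = default_backgrounds("shaanxi"),
                         toxicity = default_toxicity(),
                         er_scheme = derive_er_scheme(toxicity),
                         ri_scheme = derive_ri_scheme(toxicity),
                         metals = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(sites), "site_id" %in% names(sites))
  metals <- resolve_metals(sites, metals, names(backgrounds),
                           need_fractions = (mode == "modified"))
  missing_tr <- setdiff(metals, names(toxicity$tr))
  if (length(missing_tr)) {
    stop("no toxicity coefficient for: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }

  per_metal <- purrr::map(metals, function(m) {
    total_col <- paste0(m, "_total")
    total <- if (total_col %in% names(sites)) sites[[total_col]] else NA_real_
    if (mode == "classic") {
      if (!total_col %in% names(sites) || anyNA(sites[[total_col]])) {
        stop("classic mode needs complete `", total_col, "` values", call. = FALSE)
      }
      cri <- rep(NA_real_, nrow(sites))
      cri_prime <- rep(NA_real_, nrow(sites))
      cf <- contamination_factor(total, backgrounds[[m]])
    } else {
      fcols <- paste0(m, "_", FRACTIONS)
      miss <- setdiff(fcols, names(sites))
      if (length(miss)) {
        stop("modified mode needs fraction columns: ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      cri <- corrected_concentration(sites[[fcols[1]]], sites[[fcols[2]]],
                                     sites[[fcols[3]]], sites[[fcols[4]]],
                                     theta = toxicity$theta)
      cri_prime <- secondary_correction(cri, backgrounds[[m]])
      cf <- contamination_factor(cri_prime, backgrounds[[m]])
    }
    tibble::tibble(
      site_id = sites$site_id, metal = m, mode = mode,
      total = as.numeric(total), cri = cri, cri_prime = cri_prime,
      cf = cf, er = single_hazard_index(cf, toxicity$tr[[m]])
    )
  })

  dplyr::bind_rows(per_metal) |>
    dplyr::mutate(er_class = classify(.data$er, er_scheme)) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(ri = comprehensive_index(.data$er)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      ri_class = classify(.data$ri, ri_scheme),
      metal = factor(.data$metal, levels = metals)
    ) |>
    dplyr::arrange(match(.data$site_id, sites$site_id), .data$metal) |>
    dplyr::mutate(metal = as.character(.data$metal))
}

#' Per-site comprehensive index summary
#'
#' Collapses an [assess_sites()] table to one row per site.
#'
#' @param assessment Output of [assess_sites()].
#' @return Tibble `site_id`, `mode`, `ri`, `ri_class`.
#' @export
summarize_ri <- function(assessment) {
  assessment |>
    dplyr::distinct(.data$site_id, .data$mode, .data$ri, .data$ri_class)
}

# -- internal helpers ---------------------------------------------------------

resolve_metals <- function(sites, metals, covered, need_fractions = FALSE) {
  if (is.null(metals)) {
    suffix <- if (need_fractions) "_F1" else "_total"
    present <- sub(paste0(suffix, "$"), "",
                   grep(paste0(suffix, "$"), names(sites), value = TRUE))
    metals <- intersect(covered, present)
    # keep study order when applicable
    if (all(metals %in% STUDY_METALS)) metals <- intersect(STUDY_METALS, metals)
  }
  if (length(metals) == 0) {
    stop("no assessable metals found in the site table", call. = FALSE)
  }
  uncovered <- setdiff(metals, covered)
  if (length(uncovered)) {
    stop("no background value for: ", paste(uncovered, collapse = ", "),
         call. = FALSE)
  }
  metals
}

sites_totals_long <- function(sites, metals, covered) {
  stopifnot(is.data.frame(sites), "site_id" %in% names(sites))
  metals <- resolve_metals(sites, metals, covered)
  cols <- paste0(metals, "_total")
  miss <- setdiff(cols, names(sites))
  if (length(miss)) {
    stop("missing total columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  sites |>
    dplyr::select("site_id", dplyr::all_of(cols)) |>
    tidyr::pivot_longer(-"site_id", names_to = "metal", values_to = "total",
                        names_pattern = "(.*)_total") |>
    dplyr::mutate(metal = as.character(.data$metal)) |>
    dplyr::arrange(match(.data$site_id, sites$site_id), match(.data$metal, metals))
}
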