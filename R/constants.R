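#' Study metals
#'
#' The six heavy metals assessed in the reference gold-mine tailings study,
#' in the conventional reporting order. All functions accept any metal set;
#' this constant is the shipped default.
#'
#' @format Character vector of element symbols.
#' @export
STUDY_METALS <- c("Cr", "Ni", "Cu", "Zn", "As", "Pb")

#' Soil background concentrations
#'
#' Reference background concentrations (mg/kg) used by the index methods and
#' the exceedance screen. Two bundled sets:
#'
#' * `"shaanxi"` — Shaanxi Province soil environmental background values,
#'   used as the reference `C0` for the geoaccumulation index and both
#'   Hakanson modes.
#' * `"china"` — national mean soil background values (CNEMC 1990
#'   compilation), used only for exceedance-rate screening. These national
#'   means are standard literature values, not site measurements.
#'
#' The two roles are independent: pass whichever set a given screen calls
#' for, or a named numeric vector of your own.
#'
#' @param set `"shaanxi"` or `"china"`.
#' @return Named numeric vector, mg/kg, one entry per metal in
#'   [STUDY_METALS].
#' @examples
#' default_backgrounds("shaanxi")[["As"]]
#' @export
default_backgrounds <- function(set = c("shaanxi", "china")) {
  set <- match.arg(set)
  switch(set,
    shaanxi = c(Cr = 67.0, Ni = 33.9, Cu = 26.4, Zn = 72.2, As = 14.10, Pb = 17.0),
    china   = c(Cr = 61.0, Ni = 26.9, Cu = 22.6, Zn = 74.2, As = 11.2,  Pb = 26.0)
  )
}

#' Toxicity parameters for the Hakanson indices
#'
#' Bundles the metal-specific toxicity response coefficients `Tr` with the
#' fraction toxicity weights `theta` used by the corrected-concentration
#' formula. The default `Tr` set is Cr = 2, Ni = Cu = Pb = 5, Zn = 1,
#' As = 10; the default weights are (1.6, 1.0, 0.6) for the acid-soluble,
#' reducible + oxidizable, and residual fractions respectively. Weights must
#' be strictly decreasing and positive (mobile fractions weigh more).
#'
#' @param tr Named numeric vector of toxicity response coefficients, all
#'   positive.
#' @param theta Numeric length-3 vector `(theta1, theta2, theta3)` with
#'   `theta1 > theta2 > theta3 > 0`.
#' @return A list of class `"toxicity_params"` with elements `tr` and
#'   `theta`.
#' @export
default_toxicity <- function(tr = c(Cr = 2, Ni = 5, Cu = 5, Zn = 1, As = 10, Pb = 5),
                             theta = c(1.6, 1.0, 0.6)) {
  stopifnot(is.numeric(tr), length(tr) >= 1, !is.null(names(tr)))
  if (any(!is.finite(tr)) || any(tr <= 0)) {
    stop("all toxicity response coefficients must be finite and positive", call. = FALSE)
  }
  if (length(theta) != 3 || any(!is.finite(theta)) || any(theta <= 0) ||
      !(theta[1] > theta[2] && theta[2] > theta[3])) {
    stop("`theta` must be three positive weights with theta1 > theta2 > theta3", call. = FALSE)
  }
  structure(list(tr = tr, theta = unname(theta)), class = "toxicity_params")
}

#' Constants of the original Hakanson risk grading
#'
#' The original Hakanson scheme graded the comprehensive index RI for eight
#' pollutants whose toxicity coefficients sum to 133, with a lowest RI class
#' limit of 150. Dividing the two gives the unit toxicity coefficient used
#' to rescale the RI grading to any other pollutant set (see
#' [derive_ri_scheme()]).
#'
#' @param original_ri_lowest_limit Lowest RI class limit of the original
#'   eight-pollutant scheme.
#' @param original_toxicity_sum Toxicity-coefficient total of the original
#'   eight pollutants.
#' @return List of class `"hakanson_constants"`.
#' @export
hakanson_constants <- function(original_ri_lowest_limit = 150,
                               original_toxicity_sum = 133) {
  stopifnot(
    is.numeric(original_ri_lowest_limit), original_ri_lowest_limit > 0,
    is.numeric(original_toxicity_sum), original_toxicity_sum > 0
  )
  structure(
    list(
      original_ri_lowest_limit = original_ri_lowest_limit,
      original_toxicity_sum = original_toxicity_sum
    ),
    class = "hakanson_constants"
  )
}

# fraction column suffixes, in BCR order
FRACTIONS <- c("F1", "F2", "F3", "F4")

# default relative tolerance for the advisory fraction-sum vs total check,
# motivated by sequential-extraction recoveries of roughly 96-105%
MASS_BALANCE_TOL <- 0.15
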