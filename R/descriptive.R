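#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) over the mean, as a
#' percentage. Used as a proxy for spatial heterogeneity: larger values
#' indicate a more dispersed, anthropogenically influenced distribution.
#'
#' @param xs Numeric vector, `n >= 2`, non-zero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # 50
#' @export
coefficient_of_variation <- function(xs) {
  xs <- xs[!is.na(xs)]
  if (length(xs) < 2) stop("need at least two observations", call. = FALSE)
  m <- mean(xs)
  if (m == 0) stop("coefficient of variation undefined for zero mean", call. = FALSE)
  100 * stats::sd(xs) / m
}

#' Background exceedance rate
#'
#' Percentage of sampling points whose concentration strictly exceeds a
#' reference background value.
#'
#' @param concs Numeric vector of concentrations, `n >= 1`.
#' @param background Reference value, positive.
#' @return Percentage in `[0, 100]`.
#' @export
exceedance_rate <- function(concs, background) {
  concs <- concs[!is.na(concs)]
  stopifnot(length(concs) >= 1, is.finite(background), background > 0)
  100 * sum(concs > background) / length(concs)
}

#' Descriptive summary of metal totals
#'
#' Per-metal mean, standard deviation, range, coefficient of variation, and
#' exceedance rate against a reference background (conventionally the
#' national background set, see [default_backgrounds()]).
#'
#' @param sites Site table in the wide layout.
#' @param backgrounds Named background vector for the exceedance screen.
#' @param metals Metals to summarise; default: all covered metals.
#' @return Tibble with one row per metal: `metal`, `n`, `mean`, `sd`, `min`,
#'   `max`, `cv`, `background`, `mean_ratio`, `exceedance`.
#' @export
describe_metals <- function(sites, backgrounds = default_backgrounds("china"),
                            metals = NULL) {
  long <- sites_totals_long(sites, metals, names(backgrounds))
  long |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$total),
      sd = stats::sd(.data$total),
      min = min(.data$total),
      max = max(.data$total),
      cv = coefficient_of_variation(.data$total),
      background = backgrounds[[unique(.data$metal)]],
      mean_ratio = .data$mean / .data$background,
      exceedance = exceedance_rate(.data$total, .data$background),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metal, unique(long$metal)))
}

#' Fraction profile of one metal
#'
#' Expresses the four BCR fractions as percentages of their sum and ranks
#' them. Ties keep the BCR order F1, F2, F3, F4 (stable sort).
#'
#' @param f1,f2,f3,f4 Fraction concentrations, mg/kg, non-negative scalars
#'   with a positive sum.
#' @return Tibble with columns `fraction`, `concentration`, `percent`,
#'   `rank` (1 = dominant).
#' @examples
#' fraction_profile(10, 5, 5, 80)
#' @export
fraction_profile <- function(f1, f2, f3, f4) {
  fr <- c(f1, f2, f3, f4)
  if (length(fr) != 4 || any(!is.finite(fr)) || any(fr < 0)) {
    stop("need four finite non-negative fraction values", call. = FALSE)
  }
  s <- sum(fr)
  if (s <= 0) stop("fraction sum must be positive", call. = FALSE)
  pct <- 100 * fr / s
  tibble::tibble(
    fraction = FRACTIONS,
    concentration = fr,
    percent = pct,
    rank = rank(-pct, ties.method = "first")
  )
}

#' Site-by-metal fraction profiles
#'
#' Long table of per-site fraction percentages for every metal with
#' fraction columns, plus `mean_fraction_profile()` for the study-level
#' mean profile.
#'
#' @param sites Site table in the wide layout with `<metal>_F1` ... `_F4`
#'   columns.
#' @param metals Metals to profile; default: all with fraction columns.
#' @return Tibble `site_id`, `metal`, `fraction`, `concentration`,
#'   `percent`.
#' @export
fraction_profiles <- function(sites, metals = NULL) {
  stopifnot(is.data.frame(sites), "site_id" %in% names(sites))
  if (is.null(metals)) {
    metals <- sub("_F1$", "", grep("_F1$", names(sites), value = TRUE))
    if (all(metals %in% STUDY_METALS)) metals <- intersect(STUDY_METALS, metals)
  }
  if (length(metals) == 0) stop("no fraction columns found", call. = FALSE)
  cols <- as.vector(outer(metals, FRACTIONS, paste, sep = "_"))
  miss <- setdiff(cols, names(sites))
  if (length(miss)) {
    stop("missing fraction columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  long <- sites |>
    dplyr::select("site_id", dplyr::all_of(cols)) |>
    tidyr::pivot_longer(-"site_id",
                        names_to = c("metal", "fraction"), names_sep = "_",
                        values_to = "concentration")
  long |>
    dplyr::group_by(.data$site_id, .data$metal) |>
    dplyr::mutate(percent = 100 * .data$concentration / sum(.data$concentration)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$site_id, sites$site_id),
                   match(.data$metal, metals), .data$fraction)
}

#' @rdname fraction_profiles
#' @details `mean_fraction_profile()` ranks the fractions by their mean
#'   contents across sites (each fraction's mean concentration as a share of
#'   the summed means), the convention of survey reports; this is not the
#'   same as averaging per-site percentages, which is dominated by extreme
#'   sites when a fraction is strongly right-skewed.
#' @return `mean_fraction_profile()`: tibble `metal`, `fraction`,
#'   `mean_concentration`, `mean_percent`, `rank` (1 = dominant).
#' @export
mean_fraction_profile <- function(sites, metals = NULL) {
  fraction_profiles(sites, metals) |>
    dplyr::group_by(.data$metal, .data$fraction) |>
    dplyr::summarise(mean_concentration = mean(.data$concentration),
                     .groups = "drop_last") |>
    dplyr::mutate(
      mean_percent = 100 * .data$mean_concentration / sum(.data$mean_concentration),
      rank = rank(-.data$mean_percent, ties.method = "first")
    ) |>
    dplyr::ungroup()
}

#' Correlation screen between two column blocks
#'
#' Pairwise correlations (Pearson by default, Spearman optionally) between
#' an x-block (e.g. fraction concentrations) and a y-block (e.g. soil
#' physicochemical properties), with two-sided p-values and conventional
#' significance stars at p <= 0.05 (`*`) and p <= 0.01 (`**`). Missing
#' values are handled pairwise-complete. Zero-variance pairs are flagged
#' (`NA` estimates), not fatal. No multiplicity correction is applied.
#'
#' @param data Data frame holding both blocks.
#' @param x_cols,y_cols Character vectors of column names.
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble `x`, `y`, `n`, `r`, `p`, `signif` (`"ns"`, `"*"`, `"**"`).
#' @export
correlation_screen <- function(data, x_cols, y_cols,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(x_cols, y_cols), names(data))
  if (length(miss)) {
    stop("columns not found: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  grid <- tidyr::expand_grid(x = x_cols, y = y_cols)
  res <- purrr::pmap(grid, function(x, y) {
    ok <- stats::complete.cases(data[[x]], data[[y]])
    xv <- data[[x]][ok]
    yv <- data[[y]][ok]
    n <- length(xv)
    if (n < 5) stop("need at least 5 paired observations for ", x, " vs ", y,
                    call. = FALSE)
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      warning("zero variance in pair ", x, " vs ", y, "; estimate flagged NA",
              call. = FALSE)
      return(tibble::tibble(n = n, r = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(xv, yv, method = method,
                                           alternative = "two.sided"))
    tibble::tibble(n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res)) |>
    dplyr::mutate(signif = dplyr::case_when(
      is.na(.data$p) ~ NA_character_,
      .data$p <= 0.01 ~ "**",
      .data$p <= 0.05 ~ "*",
      TRUE ~ "ns"
    ))
}

#' Heat-map of a correlation screen
#'
#' @param screen Output of [correlation_screen()].
#' @return A ggplot object.
#' @export
plot_correlation_screen <- function(screen) {
  ggplot2::ggplot(screen, ggplot2::aes(x = .data$y, y = .data$x, fill = .data$r)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$r), "",
                     paste0(sprintf("%.2f", .data$r),
                            ifelse(.data$signif %in% c("*", "**"), .data$signif, "")))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Stacked fraction-profile bar chart
#'
#' @param profiles Output of [fraction_profiles()].
#' @return A ggplot object, one facet per metal.
#' @export
plot_fraction_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$site_id, y = .data$percent,
                               fill = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metal) +
    ggplot2::labs(x = "site", y = "share of fraction sum (%)", fill = "BCR fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
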