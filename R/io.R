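#' Read a site table
#'
#' Reads the wide delimited layout: one row per sampling point, a mandatory
#' `site_id` column, `<metal>_total` columns (mg/kg), optional
#' `<metal>_F1` ... `<metal>_F4` BCR fraction columns (mg/kg), and optional
#' property columns. All concentration columns must be numeric and
#' non-negative; duplicate site ids are rejected. When a metal carries both
#' a total and all four fractions, a fraction-sum vs total disagreement
#' beyond `mass_balance_tol` raises a warning (never a rejection — recovery
#' of a sequential extraction is not exact).
#'
#' @param path CSV file path.
#' @param mass_balance_tol Advisory relative tolerance for
#'   `|fraction_sum / total - 1|`; default 0.15.
#' @return Site tibble.
#' @export
read_sites <- function(path, mass_balance_tol = MASS_BALANCE_TOL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sites <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sites(sites, mass_balance_tol)
  sites
}

#' @rdname read_sites
#' @param sites Site tibble to write.
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  readr::write_csv(sites, path)
  invisible(path)
}

validate_sites <- function(sites, mass_balance_tol = MASS_BALANCE_TOL) {
  stopifnot(is.data.frame(sites))
  if (!"site_id" %in% names(sites)) {
    stop("site table needs a `site_id` column", call. = FALSE)
  }
  dup <- sites$site_id[duplicated(sites$site_id)]
  if (length(dup)) {
    stop("duplicate site ids: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  conc_cols <- grep("_(total|F[1-4])$", names(sites), value = TRUE)
  for (col in conc_cols) {
    v <- sites[[col]]
    if (!is.numeric(v)) {
      stop("column `", col, "` is not numeric", call. = FALSE)
    }
    bad <- which(v < 0)
    if (length(bad)) {
      stop("negative concentration at site ", sites$site_id[bad[1]],
           ", column `", col, "`", call. = FALSE)
    }
  }
  # advisory mass-balance check
  metals <- sub("_total$", "", grep("_total$", names(sites), value = TRUE))
  for (m in metals) {
    fcols <- paste0(m, "_", FRACTIONS)
    if (!all(fcols %in% names(sites))) next
    fsum <- rowSums(sites[fcols])
    tot <- sites[[paste0(m, "_total")]]
    ok <- is.finite(fsum) & is.finite(tot) & tot > 0
    off <- which(ok & abs(fsum / tot - 1) > mass_balance_tol)
    if (length(off)) {
      warning("fraction sum of ", m, " differs from the total by more than ",
              round(100 * mass_balance_tol), "% at site(s) ",
              paste(sites$site_id[off], collapse = ", "), call. = FALSE)
    }
  }
  invisible(sites)
}

#' Percentage of sites per risk class
#'
#' The class-share tables reported alongside the indices: for each metal the
#' percentage of sites in each Er class, plus one row set for the RI
#' classes.
#'
#' @param assessment Output of [assess_sites()].
#' @return Tibble `variable` (metal or `"RI"`), `class`, `percent`.
#' @export
class_percentages <- function(assessment) {
  er_part <- assessment |>
    dplyr::count(.data$metal, .data$er_class, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$metal) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::transmute(variable = .data$metal,
                     class = .data$er_class, percent = .data$percent)
  ri_part <- summarize_ri(assessment) |>
    dplyr::count(.data$ri_class, .drop = FALSE, name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::transmute(variable = "RI", class = .data$ri_class,
                     percent = .data$percent)
  dplyr::bind_rows(er_part, ri_part)
}

#' Run the full assessment pipeline
#'
#' Descriptive screening, geoaccumulation index, Hakanson assessment in one
#' or both modes, and (optionally) the Monte Carlo propagation on the
#' modified-mode corrected concentrations, assembled into one report
#' bundle. All resolved parameters and per-stage diagnostics (outliers
#' flagged, distribution decisions, rejected draws) are recorded in the
#' bundle's `log`.
#'
#' @param sites Site tibble (see [read_sites()]).
#' @param mode `"modified"`, `"classic"`, or `"both"`.
#' @param mc Run the Monte Carlo stage (needs fraction columns).
#' @param n_draws,seed,alpha Monte Carlo settings (see [mc_propagate()] and
#'   [fit_site_distributions()]).
#' @param backgrounds Named background vector for the index methods
#'   (reference `C0`/`Bn`).
#' @param exceedance_backgrounds Named background vector for the exceedance
#'   screen; an independent role from `backgrounds`.
#' @param toxicity A [default_toxicity()] bundle.
#' @param out_dir If non-`NULL`, the report tables are written there as CSV
#'   files plus a plain-text run log.
#' @return List of class `"risk_report"`: `description`, `mean_profile`,
#'   `igeo`, `classic`, `modified`, `class_percentages`, `mc` (an
#'   `"mc_risk"` or `NULL`), `log`.
#' @export
run_pipeline <- function(sites, mode = c("both", "modified", "classic"),
                         mc = TRUE, n_draws = 50000, seed = 1L, alpha = 0.05,
                         backgrounds = default_backgrounds("shaanxi"),
                         exceedance_backgrounds = default_backgrounds("china"),
                         toxicity = default_toxicity(), out_dir = NULL) {
  mode <- match.arg(mode)
  validate_sites(sites)
  has_totals <- any(grepl("_total$", names(sites)))
  has_fractions <- any(grepl("_F1$", names(sites)))
  if (mode %in% c("both", "classic") && !has_totals) {
    stop("classic mode needs `<metal>_total` columns", call. = FALSE)
  }
  if (mode %in% c("both", "modified") && !has_fractions) {
    stop("modified mode needs `<metal>_F1`..`_F4` columns", call. = FALSE)
  }

  er_scheme <- derive_er_scheme(toxicity)
  ri_scheme <- derive_ri_scheme(toxicity)

  report <- list(
    description = if (has_totals) describe_metals(sites, exceedance_backgrounds) else NULL,
    mean_profile = if (has_fractions) mean_fraction_profile(sites) else NULL,
    igeo = if (has_totals) assess_igeo(sites, backgrounds) else NULL,
    classic = NULL, modified = NULL, mc = NULL
  )
  if (mode %in% c("both", "classic")) {
    report$classic <- assess_sites(sites, "classic", backgrounds, toxicity,
                                   er_scheme, ri_scheme)
  }
  if (mode %in% c("both", "modified")) {
    report$modified <- assess_sites(sites, "modified", backgrounds, toxicity,
                                    er_scheme, ri_scheme)
  }
  cp <- purrr::compact(list(
    classic = if (!is.null(report$classic)) class_percentages(report$classic),
    modified = if (!is.null(report$modified)) class_percentages(report$modified)
  ))
  report$class_percentages <- dplyr::bind_rows(cp, .id = "mode")

  specs <- NULL
  if (mc) {
    if (!has_fractions) stop("the Monte Carlo stage needs fraction columns", call. = FALSE)
    specs <- fit_site_distributions(sites, toxicity, alpha = alpha)
    report$mc <- mc_propagate(specs, backgrounds, toxicity, er_scheme, ri_scheme,
                              n_draws = n_draws, seed = seed)
  }

  report$log <- list(
    mode = mode, seed = as.integer(seed), n_draws = if (mc) n_draws else NA,
    alpha = alpha, theta = toxicity$theta, tr = toxicity$tr,
    backgrounds = backgrounds, exceedance_backgrounds = exceedance_backgrounds,
    er_boundaries = er_scheme$boundaries, ri_boundaries = ri_scheme$boundaries,
    distribution_fits = specs,
    rejected_draws = if (mc) report$mc$rejected else NULL
  )
  class(report) <- "risk_report"

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report> stages:",
      paste(names(purrr::compact(unclass(x)[c("description", "mean_profile",
                                              "igeo", "classic", "modified",
                                              "mc")])), collapse = ", "), "\n")
  if (!is.null(x$mc)) print(x$mc)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tbl, name) {
    if (!is.null(tbl)) readr::write_csv(tbl, file.path(out_dir, paste0(name, ".csv")))
  }
  emit(report$description, "description")
  emit(report$mean_profile, "mean_fraction_profile")
  emit(report$igeo, "igeo")
  emit(report$classic, "assessment_classic")
  emit(report$modified, "assessment_modified")
  emit(report$class_percentages, "class_percentages")
  if (!is.null(report$mc)) {
    emit(report$mc$percentiles, "mc_percentiles")
    emit(report$mc$class_probs, "mc_class_probabilities")
    emit(report$mc$sensitivity, "mc_sensitivity")
  }
  log <- report$log
  fmt <- function(x) {
    paste(vapply(x, function(v) format(v, digits = 10, trim = TRUE), ""),
          collapse = " ")
  }
  lines <- c(
    paste0("mode: ", log$mode),
    paste0("seed: ", log$seed),
    paste0("n_draws: ", log$n_draws),
    paste0("alpha: ", log$alpha),
    paste0("theta: ", fmt(log$theta)),
    paste0("tr: ", paste(names(log$tr), log$tr, sep = "=", collapse = " ")),
    paste0("backgrounds: ",
           paste(names(log$backgrounds), log$backgrounds, sep = "=", collapse = " ")),
    paste0("exceedance_backgrounds: ",
           paste(names(log$exceedance_backgrounds), log$exceedance_backgrounds,
                 sep = "=", collapse = " ")),
    paste0("er_boundaries: ", fmt(log$er_boundaries)),
    paste0("ri_boundaries: ", fmt(log$ri_boundaries))
  )
  if (!is.null(log$distribution_fits)) {
    lines <- c(lines, "distribution_fits:",
               utils::capture.output(as.data.frame(
                 log$distribution_fits[, c("metal", "family", "location",
                                           "scale", "n_used")]
               )))
    out <- purrr::map_chr(seq_len(nrow(log$distribution_fits)), function(i) {
      o <- log$distribution_fits$outliers[[i]]
      paste0("  outliers ", log$distribution_fits$metal[i], ": ",
             if (length(o)) paste(o, collapse = ", ") else "none")
    })
    lines <- c(lines, out)
  }
  if (!is.null(log$rejected_draws)) {
    lines <- c(lines, paste0("rejected_draws: ",
                             paste(names(log$rejected_draws), log$rejected_draws,
                                   sep = "=", collapse = " ")))
  }
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
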