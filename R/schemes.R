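#' Build a risk/pollution classification scheme
#'
#' A scheme is an ordered set of class labels separated by strictly
#' increasing numeric boundaries. Intervals are half-open `[lower, upper)`:
#' the first class is `(-Inf, b1)`, the last `[b_last, Inf)`, and a value
#' exactly on a boundary belongs to the class above it.
#'
#' @param kind Scheme family, one of `"igeo"`, `"er"`, `"ri"` (free-form
#'   strings are accepted for reuse).
#' @param labels Ordered character vector of class names.
#' @param boundaries Strictly increasing numeric cut points;
#'   `length(labels) == length(boundaries) + 1`.
#' @return Object of class `"risk_scheme"`.
#' @seealso [classify()], [igeo_scheme()], [derive_er_scheme()],
#'   [derive_ri_scheme()]
#' @export
risk_scheme <- function(kind, labels, boundaries) {
  stopifnot(is.character(kind), length(kind) == 1, nzchar(kind))
  boundaries <- as.numeric(boundaries)
  if (any(!is.finite(boundaries))) {
    stop("scheme boundaries must be finite", call. = FALSE)
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("scheme boundaries must be strictly increasing", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != length(boundaries) + 1) {
    stop("need exactly one more label than boundaries", call. = FALSE)
  }
  structure(list(kind = kind, labels = labels, boundaries = boundaries),
            class = "risk_scheme")
}

#' @export
print.risk_scheme <- function(x, ...) {
  cat("<risk_scheme:", x$kind, ">\n")
  lo <- c(-Inf, x$boundaries)
  hi <- c(x$boundaries, Inf)
  for (i in seq_along(x$labels)) {
    cat(sprintf("  [%g, %g)  %s\n", lo[i], hi[i], x$labels[i]))
  }
  invisible(x)
}

#' Geoaccumulation-index pollution scheme
#'
#' Seven pollution degrees separated at Igeo = 0, 1, 2, 3, 4, 5, from
#' "Unpolluted" up to "Extremely polluted".
#'
#' @return A [risk_scheme()] of kind `"igeo"`.
#' @export
igeo_scheme <- function() {
  risk_scheme(
    "igeo",
    c("Unpolluted", "Lightly polluted", "Moderately polluted",
      "Moderately to heavily polluted", "Heavily polluted",
      "Heavily to extremely polluted", "Extremely polluted"),
    0:5
  )
}

# canonical five risk-degree labels, low to very high
ER_RI_LABELS <- c("low", "moderate", "considerable", "high", "very high")

risk_labels <- function(n_classes) {
  if (n_classes <= length(ER_RI_LABELS)) {
    c(ER_RI_LABELS[seq_len(n_classes - 1)], ER_RI_LABELS[length(ER_RI_LABELS)])
  } else {
    c(ER_RI_LABELS, paste("class", seq.int(length(ER_RI_LABELS) + 1, n_classes)))
  }
}

#' Classify values against a scheme
#'
#' Assigns each value the unique label of the half-open interval
#' `[lower, upper)` that contains it. A value exactly on a boundary gets the
#' label of the interval whose lower edge it is.
#'
#' @param value Numeric vector, all finite.
#' @param scheme A [risk_scheme()].
#' @return Factor with the scheme's labels as ordered levels, same length as
#'   `value`.
#' @examples
#' classify(c(-0.17, 5.68), igeo_scheme())
#' @export
classify <- function(value, scheme) {
  stopifnot(inherits(scheme, "risk_scheme"))
  if (length(value) == 0) {
    return(factor(character(), levels = scheme$labels, ordered = TRUE))
  }
  if (any(!is.finite(value))) {
    stop("cannot classify non-finite values", call. = FALSE)
  }
  idx <- findInterval(value, scheme$boundaries) + 1L
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}
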