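#' Define a mock-community expected composition
#'
#' @param fractions Named numeric vector (taxon label -> expected fraction)
#'   summing to 1.
#' @return An object of class `"mock_composition"`.
#' @export
mock_composition <- function(fractions) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (anyDuplicated(names(fractions))) stop("duplicate labels", call. = FALSE)
  if (any(fractions < 0)) stop("negative fractions", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  structure(list(fractions = fractions), class = "mock_composition")
}

#' Even eight-genus bacterial mock composition
#'
#' A synthetic stand-in for the theoretical composition of the ZymoBIOMICS
#' bacterial standard: the eight bacterial genera at equal 12.5% fractions.
#' The vendor's exact certified fractions are lot-specific; supply them via
#' [mock_composition()] when available.
#'
#' @return A `"mock_composition"` over the eight genera.
#' @export
zymo_mock_composition <- function() {
  genera <- c("Bacillus", "Enterococcus", "Escherichia", "Lactobacillus",
              "Listeria", "Pseudomonas", "Salmonella", "Staphylococcus")
  mock_composition(stats::setNames(rep(1 / 8, 8L), genera))
}

observed_fractions <- function(observed) {
  if (inherits(observed, "taxon_profile")) {
    v <- observed$relative %||% (observed$counts / sum(observed$counts))
  } else {
    stopifnot(is.numeric(observed), !is.null(names(observed)))
    v <- observed / sum(observed)
  }
  v
}

#' Pearson concordance between expected and observed composition
#'
#' Takes the union of taxon labels, imputing 0 for taxa absent from either
#' side, and returns the Pearson correlation of the two fraction vectors.
#' Invariant to uniform rescaling of the observed counts.
#'
#' @param expected A [mock_composition()].
#' @param observed A [taxon_profile()] or named numeric vector of counts or
#'   fractions.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_concordance <- function(expected, observed) {
  stopifnot(inherits(expected, "mock_composition"))
  obs <- observed_fractions(observed)
  labels <- union(names(expected$fractions), names(obs))
  e <- o <- stats::setNames(numeric(length(labels)), labels)
  e[names(expected$fractions)] <- expected$fractions
  o[names(obs)] <- obs
  if (stats::sd(e) == 0 || stats::sd(o) == 0) {
    stop("zero variance: Pearson correlation undefined", call. = FALSE)
  }
  stats::cor(e, o)
}

total_variation <- function(expected, observed) {
  obs <- observed_fractions(observed)
  labels <- union(names(expected$fractions), names(obs))
  e <- o <- stats::setNames(numeric(length(labels)), labels)
  e[names(expected$fractions)] <- expected$fractions
  o[names(obs)] <- obs
  sum(abs(e - o)) / 2
}

#' Mock-community recovery report across primer sets
#'
#' For each primer set, the Pearson concordance with the expected
#' composition and the total-variation distance (half the L1 distance of
#' the fraction vectors, a bounded complement to r). Rows are ordered by
#' decreasing r, ties broken by increasing total-variation distance, then
#' by primer name — a deterministic total order.
#'
#' @param expected A [mock_composition()].
#' @param observed Named list, primer set -> observed profile.
#' @return Data frame `primer_set`, `pearson_r`, `tv_distance`, ordered
#'   best-first.
#' @export
recovery_report <- function(expected, observed) {
  stopifnot(length(observed) >= 1L, !is.null(names(observed)))
  r <- vapply(observed, function(o) pearson_concordance(expected, o),
              numeric(1L))
  tv <- vapply(observed, function(o) total_variation(expected, o), numeric(1L))
  out <- data.frame(primer_set = names(observed), pearson_r = r,
                    tv_distance = tv, row.names = NULL)
  out[order(-out$pearson_r, out$tv_distance, out$primer_set), , drop = FALSE]
}
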