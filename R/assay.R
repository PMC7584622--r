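#' Chemotaxis response index
#'
#' Plate-gradient metric `RI = D1 / (D1 + D2)` where `D1` is the distance
#' from the inoculation site to the colony edge closest to the attractant
#' spot and `D2` to the edge furthest from it. Vectorized.
#'
#' @param D1,D2 Non-negative distances (mm); `D1 + D2` must be positive.
#' @return Numeric response index in `[0, 1]`.
#' @export
response_index <- function(D1, D2) {
  if (any(D1 < 0 | D2 < 0)) abort("distances must be non-negative")
  if (any(D1 + D2 == 0)) abort("D1 + D2 must be positive")
  D1 / (D1 + D2)
}

#' Chemotaxis call from a response index
#'
#' Strictly greater than 0.52 scores as chemoattraction.
#'
#' @param ri Response index values.
#' @param threshold Decision threshold (default 0.52).
#' @return Logical vector.
#' @export
is_chemotactic <- function(ri, threshold = 0.52) {
  ri > threshold
}

#' Background-corrected capillary count
#'
#' Subtracts the cells that swam into buffer-only capillaries; negative raw
#' differences are floored at zero and flagged.
#'
#' @param treatment_cfu,buffer_cfu Non-negative CFU counts (vectorized).
#' @return Tibble with `net_cfu` and `flagged` (TRUE where the raw
#'   difference was negative).
#' @export
capillary_net_count <- function(treatment_cfu, buffer_cfu) {
  if (any(treatment_cfu < 0 | buffer_cfu < 0)) abort("counts must be non-negative")
  raw <- treatment_cfu - buffer_cfu
  tibble(net_cfu = pmax(raw, 0), flagged = raw < 0)
}

#' Fold induction over background
#'
#' @param signal Measured signal (e.g. bioluminescence).
#' @param background Strictly positive background level.
#' @return `signal / background`.
#' @export
fold_induction <- function(signal, background) {
  if (any(background <= 0)) abort("background must be positive")
  signal / background
}

#' Dose with maximal response
#'
#' Argmax over a dose-response series; ties go to the lower dose.
#'
#' @param dose,response Equal-length numeric vectors; `dose` non-empty.
#' @return The dose at the maximum response.
#' @export
optimal_dose <- function(dose, response) {
  if (length(dose) == 0 || length(dose) != length(response)) {
    abort("dose and response must be non-empty and of equal length")
  }
  peak <- max(response)
  min(dose[response == peak])
}
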