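#' Unit conversion constants and helpers
#'
#' All internal computation uses mg/L of elemental magnesium and hours.
#' Serum magnesium is conventionally reported in mmol/L; doses are labelled
#' in grams of the magnesium sulfate salt. Two constants bridge the units:
#'
#' * `MG_PER_MMOL` — 24.305 mg elemental Mg per mmol (atomic weight of Mg),
#'   so 1 mmol/L = 24.305 mg/L.
#' * `MG_PER_G_MGSO4_7H2O` — mg elemental Mg per labelled gram of
#'   MgSO4.7H2O (MW 246.47): 1000 * 24.305 / 246.47 = 98.61 mg/g. The
#'   heptahydrate is the form dispensed for intravenous use; the salt factor
#'   is configurable everywhere it is consumed in case another form is
#'   modelled.
#'
#' @name units
NULL

#' @rdname units
#' @export
MG_PER_MMOL <- 24.305

#' @rdname units
#' @export
MG_PER_G_MGSO4_7H2O <- 1000 * 24.305 / 246.47

#' Convert between mmol/L and mg/L elemental magnesium
#'
#' @param x numeric vector of concentrations.
#' @return numeric vector in the other unit.
#' @examples
#' mmol_to_mg(2)    # lower edge of the therapeutic window, in mg/L
#' mg_to_mmol(48.61)
#' @export
mmol_to_mg <- function(x) x * MG_PER_MMOL

#' @rdname mmol_to_mg
#' @export
mg_to_mmol <- function(x) x / MG_PER_MMOL

#' Therapeutic window for seizure prophylaxis, in mmol/L
#'
#' The target serum magnesium range 2.0-3.5 mmol/L used for probability of
#' target attainment.
#' @export
THERAPEUTIC_WINDOW_MMOL <- c(2.0, 3.5)
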