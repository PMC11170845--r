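#' Dose events, regimens and PK parameter sets
#'
#' A `dose_event` is a single constant-rate intravenous infusion: `start`
#' (hours since study start), `grams` (labelled grams of magnesium sulfate
#' salt) and `duration` (hours, strictly positive; bolus dosing is not used
#' for seizure prophylaxis). A `regimen` is an ordered list of dose events
#' plus the salt factor converting labelled grams to mg of elemental Mg.
#'
#' @param start infusion start time, hours (>= 0).
#' @param grams labelled grams of MgSO4 salt (>= 0).
#' @param duration infusion duration in hours (> 0).
#' @return `dose_event()` returns a list with class `"mg_dose_event"`.
#' @export
dose_event <- function(start, grams, duration) {
  stopifnot(is.finite(start), start >= 0,
            is.finite(grams), grams >= 0,
            is.finite(duration), duration > 0)
  structure(list(start = start, grams = grams, duration = duration),
            class = "mg_dose_event")
}

#' @rdname dose_event
#' @param events list of `dose_event` objects (any order; sorted on creation).
#' @param salt_factor mg elemental Mg per labelled gram of salt
#'   (default: heptahydrate, [MG_PER_G_MGSO4_7H2O]).
#' @return `regimen()` returns a list with class `"mg_regimen"`.
#' @examples
#' reg <- regimen(list(
#'   dose_event(0, 5, 1/3),        # 5 g loading over 20 min
#'   dose_event(1/3, 10, 6.7)      # 10 g maintenance over 6.7 h
#' ))
#' @export
regimen <- function(events = list(), salt_factor = MG_PER_G_MGSO4_7H2O) {
  stopifnot(is.list(events), is.finite(salt_factor), salt_factor > 0)
  for (e in events) stopifnot(inherits(e, "mg_dose_event"))
  if (length(events) > 1) {
    ord <- order(vapply(events, `[[`, numeric(1), "start"))
    events <- events[ord]
  }
  structure(list(events = events, salt_factor = salt_factor),
            class = "mg_regimen")
}

#' @rdname dose_event
#' @param CL clearance, L/h (> 0).
#' @param V volume of distribution, L (> 0).
#' @param baseline endogenous serum magnesium in the model's concentration
#'   unit (mg/L internally); added to every prediction.
#' @return `pk_params()` returns a list with class `"mg_pk_params"`.
#' @export
pk_params <- function(CL, V, baseline = 0) {
  if (!is.finite(CL) || CL <= 0 || !is.finite(V) || V <= 0)
    stop("CL and V must be finite and strictly positive")
  if (!is.finite(baseline) || baseline < 0)
    stop("baseline must be finite and non-negative")
  structure(list(CL = unname(CL), V = unname(V), baseline = unname(baseline)),
            class = "mg_pk_params")
}

## Above-baseline concentration of one infusion event for vectors of times
## and (recycled) CL, k. rate in mg/h; times in h. The closed form for a
## one-compartment model: during the infusion (R0/CL)(1 - e^{-k tau}),
## after it the end-of-infusion value decays exponentially.
.event_conc <- function(t, rate, t0, dur, CL, k) {
  te <- t0 + dur
  tau <- pmin(pmax(t - t0, 0), dur)          # elapsed infusion time
  c_inf <- (rate / CL) * (1 - exp(-k * tau)) # value at min(t, te)
  decay <- exp(-k * pmax(t - te, 0))
  c_inf * decay * (t > t0)
}

## Analytic sensitivities of .event_conc to a = log CL and b = log V
## (holding rate fixed). k = CL/V so dk/da = k, dk/db = -k.
## Returns list(c, dca, dcb).
.event_conc_grad <- function(t, rate, t0, dur, CL, k) {
  te <- t0 + dur
  on <- t > t0
  tau <- pmin(pmax(t - t0, 0), dur)
  dt_after <- pmax(t - te, 0)
  e_tau <- exp(-k * tau)
  decay <- exp(-k * dt_after)
  g <- (1 - e_tau) * decay                   # shape factor, conc = (R/CL) g
  ## dg/dk = [tau e^{-k tau}] decay + (1 - e^{-k tau})(-dt_after) decay
  dgdk <- (tau * e_tau - (1 - e_tau) * dt_after) * decay
  cc <- (rate / CL) * g * on
  dcda <- (-cc + (rate / CL) * dgdk * k) * on  # d/d logCL
  dcdb <- (-(rate / CL) * dgdk * k) * on       # d/d logV
  list(c = cc, dca = dcda, dcdb = dcdb)
}

#' Serum magnesium concentration under a regimen (analytic one-compartment)
#'
#' Total concentration at time `t` is the individual baseline plus the
#' linear superposition of the analytic one-compartment infusion solution
#' over every dose event. Continuous in `t`, non-negative, exact (no ODE
#' integration).
#'
#' @param reg a [regimen()].
#' @param params a [pk_params()].
#' @param t numeric vector of times (hours, >= 0).
#' @param above_baseline if `TRUE`, return the drug-attributable
#'   concentration only (baseline excluded).
#' @return numeric vector of concentrations, same unit as
#'   `params$baseline` (mg/L in the package's internal convention).
#' @examples
#' reg <- regimen(list(dose_event(0, 10, 6.7)))
#' p <- pk_params(CL = 2.98, V = 25.07, baseline = mmol_to_mg(0.76))
#' mg_to_mmol(conc_at(reg, p, c(1, 4, 6.7, 12)))
#' @export
conc_at <- function(reg, params, t, above_baseline = FALSE) {
  stopifnot(inherits(reg, "mg_regimen"), inherits(params, "mg_pk_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("times must be finite and >= 0")
  k <- params$CL / params$V
  above <- numeric(length(t))
  for (e in reg$events) {
    if (e$grams == 0) next
    rate <- e$grams * reg$salt_factor / e$duration   # mg elemental Mg / h
    above <- above + .event_conc(t, rate, e$start, e$duration, params$CL, k)
  }
  if (above_baseline) above else above + params$baseline
}

#' @rdname conc_at
#' @param times non-decreasing numeric grid of times (hours).
#' @return `conc_profile()` returns a data.frame with columns `time`,
#'   `conc_above` (drug-attributable) and `conc_total`.
#' @export
conc_profile <- function(reg, params, times) {
  if (is.unsorted(times)) stop("times must be non-decreasing")
  above <- conc_at(reg, params, times, above_baseline = TRUE)
  data.frame(time = times, conc_above = above,
             conc_total = above + params$baseline)
}

#' Total labelled grams of salt in a regimen
#' @param reg a [regimen()].
#' @return numeric scalar, grams.
#' @export
regimen_total_grams <- function(reg) {
  sum(vapply(reg$events, `[[`, numeric(1), "grams"))
}
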