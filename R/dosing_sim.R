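#' The four candidate dosing regimens
#'
#' Loading dose of 2.5 or 5 g over 20 min, followed immediately by a
#' maintenance dose of 10 g over 6.7 h or 15 g over 7.7 h.
#'
#' @param salt_factor mg elemental Mg per labelled gram.
#' @return named list of four [regimen()] objects:
#'   `L2.5_M10`, `L5_M10`, `L2.5_M15`, `L5_M15`.
#' @export
standard_regimens <- function(salt_factor = MG_PER_G_MGSO4_7H2O) {
  load_dur <- 20 / 60
  mk <- function(load_g, maint_g, maint_dur)
    regimen(list(dose_event(0, load_g, load_dur),
                 dose_event(load_dur, maint_g, maint_dur)),
            salt_factor = salt_factor)
  list(`L2.5_M10` = mk(2.5, 10, 6.7),
       `L5_M10`   = mk(5, 10, 6.7),
       `L2.5_M15` = mk(2.5, 15, 7.7),
       `L5_M15`   = mk(5, 15, 7.7))
}

#' Simulation grid of covariate cells
#'
#' Renal function at 140/175/213 ml/min, BMI at 27/29/33 kg/m2 (quartiles
#' of the cohort), crossed with furosemide use.
#'
#' @param ccr,bmi,furosemide grid levels.
#' @return data.frame, one row per cell.
#' @export
simulation_grid <- function(ccr = c(140, 175, 213), bmi = c(27, 29, 33),
                            furosemide = c(0, 1)) {
  expand.grid(CCR = ccr, BMI = bmi, FURO = furosemide)
}

#' Simulate a virtual population under one regimen and covariate cell
#'
#' Draws `eta ~ N(0, omega2)` per individual, maps the cell's covariates
#' through the model to individual CL and V, and evaluates the analytic
#' concentration profile on a time grid. Attainment is judged on the
#' model-predicted (noise-free) concentration by default: residual error
#' represents assay noise, not biology; `residual = TRUE` adds it.
#'
#' @param theta named fixed-effect vector.
#' @param omega2 length-2 variances `c(CL, V)`.
#' @param cell one-row data.frame / named list of covariates for the cell.
#' @param reg a [regimen()].
#' @param n number of simulated individuals.
#' @param seed integer seed. Draws are positionally reproducible: the
#'   first `n` individuals of a larger simulation with the same seed are
#'   identical.
#' @param spec generating [model_spec()].
#' @param baseline endogenous magnesium added to every profile, mg/L
#'   (default 0.76 mmol/L; the therapeutic window refers to total serum
#'   magnesium).
#' @param times time grid, hours.
#' @param sigma residual model (used only when `residual = TRUE`).
#' @param residual include residual noise in the simulated concentrations.
#' @return matrix `n x length(times)` of total concentrations in mmol/L,
#'   with attribute `"times"`.
#' @export
simulate_population <- function(theta, omega2, cell, reg, n = 1000, seed = 1,
                                spec = final_model_spec(),
                                baseline = mmol_to_mg(0.76),
                                times = seq(0, 8, by = 0.25),
                                sigma = NULL, residual = FALSE) {
  stopifnot(n >= 1)
  tv <- typical_values(theta, cell, spec)
  set.seed(seed)
  ## interleaved draws: individual i always consumes the same stream
  ## positions, so the first n rows are invariant to enlarging n
  z <- matrix(stats::rnorm(2 * n), n, 2, byrow = TRUE)
  eta <- cbind(z[, 1] * sqrt(max(omega2[["CL"]], 0)),
               z[, 2] * sqrt(max(omega2[["V"]], 0)))
  CL <- tv[["CL"]] * exp(eta[, 1])
  V <- tv[["V"]] * exp(eta[, 2])
  k <- CL / V
  conc <- matrix(0, n, length(times))
  for (e in reg$events) {
    if (e$grams == 0) next
    rate <- e$grams * reg$salt_factor / e$duration
    for (j in seq_along(times))
      conc[, j] <- conc[, j] + .event_conc(times[j], rate, e$start,
                                           e$duration, CL, k)
  }
  conc <- conc + baseline
  if (residual) {
    if (is.null(sigma)) stop("residual = TRUE needs a sigma model")
    conc <- conc + matrix(stats::rnorm(length(conc), 0,
                                       sqrt(.sigma2(sigma, as.vector(conc)))),
                          n, length(times))
  }
  conc <- mg_to_mmol(conc)
  attr(conc, "times") <- times
  conc
}

#' Hourly probability of target attainment
#'
#' Fraction of simulated individuals whose total concentration lies in the
#' closed therapeutic window at each check time.
#'
#' @param conc matrix from [simulate_population()] (mmol/L, with a
#'   `"times"` attribute).
#' @param window therapeutic window, mmol/L (closed interval).
#' @param check_times hourly check times (default 1..8 h).
#' @return data.frame `time`, `pta` of class `"mg_pta"`, with the window
#'   as an attribute.
#' @export
pta <- function(conc, window = THERAPEUTIC_WINDOW_MMOL,
                check_times = 1:8) {
  times <- attr(conc, "times")
  if (is.null(times)) stop("conc needs a 'times' attribute")
  idx <- match(check_times, times)
  if (anyNA(idx)) stop("time grid does not cover the check times: ",
                       paste(check_times[is.na(idx)], collapse = ", "))
  frac <- vapply(idx, function(j)
    mean(conc[, j] >= window[1] & conc[, j] <= window[2]), numeric(1))
  structure(data.frame(time = check_times, pta = frac),
            class = c("mg_pta", "data.frame"), window = window)
}

#' Is a regimen appropriate for a cell?
#'
#' The rule: more than 90% of individuals inside the therapeutic window at
#' every hourly check from hour 4 through hour 8 inclusive (the "after the
#' fourth hour" criterion; strictly greater than 0.90).
#'
#' @param pta_result a data.frame from [pta()].
#' @param hours check hours that must all qualify.
#' @param min_fraction strict lower bound on the attained fraction.
#' @return logical flag.
#' @export
regimen_appropriate <- function(pta_result, hours = 4:8,
                                min_fraction = 0.90) {
  idx <- match(hours, pta_result$time)
  if (anyNA(idx)) stop("PTA result is missing hours: ",
                       paste(hours[is.na(idx)], collapse = ", "))
  all(pta_result$pta[idx] > min_fraction)
}

#' PTA over the full regimen x covariate grid
#'
#' @param theta,omega2,spec model; see [simulate_population()].
#' @param regimens named list of regimens (default [standard_regimens()]).
#' @param grid data.frame of cells (default [simulation_grid()]).
#' @param n individuals per cell.
#' @param seed master seed (one sub-seed per regimen x cell).
#' @param baseline endogenous magnesium, mg/L.
#' @return data.frame: regimen, cell covariates, hour, pta, appropriate
#'   (per regimen x cell).
#' @export
pta_grid <- function(theta, omega2, spec = final_model_spec(),
                     regimens = standard_regimens(),
                     grid = simulation_grid(), n = 1000, seed = 1,
                     baseline = mmol_to_mg(0.76)) {
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(regimens) * nrow(grid)),
                      nrow = length(regimens))
  out <- list()
  for (r in seq_along(regimens)) {
    for (g in seq_len(nrow(grid))) {
      conc <- simulate_population(theta, omega2, grid[g, ], regimens[[r]],
                                  n = n, seed = sub_seeds[r, g], spec = spec,
                                  baseline = baseline)
      p <- pta(conc)
      out[[length(out) + 1L]] <- cbind(
        data.frame(regimen = names(regimens)[r]),
        grid[g, , drop = FALSE], p,
        appropriate = regimen_appropriate(p), row.names = NULL)
    }
  }
  do.call(rbind, out)
}
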