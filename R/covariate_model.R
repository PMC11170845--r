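#' Covariate model specification
#'
#' The population model expresses individual clearance and volume as a
#' typical value times covariate factors times a log-normal random effect:
#'
#' \deqn{CL_i = tvCL \prod_m f_m(x_{im}) e^{\eta_{CL,i}}, \qquad
#'       V_i  = tvV  \prod_m f_m(x_{im}) e^{\eta_{V,i}}}
#'
#' Continuous covariates enter as power terms \eqn{(x/ref)^{coef}};
#' categorical (binary) covariates as proportional terms \eqn{1 + coef\,x}.
#' Coefficients are stored signed, so the final-model clearance factor for
#' furosemide, (1 - 0.16 furosemide), corresponds to `coef = -0.16`.
#'
#' `covariate_effect()` describes one candidate/retained effect;
#' `model_spec()` bundles the structural choices consumed by [foce_fit()].
#'
#' @param parameter `"CL"` or `"V"`.
#' @param covariate column name of the covariate in the dataset.
#' @param form `"power"` (continuous) or `"proportional"` (binary).
#' @param ref reference (normalization) value for power terms; ignored for
#'   proportional terms.
#' @return a list of class `"mg_effect"`.
#' @export
covariate_effect <- function(parameter = c("CL", "V"), covariate,
                             form = c("power", "proportional"), ref = NA) {
  parameter <- match.arg(parameter)
  form <- match.arg(form)
  if (form == "power" && (!is.finite(ref) || ref <= 0))
    stop("power effects need a positive reference value")
  structure(list(parameter = parameter, covariate = covariate,
                 form = form, ref = ref,
                 name = paste0("d", parameter, "d", covariate)),
            class = "mg_effect")
}

#' @rdname covariate_effect
#' @param effects list of [covariate_effect()] objects.
#' @param error residual-error model: list with `kind` in
#'   `"additive"`, `"proportional"`, `"combined"`.
#' @param baseline one of `"data"` (use the per-subject `BASELINE` column,
#'   a measured pre-treatment magnesium), `"global"` (single constant,
#'   `baseline_value`), `"zero"` (model total concentration with no
#'   endogenous offset).
#' @param baseline_value global baseline, mg/L (used when
#'   `baseline = "global"`).
#' @param salt_factor mg elemental Mg per labelled gram of salt.
#' @export
model_spec <- function(effects = list(),
                       error = list(kind = "additive"),
                       baseline = c("data", "global", "zero"),
                       baseline_value = mmol_to_mg(0.76),
                       salt_factor = MG_PER_G_MGSO4_7H2O) {
  baseline <- match.arg(baseline)
  stopifnot(error$kind %in% c("additive", "proportional", "combined"))
  for (e in effects) stopifnot(inherits(e, "mg_effect"))
  nm <- vapply(effects, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate covariate effects: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  structure(list(effects = effects, error = error, baseline = baseline,
                 baseline_value = baseline_value, salt_factor = salt_factor),
            class = "mg_model_spec")
}

#' Final published covariate model
#'
#' CL depends on creatinine clearance and BMI through power terms and on
#' furosemide through a proportional term; V depends on furosemide. The
#' default normalization constants for the power terms are the published
#' ones (both 51); `ref_ccr`/`ref_bmi` override them (e.g. with cohort
#' medians) — predictions are invariant to the choice once the typical
#' values are re-estimated, see the methods vignette.
#'
#' @param ref_ccr,ref_bmi normalization constants for the CCR and BMI power
#'   terms.
#' @param ... passed to [model_spec()].
#' @return a `"mg_model_spec"`.
#' @export
final_model_spec <- function(ref_ccr = 51, ref_bmi = 51, ...) {
  model_spec(effects = list(
    covariate_effect("CL", "CCR", "power", ref = ref_ccr),
    covariate_effect("CL", "BMI", "power", ref = ref_bmi),
    covariate_effect("CL", "FURO", "proportional"),
    covariate_effect("V", "FURO", "proportional")
  ), ...)
}

#' Published final-model parameter estimates
#'
#' Typical clearance 2.98 L/h and volume 25.07 L, power exponents 0.39
#' (CCR) and -0.54 (BMI) on CL, proportional furosemide coefficients -0.16
#' (CL) and -0.25 (V), between-subject variances 0.082 (CL) and 0.023 (V),
#' additive residual SD 3.65 mg/L.
#'
#' @return named list with `theta` (named numeric), `omega2` (named numeric,
#'   CL and V variances) and `sigma` (error model list).
#' @export
published_estimates <- function() {
  list(
    theta = c(tvCL = 2.98, tvV = 25.07,
              dCLdCCR = 0.39, dCLdBMI = -0.54,
              dCLdFURO = -0.16, dVdFURO = -0.25),
    omega2 = c(CL = 0.082, V = 0.023),
    sigma = list(kind = "additive", stdev0 = 3.65)
  )
}

#' One multiplicative covariate factor
#'
#' @param form `"power"` or `"proportional"`.
#' @param x covariate value (positive for power; 0/1 for proportional).
#' @param coef signed coefficient.
#' @param ref reference value for the power form.
#' @return multiplicative factor (> 0 for a valid model).
#' @examples
#' covariate_term("power", 182.18, 0.39, 51)
#' covariate_term("proportional", 1, -0.16)
#' @export
covariate_term <- function(form, x, coef, ref = NA) {
  fac <- switch(form,
    power = {
      if (any(x <= 0) || !is.finite(ref) || ref <= 0)
        stop("power form requires positive covariate and reference")
      (x / ref)^coef
    },
    proportional = 1 + coef * x,
    stop("unknown covariate form: ", form)
  )
  if (any(fac <= 0))
    stop("covariate factor is non-positive; model invalid at these values")
  fac
}

#' Typical (population) CL and V for given covariates
#'
#' Applies every covariate factor in the model spec to the typical values.
#' `theta` must contain `tvCL`, `tvV` and one entry per effect, named
#' `d<parameter>d<covariate>` (e.g. `dCLdCCR`).
#'
#' @param theta named numeric vector of fixed effects.
#' @param cov one-row data.frame (or named list) of covariate values.
#' @param spec a [model_spec()].
#' @return named numeric `c(CL = ..., V = ...)`.
#' @examples
#' th <- published_estimates()$theta
#' typical_values(th, list(CCR = 51, BMI = 51, FURO = 0), final_model_spec())
#' @export
typical_values <- function(theta, cov, spec) {
  stopifnot(all(c("tvCL", "tvV") %in% names(theta)))
  CL <- unname(theta["tvCL"]); V <- unname(theta["tvV"])
  if (CL <= 0 || V <= 0) stop("typical values must be positive")
  for (e in spec$effects) {
    if (!e$name %in% names(theta))
      stop("theta is missing coefficient ", e$name)
    x <- cov[[e$covariate]]
    if (is.null(x)) stop("covariates are missing column ", e$covariate)
    fac <- covariate_term(e$form, x, unname(theta[e$name]), e$ref)
    if (e$parameter == "CL") CL <- CL * fac else V <- V * fac
  }
  c(CL = CL, V = V)
}

#' Individual PK parameters from covariates and random effects
#'
#' @inheritParams typical_values
#' @param eta named numeric `c(CL = etaCL, V = etaV)` random effects.
#' @param baseline endogenous magnesium, mg/L.
#' @return a [pk_params()].
#' @export
individual_params <- function(theta, cov, eta = c(CL = 0, V = 0), spec,
                              baseline = 0) {
  tv <- typical_values(theta, cov, spec)
  pk_params(CL = tv["CL"] * exp(unname(eta["CL"])),
            V  = tv["V"]  * exp(unname(eta["V"])),
            baseline = baseline)
}
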