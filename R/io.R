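#' Validate an event dataset
#'
#' Checks the NONMEM-style layout invariants: required columns present;
#' times finite, non-negative and non-decreasing within subject; EVID in
#' {0,1}; dose rows have positive AMT and DUR and no DV; observation rows
#' have non-negative DV; every subject has at least one observation.
#' Violations are collected and reported together with their row numbers.
#'
#' @param dataset data.frame.
#' @return invisibly `TRUE`; stops with an informative message otherwise.
#' @export
validate_dataset <- function(dataset) {
  errs <- character(0)
  need <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "MDV")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) {
    stop("dataset is missing required columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(dataset$TIME) | dataset$TIME < 0)
  if (length(bad)) errs <- c(errs, paste0("negative or non-finite TIME in rows: ",
                                          paste(bad, collapse = ", ")))
  bad <- which(!dataset$EVID %in% c(0L, 1L))
  if (length(bad)) errs <- c(errs, paste0("EVID outside {0,1} in rows: ",
                                          paste(bad, collapse = ", ")))
  for (id in unique(dataset$ID)) {
    rows <- which(dataset$ID == id)
    if (is.unsorted(dataset$TIME[rows]))
      errs <- c(errs, paste0("TIME not non-decreasing for subject ", id))
    if (!any(dataset$EVID[rows] == 0))
      errs <- c(errs, paste0("subject ", id, " has no observation row"))
  }
  dose <- which(dataset$EVID == 1)
  bad <- dose[!is.finite(dataset$AMT[dose]) | dataset$AMT[dose] <= 0]
  if (length(bad)) errs <- c(errs, paste0("dose rows without positive AMT: ",
                                          paste(bad, collapse = ", ")))
  bad <- dose[!is.finite(dataset$DUR[dose]) | dataset$DUR[dose] <= 0]
  if (length(bad)) errs <- c(errs, paste0("dose rows without positive DUR: ",
                                          paste(bad, collapse = ", ")))
  bad <- dose[!is.na(dataset$DV[dose])]
  if (length(bad)) errs <- c(errs, paste0("dose rows carrying a DV: ",
                                          paste(bad, collapse = ", ")))
  obs <- which(dataset$EVID == 0 & dataset$MDV == 0)
  bad <- obs[!is.finite(dataset$DV[obs]) | dataset$DV[obs] < 0]
  if (length(bad)) errs <- c(errs, paste0("observation rows without valid DV: ",
                                          paste(bad, collapse = ", ")))
  if (length(errs)) stop("invalid dataset:\n  ", paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

#' Read / write an event dataset CSV
#'
#' On disk, doses are labelled grams of salt and concentrations (DV and,
#' if present, BASELINE) are in the unit named by `dv_unit`; internally
#' the package works in mg/L of elemental magnesium. Reading applies the
#' conversion and validates; writing reverses it.
#'
#' @param path CSV file path.
#' @param dv_unit `"mmol/L"` (conventional reporting unit, default) or
#'   `"mg/L"`.
#' @return `read_dataset()`: validated data.frame in internal units.
#' @export
read_dataset <- function(path, dv_unit = c("mmol/L", "mg/L")) {
  dv_unit <- match.arg(dv_unit)
  d <- utils::read.csv(path)
  validate_dataset(d)
  if (dv_unit == "mmol/L") {
    d$DV <- mmol_to_mg(d$DV)
    if (!is.null(d$BASELINE)) d$BASELINE <- mmol_to_mg(d$BASELINE)
  }
  d
}

#' @rdname read_dataset
#' @param dataset data.frame in internal units.
#' @export
write_dataset <- function(dataset, path, dv_unit = c("mmol/L", "mg/L")) {
  dv_unit <- match.arg(dv_unit)
  d <- dataset
  if (dv_unit == "mmol/L") {
    d$DV <- mg_to_mmol(d$DV)
    if (!is.null(d$BASELINE)) d$BASELINE <- mg_to_mmol(d$BASELINE)
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Default SCM candidate list
#'
#' Continuous covariates (CCR, BMI, age, albumin) as power terms
#' referenced at the dataset median; binary covariates (furosemide,
#' labetalol, nifedipine, ADR) as proportional terms; each candidate
#' offered on both CL and V.
#'
#' @param dataset event dataset (for the median references).
#' @param continuous,binary covariate column names.
#' @return list of [covariate_effect()].
#' @export
default_scm_candidates <- function(dataset,
                                   continuous = c("CCR", "BMI", "AGE", "ALBUMIN"),
                                   binary = c("FURO", "LABETALOL",
                                              "NIFEDIPINE", "ADR")) {
  first <- match(unique(dataset$ID), dataset$ID)
  out <- list()
  for (par in c("CL", "V")) {
    for (cv in continuous) {
      if (is.null(dataset[[cv]])) next
      out[[length(out) + 1L]] <-
        covariate_effect(par, cv, "power",
                         ref = stats::median(dataset[[cv]][first]))
    }
    for (cv in binary) {
      if (is.null(dataset[[cv]])) next
      out[[length(out) + 1L]] <- covariate_effect(par, cv, "proportional")
    }
  }
  out
}

#' Default pipeline configuration
#'
#' One declarative list covering the study design, generating truth,
#' model, SCM candidates, diagnostic sizes, the simulation grid and all
#' seeds. Every entry can be overridden via `modifyList()`-style `...`.
#'
#' @param ... named overrides.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    dataset_path = NULL,              # read instead of generate when set
    design = study_design(),
    distributions = covariate_distributions(),
    truth = published_estimates(),
    spec = final_model_spec(),
    run_scm = TRUE,
    scm_candidates = NULL,            # default: default_scm_candidates()
    bootstrap_B = 200,
    vpc_n_sim = 500,
    pta_n = 1000,
    pta_baseline_mmol = 0.76,
    output_dir = NULL
  )
  ov <- list(...)
  cfg[names(ov)] <- ov     # wholesale replacement, no deep merging
  cfg
}

## choose one first-line regimen per furosemide group: the regimen
## appropriate in the most CCR x BMI cells; ties broken by the lowest
## total dose (least exposure), then by name.
.recommend <- function(pta_tab) {
  regs <- standard_regimens()
  grams <- vapply(regs, regimen_total_grams, numeric(1))
  out <- list()
  for (furo in sort(unique(pta_tab$FURO))) {
    sub <- pta_tab[pta_tab$FURO == furo, ]
    per <- unique(sub[, c("regimen", "CCR", "BMI", "appropriate")])
    cnt <- tapply(per$appropriate, per$regimen, sum)
    cand <- names(cnt)[cnt == max(cnt)]
    pick <- cand[order(grams[cand], cand)][1]
    out[[paste0("furosemide_", furo)]] <- list(
      first_line = pick,
      cells_appropriate = unname(max(cnt)),
      cells_total = length(unique(paste(sub$CCR, sub$BMI))),
      all_counts = as.list(cnt))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Composes: generate (or read) the dataset, fit the base model, stepwise
#' covariate selection, refit the final model with standard errors,
#' nonparametric bootstrap, goodness-of-fit and VPC diagnostics, and the
#' Monte Carlo dose-optimization grid with a first-line regimen
#' recommendation per furosemide group. Deterministic given the config
#' seeds. When `config$output_dir` is set, tables are written as CSV and
#' the recommendation as JSON.
#'
#' @param config list from [default_config()].
#' @return list bundle: `dataset`, `base_fit`, `scm`, `final_fit`,
#'   `parameter_table`, `bootstrap`, `gof`, `vpc`, `pta`, `recommendation`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  msg <- function(...) message("[mgppk] ", ...)

  if (!is.null(cfg$dataset_path)) {
    msg("reading dataset: ", cfg$dataset_path)
    dataset <- read_dataset(cfg$dataset_path)
  } else {
    msg("generating synthetic study (seed ", cfg$seed, ")")
    dataset <- generate_study(cfg$design, cfg$distributions,
                              cfg$truth$theta, cfg$truth$omega2,
                              cfg$truth$sigma, cfg$spec, seed = cfg$seed)
  }
  validate_dataset(dataset)

  base_spec <- model_spec(effects = list(), error = cfg$spec$error,
                          baseline = cfg$spec$baseline,
                          baseline_value = cfg$spec$baseline_value,
                          salt_factor = cfg$spec$salt_factor)
  msg("fitting base model")
  base_fit <- foce_fit(dataset, base_spec, options = list(compute_se = FALSE))

  scm_res <- NULL
  if (isTRUE(cfg$run_scm)) {
    cand <- cfg$scm_candidates
    if (is.null(cand)) cand <- default_scm_candidates(dataset)
    msg("stepwise covariate modeling (", length(cand), " candidates)")
    scm_res <- run_scm(dataset, base_spec, cand)
    final_spec <- scm_res$final_fit$spec
  } else {
    final_spec <- cfg$spec
  }

  msg("refitting final model with standard errors")
  final_fit <- foce_fit(dataset, final_spec,
                        options = list(compute_se = TRUE))
  ptab <- parameter_table(final_fit)

  msg("bootstrap (B = ", cfg$bootstrap_B, ")")
  boot <- bootstrap_model(dataset, final_spec, B = cfg$bootstrap_B,
                          seed = cfg$seed + 1L,
                          inits = list(theta = final_fit$theta,
                                       omega2 = final_fit$omega2,
                                       sigma = final_fit$sigma[
                                         setdiff(names(final_fit$sigma), "kind")]))

  msg("goodness of fit and VPC")
  gof <- gof_table(final_fit)
  vpc_res <- vpc(final_fit, n_sim = cfg$vpc_n_sim, seed = cfg$seed + 2L)

  msg("Monte Carlo dose optimization (n = ", cfg$pta_n, " per cell)")
  pta_tab <- pta_grid(final_fit$theta, final_fit$omega2,
                      spec = final_spec, n = cfg$pta_n,
                      seed = cfg$seed + 3L,
                      baseline = mmol_to_mg(cfg$pta_baseline_mmol))
  rec <- .recommend(pta_tab)

  bundle <- list(dataset = dataset, base_fit = base_fit, scm = scm_res,
                 final_fit = final_fit, parameter_table = ptab,
                 bootstrap = boot, gof = gof, vpc = vpc_res,
                 pta = pta_tab, recommendation = rec, config = cfg)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(cfg$output_dir, f)
    write_dataset(dataset, p("dataset.csv"))
    utils::write.csv(ptab, p("parameter_table.csv"), row.names = FALSE)
    if (!is.null(scm_res))
      utils::write.csv(scm_res$trace, p("scm_trace.csv"), row.names = FALSE)
    utils::write.csv(boot$summary, p("bootstrap_summary.csv"), row.names = FALSE)
    utils::write.csv(gof, p("gof_table.csv"), row.names = FALSE)
    utils::write.csv(vpc_res$bands, p("vpc_bands.csv"), row.names = FALSE)
    utils::write.csv(pta_tab, p("pta_grid.csv"), row.names = FALSE)
    jsonlite::write_json(rec, p("recommendation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    msg("outputs written to ", cfg$output_dir)
  }
  bundle
}
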