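## Shared fixtures, all built in code.

## Published final-model truth
TRUTH <- published_estimates()

## Median-normalized model spec: tvCL/tvV apply to the median patient
## (CCR 182.18 ml/min, BMI 29.13 kg/m2), the parameterization under which
## the published typical values are internally consistent.
med_spec <- function(...) final_model_spec(ref_ccr = 182.18, ref_bmi = 29.13, ...)

## A small study with rich sampling for fast, well-identified fits
rich_design <- function(n = 40, offsets = c(0, 0.5, 1, 2, 4, 6, 8, 12)) {
  study_design(n_subjects = n, sampling_offsets = offsets, dropout = 0)
}

## One-subject dataset built by hand (doses + observations at given times)
one_subject_data <- function(times, dv, reg, cov = list(), id = 1) {
  dose_rows <- data.frame(
    ID = id,
    TIME = vapply(reg$events, `[[`, numeric(1), "start"),
    EVID = 1L,
    AMT = vapply(reg$events, `[[`, numeric(1), "grams"),
    DUR = vapply(reg$events, `[[`, numeric(1), "duration"),
    DV = NA_real_, MDV = 1L)
  obs_rows <- data.frame(ID = id, TIME = times, EVID = 0L, AMT = NA_real_,
                         DUR = NA_real_, DV = dv, MDV = 0L)
  d <- rbind(dose_rows, obs_rows)
  d <- d[order(d$TIME, -d$EVID), ]
  for (nm in names(cov)) d[[nm]] <- cov[[nm]]
  rownames(d) <- NULL
  d
}

## Exact marginal -2LL by tensor Gauss-Hermite quadrature, built on the
## public prediction path (conc_at + dnorm), independent of the FOCE engine.
gh_neg2ll <- function(dataset, theta, omega2, sigma, spec, n_nodes = 30) {
  gh <- pracma::gaussHermite(n_nodes)
  ids <- unique(dataset$ID)
  total <- 0
  for (id in ids) {
    sub <- dataset[dataset$ID == id, ]
    obs <- sub[sub$EVID == 0, ]
    dos <- sub[sub$EVID == 1, ]
    reg <- regimen(lapply(seq_len(nrow(dos)), function(r)
      dose_event(dos$TIME[r], dos$AMT[r], dos$DUR[r])),
      salt_factor = spec$salt_factor)
    base <- switch(spec$baseline, data = obs$BASELINE[1],
                   global = spec$baseline_value, zero = 0)
    lik_at <- function(eCL, eV) {
      p <- individual_params(theta, sub[1, ], c(CL = eCL, V = eV), spec,
                             baseline = base)
      f <- conc_at(reg, p, obs$TIME)
      sd_res <- sqrt(switch(sigma$kind,
        additive = rep(sigma$stdev0^2, length(f)),
        proportional = pmax(sigma$cv0 * f, 1e-6)^2,
        combined = sigma$stdev0^2 + (sigma$cv0 * f)^2))
      prod(stats::dnorm(obs$DV, f, sd_res))
    }
    L <- 0
    for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
      ## eta = sqrt(2 omega2) x  (Gauss-Hermite change of variables)
      L <- L + gh$w[i] * gh$w[j] / pi *
        lik_at(sqrt(2 * omega2[["CL"]]) * gh$x[i],
               sqrt(2 * omega2[["V"]]) * gh$x[j])
    }
    total <- total - 2 * log(L)
  }
  total
}
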