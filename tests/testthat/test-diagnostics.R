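## build an "mg_fit"-shaped object at chosen parameters, skipping the fit:
## diagnostics only consume (theta, omega2, sigma, etas, dataset, spec)
fake_fit <- function(dataset, spec, theta, omega2, sigma, etas = NULL) {
  ids <- unique(dataset$ID)
  if (is.null(etas))
    etas <- matrix(0, length(ids), 2, dimnames = list(ids, c("CL", "V")))
  structure(list(theta = theta, omega2 = omega2, sigma = sigma,
                 etas = etas, dataset = dataset, spec = spec,
                 converged = TRUE),
            class = "mg_fit")
}

test_that("with no random effects CWRES is exactly the standardized residual", {
  spec <- model_spec(effects = list(), baseline = "global",
                     baseline_value = 18)
  d <- generate_study(study_design(n_subjects = 10), spec = spec,
                      theta = c(tvCL = 3, tvV = 25),
                      omega2 = c(CL = 0, V = 0),
                      sigma = list(kind = "additive", stdev0 = 2), seed = 3)
  fit <- fake_fit(d, spec, c(tvCL = 3, tvV = 25), c(CL = 0, V = 0),
                  list(kind = "additive", stdev0 = 2))
  g <- gof_table(fit)
  expect_equal(nrow(g), sum(d$EVID == 0))
  expect_equal(g$CWRES, (g$DV - g$PRED) / 2, tolerance = 1e-12)
  expect_equal(g$IPRED, g$PRED)
  expect_true(all(g$PRED >= 0))
})

test_that("CWRES is approximately standard normal under a well-specified model", {
  spec <- med_spec()
  d <- generate_study(spec = spec, seed = 17)      # the default 51-subject study
  fit <- foce_fit(d, spec,
                  inits = list(theta = TRUTH$theta, omega2 = TRUTH$omega2,
                               sigma = list(stdev0 = 3.65)),
                  options = list(compute_se = FALSE))
  g <- gof_table(fit)
  expect_equal(nrow(g), sum(d$EVID == 0))
  expect_true(all(is.finite(g$CWRES)))
  expect_lt(abs(mean(g$CWRES)), 0.15)
  expect_gt(sd(g$CWRES), 0.8)
  expect_lt(sd(g$CWRES), 1.2)
  ## "most CWRES between +-2"
  expect_gte(mean(abs(g$CWRES) <= 2), 0.90)
})

test_that("bootstrap of identical cloned subjects has zero-width intervals", {
  spec <- model_spec(effects = list(), baseline = "global",
                     baseline_value = 18)
  one <- generate_study(study_design(n_subjects = 1), spec = spec,
                        theta = c(tvCL = 3, tvV = 25),
                        omega2 = c(CL = 0.05, V = 0.02), seed = 8)
  clones <- do.call(rbind, lapply(1:8, function(i) { x <- one; x$ID <- i; x }))
  b <- bootstrap_model(clones, spec, B = 5, seed = 2,
                       inits = list(theta = c(tvCL = 3, tvV = 25)))
  expect_equal(b$n_success, 5)
  expect_equal(b$summary$p2.5, b$summary$p97.5, tolerance = 1e-8)
  expect_equal(b$summary$median, b$summary$p2.5, tolerance = 1e-8)
})

test_that("a single bootstrap replicate is its own summary and labels do not matter", {
  spec <- med_spec()
  d <- generate_study(study_design(n_subjects = 14), spec = spec, seed = 13)
  inits <- list(theta = TRUTH$theta, omega2 = TRUTH$omega2,
                sigma = list(stdev0 = 3.65))
  b1 <- bootstrap_model(d, spec, B = 1, seed = 4, inits = inits)
  expect_equal(b1$summary$median, b1$summary$p2.5)
  expect_equal(b1$summary$median, b1$summary$p97.5)
  expect_equal(unname(b1$summary$median), unname(b1$estimates[1, ]))

  ## relabel subjects (same order, new IDs): identical resampling stream
  d2 <- d; d2$ID <- match(d$ID, unique(d$ID)) + 100
  b <- bootstrap_model(d, spec, B = 6, seed = 9, inits = inits)
  b2 <- bootstrap_model(d2, spec, B = 6, seed = 9, inits = inits)
  expect_equal(b$summary$median, b2$summary$median, tolerance = 1e-10)
})

test_that("bootstrap intervals cover the original estimates", {
  spec <- med_spec()
  d <- generate_study(rich_design(n = 30), spec = spec, seed = 23)
  fit <- foce_fit(d, spec,
                  inits = list(theta = TRUTH$theta, omega2 = TRUTH$omega2,
                               sigma = list(stdev0 = 3.65)),
                  options = list(compute_se = FALSE))
  b <- bootstrap_model(d, spec, B = 60, seed = 24,
                       inits = list(theta = fit$theta, omega2 = fit$omega2,
                                    sigma = list(stdev0 = fit$sigma$stdev0)))
  expect_gte(b$n_success, 55)
  inside <- fit$estimates >= b$summary$p2.5 & fit$estimates <= b$summary$p97.5
  expect_gte(mean(inside), 0.9)
})

test_that("the VPC band collapses onto the prediction when all variability vanishes", {
  spec <- model_spec(effects = list(), baseline = "global", baseline_value = 18)
  d <- generate_study(study_design(n_subjects = 12), spec = spec,
                      theta = c(tvCL = 3, tvV = 25),
                      omega2 = c(CL = 0, V = 0),
                      sigma = list(kind = "additive", stdev0 = 1), seed = 33)
  fit <- fake_fit(d, spec, c(tvCL = 3, tvV = 25), c(CL = 0, V = 0),
                  list(kind = "additive", stdev0 = 1e-9))
  v <- vpc(fit, n_sim = 100, seed = 1)
  g <- gof_table(fit)
  expect_equal(v$bands$sim_lo, v$bands$sim_hi, tolerance = 1e-6)
  pred_by_bin <- tapply(g$PRED, match(g$TIME, sort(unique(g$TIME))), median)
  mid <- v$bands[v$bands$percentile == 50, ]
  expect_equal(unname(mid$sim_mid), as.numeric(pred_by_bin)[mid$bin],
               tolerance = 1e-6)
})

test_that("VPC of data simulated from the same model contains ~95% of observations", {
  spec <- med_spec()
  d <- generate_study(spec = spec, seed = 41)
  fit <- fake_fit(d, spec, TRUTH$theta, TRUTH$omega2, TRUTH$sigma)
  v <- vpc(fit, n_sim = 400, seed = 42)
  ## binomial tolerance at ~199 observations
  expect_gt(v$inside_fraction, 0.89)
  expect_lte(v$inside_fraction, 1.0)
  ## bands are nested
  expect_true(all(v$bands$sim_lo <= v$bands$sim_mid + 1e-12))
  expect_true(all(v$bands$sim_mid <= v$bands$sim_hi + 1e-12))
})

test_that("the VPC inside-fraction is invariant to the concentration unit", {
  spec <- model_spec(effects = list(), baseline = "global", baseline_value = 18)
  d <- generate_study(study_design(n_subjects = 15), spec = spec,
                      theta = c(tvCL = 3, tvV = 25), seed = 55)
  fit <- fake_fit(d, spec, c(tvCL = 3, tvV = 25), TRUTH$omega2,
                  list(kind = "additive", stdev0 = 3.65))
  v1 <- vpc(fit, n_sim = 150, seed = 7)

  ## rescale mg/L -> mmol/L throughout: DV, baseline, residual SD and 1/V
  c_fac <- 1 / 24.305
  d2 <- d; d2$DV <- d$DV * c_fac
  spec2 <- model_spec(effects = list(), baseline = "global",
                      baseline_value = 18 * c_fac,
                      salt_factor = spec$salt_factor * c_fac)
  fit2 <- fake_fit(d2, spec2, c(tvCL = 3, tvV = 25), TRUTH$omega2,
                   list(kind = "additive", stdev0 = 3.65 * c_fac))
  v2 <- vpc(fit2, n_sim = 150, seed = 7)
  expect_equal(v1$inside_fraction, v2$inside_fraction)
})
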