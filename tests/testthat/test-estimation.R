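test_that("the joint -2LL matches a directly written normal density", {
  spec <- med_spec()
  th <- TRUTH$theta
  omega2 <- c(CL = 0.082, V = 0.023)
  sigma <- list(kind = "additive", stdev0 = 3.65)
  reg <- regimen(list(dose_event(0, 5, 1), dose_event(1, 10, 7)))
  cov <- list(CCR = 160, BMI = 31, FURO = 1, BASELINE = 18.5)
  set.seed(11)
  for (i in 1:10) {
    eta <- rnorm(2, 0, 0.3)
    times <- sort(runif(4, 0, 12))
    p <- individual_params(th, cov, c(CL = eta[1], V = eta[2]), spec,
                           baseline = cov$BASELINE)
    f <- conc_at(reg, p, times)
    dv <- f + rnorm(4, 0, 3)
    d <- one_subject_data(times, dv, reg, cov)
    ## hand-written density: residual normals + eta prior normals
    direct <- -2 * (sum(dnorm(dv, f, sigma$stdev0, log = TRUE)) +
                    sum(dnorm(eta, 0, sqrt(omega2), log = TRUE)))
    expect_equal(individual_joint_neg2ll(d, eta, th, omega2, sigma, spec),
                 direct, tolerance = 1e-10)
  }
  ## perfect predictions at eta = 0: only normalization terms remain
  p0 <- individual_params(th, cov, c(CL = 0, V = 0), spec,
                          baseline = cov$BASELINE)
  f0 <- conc_at(reg, p0, c(1, 4, 8))
  d0 <- one_subject_data(c(1, 4, 8), f0, reg, cov)
  expect_equal(individual_joint_neg2ll(d0, c(0, 0), th, omega2, sigma, spec),
               3 * log(2 * pi * sigma$stdev0^2) +
                 sum(log(2 * pi * omega2)))
})

test_that("information criteria follow their defining identities", {
  ic <- information_criteria(100, 5, 199)
  expect_equal(unname(ic["AIC"]), 110)
  expect_equal(unname(ic["BIC"]), 100 + 5 * log(199))
  expect_equal(round(ic[["BIC"]], 2), 126.47)
  expect_equal(unname(information_criteria(42.5, 0, 10)), c(42.5, 42.5))
})

test_that("eta shrinkage reflects the contraction of the EBE spread", {
  ## all EBEs at zero: complete shrinkage
  expect_equal(eta_shrinkage(cbind(rep(0, 10)), 0.1), 100)
  ## EBE spread exactly omega: no shrinkage
  e <- c(-1, 1) * 0.3 / sd(c(-1, 1))
  expect_equal(eta_shrinkage(cbind(e), 0.09), 0)
  ## spread at 87% of omega: 13%
  expect_equal(eta_shrinkage(cbind(0.87 * e), 0.09), 13)
  expect_warning(eta_shrinkage(cbind(2 * e), 0.09), "clipped")
  expect_warning(eta_shrinkage(cbind(e), 0), "undefined")
})

test_that("with no random effects and one subject the fit is least squares", {
  spec <- model_spec(effects = list(), baseline = "global",
                     baseline_value = mmol_to_mg(0.76))
  reg <- regimen(list(dose_event(0, 5, 1), dose_event(1, 10, 7)))
  truth_p <- pk_params(CL = 3.4, V = 22, baseline = spec$baseline_value)
  times <- c(0.5, 1, 2, 3, 4, 6, 8, 10, 12, 16)
  dv <- conc_at(reg, truth_p, times)          # noise-free
  d <- one_subject_data(times, dv, reg)
  fit <- foce_fit(d, spec,
                  inits = list(omega2 = c(0, 0),
                               sigma = list(stdev0 = 1)),
                  options = list(compute_se = FALSE, fix_sigma = TRUE))
  expect_equal(unname(fit$theta[["tvCL"]]), 3.4, tolerance = 1e-4)
  expect_equal(unname(fit$theta[["tvV"]]), 22, tolerance = 1e-4)

  ## independent least-squares oracle over (CL, V)
  ssr <- function(par) sum((dv - conc_at(reg, pk_params(par[1], par[2],
                           spec$baseline_value), times))^2)
  ls <- optim(c(2, 15), ssr)
  expect_equal(unname(fit$theta[["tvCL"]]), ls$par[1], tolerance = 1e-3)
  expect_equal(unname(fit$theta[["tvV"]]), ls$par[2], tolerance = 1e-3)
})

test_that("the FOCE objective agrees with exact quadrature of the marginal likelihood", {
  skip_if_not_installed("pracma")
  spec <- med_spec()
  d <- generate_study(study_design(n_subjects = 8), spec = spec, seed = 21)
  th <- TRUTH$theta
  sets <- list(
    list(omega2 = c(CL = 0.082, V = 0.023),
         sigma = list(kind = "additive", stdev0 = 3.65)),
    list(omega2 = c(CL = 0.02, V = 0.01),
         sigma = list(kind = "additive", stdev0 = 2)),
    list(omega2 = c(CL = 0.15, V = 0.05),
         sigma = list(kind = "proportional", cv0 = 0.12))
  )
  for (s in sets) {
    eng <- mgppk:::.build_engine(d, spec)
    tv <- mgppk:::.typical_cl_v(eng, th)
    foce <- mgppk:::.foce_ofv(eng, tv, s$omega2, s$sigma)$ofv
    exact <- gh_neg2ll(d, th, s$omega2, s$sigma, spec)
    expect_equal(foce, exact, tolerance = 0.01)
  }
})

test_that("rich well-conditioned designs recover the generating fixed effects within 5%", {
  ## consistency check: wide covariate spread, strong effects, small BSV so
  ## that a 5% band sits well above the sampling noise of each coefficient;
  ## the median over three replicates damps the residual noise further
  dists <- covariate_distributions()
  dists$BMI$sdlog <- 0.5
  th_true <- c(tvCL = 2.98, tvV = 25.07, dCLdCCR = 0.39, dCLdBMI = -0.54,
               dCLdFURO = -0.45, dVdFURO = -0.45)
  spec <- med_spec()
  est <- sapply(c(42, 43, 44), function(s) {
    d <- generate_study(rich_design(n = 250,
                                    offsets = c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 12, 16)),
                        distributions = dists,
                        theta = th_true, omega2 = c(CL = 0.005, V = 0.005),
                        sigma = list(kind = "additive", stdev0 = 0.3),
                        spec = spec, seed = s)
    fit <- foce_fit(d, spec, inits = list(sigma = list(stdev0 = 0.3)),
                    options = list(compute_se = FALSE))
    expect_true(fit$converged)
    fit$estimates
  })
  med <- apply(est, 1, median)
  for (nm in names(th_true))
    expect_equal(unname(med[[nm]]), unname(th_true[[nm]]), tolerance = 0.05)
  expect_equal(unname(med[["stdev0"]]), 0.3, tolerance = 0.05)
})

test_that("the optimizer does not end above its starting objective and is deterministic", {
  spec <- med_spec()
  d <- generate_study(study_design(n_subjects = 20), spec = spec, seed = 31)
  inits <- list(theta = TRUTH$theta, omega2 = TRUTH$omega2,
                sigma = list(stdev0 = 3.65))
  fit1 <- foce_fit(d, spec, inits = inits, options = list(compute_se = FALSE))
  ## OFV at the supplied inits, via the internal objective
  eng <- mgppk:::.build_engine(d, spec)
  tv <- mgppk:::.typical_cl_v(eng, TRUTH$theta)
  ofv_init <- mgppk:::.foce_ofv(eng, tv, TRUTH$omega2, TRUTH$sigma)$ofv
  expect_lte(fit1$OFV, ofv_init)
  fit2 <- foce_fit(d, spec, inits = inits, options = list(compute_se = FALSE))
  expect_identical(fit1$OFV, fit2$OFV)
  expect_identical(fit1$estimates, fit2$estimates)
})

test_that("standard errors are positive, finite and shrink with the cohort size", {
  spec <- model_spec(effects = list(), baseline = "data")
  d1 <- generate_study(rich_design(n = 25), spec = spec,
                       theta = c(tvCL = 2.98, tvV = 25.07),
                       seed = 5)
  d2 <- generate_study(rich_design(n = 100), spec = spec,
                       theta = c(tvCL = 2.98, tvV = 25.07),
                       seed = 6)
  f1 <- foce_fit(d1, spec)
  f2 <- foce_fit(d2, spec)
  expect_true(all(is.finite(f1$se)) && all(f1$se > 0))
  expect_true(all(is.finite(f2$se)) && all(f2$se > 0))
  ## quadrupling subjects should roughly halve the SE of the typical values
  ratio <- f1$se[c("tvCL", "tvV")] / f2$se[c("tvCL", "tvV")]
  expect_true(all(ratio > 1.3 & ratio < 3.2))
  ## CV% definition
  expect_equal(unname(f1$cv_pct), unname(100 * f1$se / abs(f1$estimates)))
})
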