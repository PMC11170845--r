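test_that("the four candidate regimens have the stated doses, durations and rates", {
  regs <- standard_regimens()
  expect_named(regs, c("L2.5_M10", "L5_M10", "L2.5_M15", "L5_M15"))
  expect_equal(regimen_total_grams(regs$L5_M10), 15)
  expect_equal(regimen_total_grams(regs$L2.5_M10), 12.5)
  expect_equal(regimen_total_grams(regs$L5_M15), 20)
  ## total infusion spans
  end_of <- function(r) max(vapply(r$events, function(e) e$start + e$duration,
                                   numeric(1)))
  expect_equal(end_of(regs$L5_M10), 6.7 + 1 / 3, tolerance = 1e-12)   # 7.03 h
  expect_equal(end_of(regs$L5_M15), 7.7 + 1 / 3, tolerance = 1e-12)   # 8.03 h
  ## labelled rates: 5 g / 20 min = 15 g/h; 10 g / 6.7 h
  lab_rate <- function(e) e$grams / e$duration
  expect_equal(lab_rate(regs$L5_M10$events[[1]]), 15)
  expect_equal(lab_rate(regs$L5_M10$events[[2]]), 10 / 6.7)
  ## maintenance starts when loading ends
  expect_equal(regs$L2.5_M15$events[[2]]$start,
               regs$L2.5_M15$events[[1]]$duration)
})

test_that("without between-subject variability every simulated profile is the typical one", {
  cell <- list(CCR = 175, BMI = 29, FURO = 0)
  spec <- med_spec()
  conc <- simulate_population(TRUTH$theta, c(CL = 0, V = 0), cell,
                              standard_regimens()$L5_M10, n = 25, seed = 1,
                              spec = spec)
  tv <- typical_values(TRUTH$theta, cell, spec)
  p <- pk_params(tv[["CL"]], tv[["V"]], baseline = mmol_to_mg(0.76))
  typ <- mg_to_mmol(conc_at(standard_regimens()$L5_M10, p, attr(conc, "times")))
  for (i in 1:25) expect_equal(unname(conc[i, ]), typ, tolerance = 1e-12)
})

test_that("the simulated median converges to the typical profile and draws are positional", {
  cell <- list(CCR = 175, BMI = 29, FURO = 1)
  spec <- med_spec()
  reg <- standard_regimens()$L5_M10
  conc <- simulate_population(TRUTH$theta, TRUTH$omega2, cell, reg,
                              n = 10000, seed = 3, spec = spec)
  tv <- typical_values(TRUTH$theta, cell, spec)
  p <- pk_params(tv[["CL"]], tv[["V"]], baseline = mmol_to_mg(0.76))
  typ <- mg_to_mmol(conc_at(reg, p, c(2, 5, 8)))
  med <- apply(conc[, match(c(2, 5, 8), attr(conc, "times"))], 2, median)
  expect_equal(unname(med), typ, tolerance = 0.02)

  small <- simulate_population(TRUTH$theta, TRUTH$omega2, cell, reg,
                               n = 500, seed = 3, spec = spec)
  expect_equal(conc[1:500, ], small[1:500, ], ignore_attr = TRUE)
})

test_that("PTA counts exactly what a per-individual loop counts", {
  ## all-inside and all-below corner cases
  allin <- matrix(2.5, 10, 8); attr(allin, "times") <- 1:8
  expect_equal(pta(allin)$pta, rep(1, 8))
  nodrug <- matrix(0.76, 10, 8); attr(nodrug, "times") <- 1:8
  expect_equal(pta(nodrug)$pta, rep(0, 8))

  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(runif(50 * 8, 0, 5), 50, 8)
    attr(m, "times") <- 1:8
    p <- pta(m)
    brute <- sapply(1:8, function(j) {
      cnt <- 0
      for (i in 1:50) if (m[i, j] >= 2 && m[i, j] <= 3.5) cnt <- cnt + 1
      cnt / 50
    })
    expect_equal(p$pta, brute)
  }
  expect_error(pta(allin, check_times = c(1, 9)), "does not cover")
})

test_that("the appropriateness rule is a strict >90% at every hour from 4 to 8", {
  ok <- data.frame(time = 1:8, pta = c(0.2, 0.5, 0.8, rep(0.95, 5)))
  expect_true(regimen_appropriate(ok))
  edge <- ok; edge$pta[edge$time == 5] <- 0.90
  expect_false(regimen_appropriate(edge))     # boundary is exclusive
  expect_error(regimen_appropriate(ok[ok$time < 7, ]), "missing hours")

  set.seed(15)
  for (rep in 1:20) {
    fr <- runif(8, 0.7, 1)
    pr <- data.frame(time = 1:8, pta = fr)
    expect_identical(regimen_appropriate(pr), all(fr[4:8] > 0.90))
  }
})

test_that("loading-dose size and furosemide shift the profiles the expected way", {
  spec <- med_spec()
  regs <- standard_regimens()
  tt <- seq(0.1, 2, by = 0.1)
  for (furo in 0:1) {
    tv <- typical_values(TRUTH$theta, list(CCR = 175, BMI = 29, FURO = furo), spec)
    p <- pk_params(tv[["CL"]], tv[["V"]], baseline = mmol_to_mg(0.76))
    c5 <- conc_at(regs$L5_M10, p, tt)
    c25 <- conc_at(regs$L2.5_M10, p, tt)
    expect_true(all(c5 > c25))     # first two hours: larger load, higher conc
  }
  ## furosemide reduces CL and V: higher concentrations throughout
  tvf0 <- typical_values(TRUTH$theta, list(CCR = 175, BMI = 29, FURO = 0), spec)
  tvf1 <- typical_values(TRUTH$theta, list(CCR = 175, BMI = 29, FURO = 1), spec)
  tg <- seq(0.1, 8, by = 0.1)
  cf0 <- conc_at(regs$L5_M10, pk_params(tvf0[["CL"]], tvf0[["V"]]), tg)
  cf1 <- conc_at(regs$L5_M10, pk_params(tvf1[["CL"]], tvf1[["V"]]), tg)
  expect_true(all(cf1 > cf0))
})

test_that("PTA before overshoot decreases as clearance rises across renal-function cells", {
  spec <- med_spec()
  reg <- standard_regimens()$L5_M10
  tt <- seq(0.5, 8, by = 0.5)
  concs <- sapply(c(140, 175, 213), function(ccr) {
    tv <- typical_values(TRUTH$theta, list(CCR = ccr, BMI = 29, FURO = 0), spec)
    conc_at(reg, pk_params(tv[["CL"]], tv[["V"]]), tt)
  })
  ## typical concentration is ordered opposite to CL at every time
  for (i in seq_along(tt)) expect_true(all(diff(concs[i, ]) < 0))
})
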