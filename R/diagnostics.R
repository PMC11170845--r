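#' Goodness-of-fit table: PRED, IPRED and CWRES
#'
#' Per-observation population predictions (`PRED`, random effects at
#' zero), individual predictions (`IPRED`, at the empirical Bayes
#' estimates) and conditional weighted residuals. CWRES whitens the
#' FOCE-linearized residual: per subject, with `G` the sensitivity of the
#' predictions to eta at the EBE,
#' `res = DV - (f(eta*) - G eta*)` and `cov = G Omega G' + Sigma`, then
#' `CWRES = chol(cov)^-T res`. Under a correct model CWRES is
#' approximately standard normal.
#'
#' @param fit an `"mg_fit"`.
#' @return data.frame with `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `CWRES`
#'   (one row per observation). Subjects with a numerically singular
#'   covariance get `NA` CWRES.
#' @export
gof_table <- function(fit) {
  stopifnot(inherits(fit, "mg_fit"))
  eng <- .build_engine(fit$dataset, fit$spec)
  tv <- .typical_cl_v(eng, fit$theta)
  zero <- matrix(0, eng$S, 2)
  pred <- .joint_parts(eng, tv, zero, fit$omega2, fit$sigma)$f
  etas <- fit$etas[match(eng$ids, rownames(fit$etas)), , drop = FALSE]
  jp <- .joint_parts(eng, tv, etas, fit$omega2, fit$sigma, grad = TRUE)
  ipred <- jp$f

  act <- fit$omega2 > 0
  cwres <- rep(NA_real_, eng$N)
  for (s in seq_len(eng$S)) {
    oi <- which(eng$sidx == s)
    if (!any(act)) {
      cwres[oi] <- (eng$dv[oi] - pred[oi]) / sqrt(jp$s2[oi])
      next
    }
    G <- cbind(if (act[1]) jp$Ga[oi] else NULL,
               if (act[2]) jp$Gb[oi] else NULL)
    om <- diag(fit$omega2[act], nrow = sum(act))
    covm <- G %*% om %*% t(G) + diag(jp$s2[oi], nrow = length(oi))
    res <- eng$dv[oi] - (ipred[oi] - drop(G %*% etas[s, act]))
    ch <- try(chol(covm), silent = TRUE)
    if (inherits(ch, "try-error")) next
    cwres[oi] <- drop(backsolve(ch, res, transpose = TRUE))
  }
  data.frame(ID = eng$ids[eng$sidx], TIME = eng$t_obs, DV = eng$dv,
             PRED = pred, IPRED = ipred, CWRES = cwres)
}

#' Nonparametric bootstrap of the model parameters
#'
#' Resamples subjects (all their rows) with replacement, refits the model
#' to each replicate, and summarizes each parameter by the median and the
#' 2.5/97.5 percentiles across successful refits. One master seed spawns
#' one sub-seed per replicate index, so results are reproducible and
#' independent of subject labelling.
#'
#' @param dataset event dataset.
#' @param spec a [model_spec()].
#' @param B number of replicates (the reference analysis uses 1000).
#' @param seed master seed.
#' @param inits initial values for each refit (sensibly: the original
#'   estimates).
#' @param options estimation options.
#' @return list of class `"mg_bootstrap"`: `summary` (data.frame:
#'   parameter, median, p2.5, p97.5, se, cv_pct), `n_success`, `B`,
#'   `estimates` (matrix of per-replicate estimates).
#' @export
bootstrap_model <- function(dataset, spec, B = 1000, seed = 1,
                            inits = NULL, options = list()) {
  stopifnot(B >= 1)
  ids <- unique(dataset$ID)
  S <- length(ids)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, B)
  rows_of <- split(seq_len(nrow(dataset)), match(dataset$ID, ids))
  est <- NULL; n_success <- 0L
  for (b in seq_len(B)) {
    set.seed(sub_seeds[b])
    pick <- sample.int(S, S, replace = TRUE)
    reps <- lapply(seq_along(pick), function(j) {
      d <- dataset[rows_of[[pick[j]]], , drop = FALSE]
      d$ID <- j                       # clones become distinct subjects
      d
    })
    dd <- do.call(rbind, reps)
    f <- try(foce_fit(dd, spec, inits = inits,
                      options = utils::modifyList(options, list(compute_se = FALSE))),
             silent = TRUE)
    if (inherits(f, "try-error") || !f$converged) next
    n_success <- n_success + 1L
    est <- rbind(est, f$estimates)
  }
  if (is.null(est)) stop("no bootstrap replicate converged")
  qs <- apply(est, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  med <- qs[2, ]
  summary <- data.frame(parameter = colnames(est), median = med,
                        p2.5 = qs[1, ], p97.5 = qs[3, ],
                        se = apply(est, 2, stats::sd),
                        cv_pct = 100 * apply(est, 2, stats::sd) / abs(med),
                        row.names = NULL)
  structure(list(summary = summary, n_success = n_success, B = B,
                 estimates = est),
            class = "mg_bootstrap")
}

#' @export
print.mg_bootstrap <- function(x, ...) {
  cat("Nonparametric bootstrap:", x$n_success, "of", x$B,
      "replicates converged\n")
  print(transform(x$summary, median = round(median, 4),
                  p2.5 = round(p2.5, 4), p97.5 = round(p97.5, 4),
                  se = round(se, 4), cv_pct = round(cv_pct, 2)))
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the study at the observed design (same
#' subjects, covariates, doses and sampling times; random effects and
#' residual error redrawn from the fitted model), then compares observed
#' percentiles per time bin with the distribution of the same percentiles
#' across simulations. Also reports the fraction of observations inside
#' their own simulated 2.5-97.5 percentile interval.
#'
#' @param fit an `"mg_fit"`.
#' @param n_sim number of simulated replicates (>= 100).
#' @param seed integer seed.
#' @param bins optional numeric break points on TIME; by default each
#'   distinct nominal sampling time is its own bin (the design is
#'   nominal-time structured). Bins with no observations are merged with
#'   their neighbor.
#' @param probs observed percentiles to track (default 5/50/95).
#' @return list of class `"mg_vpc"`: `bands` (data.frame per bin x
#'   percentile: observed value, simulated 2.5/50/97.5 band), `
#'   inside_fraction`, `n_sim`.
#' @export
vpc <- function(fit, n_sim = 500, seed = 1, bins = NULL,
                probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(fit, "mg_fit"), n_sim >= 100)
  eng <- .build_engine(fit$dataset, fit$spec)
  tv <- .typical_cl_v(eng, fit$theta)
  bin_id <- if (is.null(bins)) match(eng$t_obs, sort(unique(eng$t_obs)))
            else findInterval(eng$t_obs, bins)
  set.seed(seed)
  sims <- matrix(NA_real_, eng$N, n_sim)
  act <- fit$omega2 > 0
  for (r in seq_len(n_sim)) {
    eta <- cbind(stats::rnorm(eng$S, 0, sqrt(max(fit$omega2[1], 0))),
                 stats::rnorm(eng$S, 0, sqrt(max(fit$omega2[2], 0))))
    eta[, !act] <- 0
    f <- .joint_parts(eng, tv, eta, fit$omega2, fit$sigma)$f
    sims[, r] <- f + stats::rnorm(eng$N, 0, sqrt(.sigma2(fit$sigma, f)))
  }
  lo <- apply(sims, 1, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(sims, 1, stats::quantile, probs = 0.975, names = FALSE)
  inside <- mean(eng$dv >= lo & eng$dv <= hi)

  ubins <- sort(unique(bin_id))
  rows <- list()
  for (b in ubins) {
    oi <- which(bin_id == b)
    obs_q <- stats::quantile(eng$dv[oi], probs = probs, names = FALSE)
    sim_q <- apply(sims[oi, , drop = FALSE], 2, stats::quantile,
                   probs = probs, names = FALSE)
    sim_q <- matrix(sim_q, nrow = length(probs))
    band <- apply(sim_q, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
                  names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      bin = b, time = stats::median(eng$t_obs[oi]), n = length(oi),
      percentile = 100 * probs, observed = obs_q,
      sim_lo = band[1, ], sim_mid = band[2, ], sim_hi = band[3, ])
  }
  structure(list(bands = do.call(rbind, rows), inside_fraction = inside,
                 n_sim = n_sim),
            class = "mg_vpc")
}

#' @export
print.mg_vpc <- function(x, ...) {
  cat("Visual predictive check (", x$n_sim, " simulations)\n", sep = "")
  cat(sprintf("observations inside simulated 2.5-97.5%% band: %.1f%%\n",
              100 * x$inside_fraction))
  print(transform(x$bands, observed = round(observed, 2),
                  sim_lo = round(sim_lo, 2), sim_mid = round(sim_mid, 2),
                  sim_hi = round(sim_hi, 2)))
  invisible(x)
}
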