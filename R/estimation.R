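## FOCE-type nonlinear mixed-effects estimation for the one-compartment
## infusion model with log-normal between-subject variability on CL and V.
##
## The marginal -2 log-likelihood is approximated subject-by-subject by a
## Laplace-type expansion at the conditional mode of the random effects
## (empirical Bayes estimate), with the curvature taken as the Gauss-Newton
## (FOCE) form G' Sigma^-1 G + Omega^-1, where G is the analytic sensitivity
## of the predictions to eta at the mode. The inner mode search is a damped
## Gauss-Newton iteration vectorized across subjects; the outer search over
## (theta, omega, sigma) uses nlminb on a transformed scale that keeps
## variances positive and proportional covariate factors positive.

## ---- engine: precompiled arrays for one dataset + model spec -------------

.build_engine <- function(dataset, spec) {
  d <- dataset
  need <- c("ID", "TIME", "EVID")
  if (!all(need %in% names(d))) stop("dataset lacks columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  obs <- d[d$EVID == 0 & (is.null(d$MDV) | d$MDV == 0), , drop = FALSE]
  dos <- d[d$EVID == 1, , drop = FALSE]
  if (nrow(obs) == 0) stop("dataset has no observation rows")
  ids <- unique(d$ID)
  S <- length(ids)
  sidx <- match(obs$ID, ids)                # subject index per observation
  N <- nrow(obs)

  baseline_obs <- switch(spec$baseline,
    data = {
      if (is.null(obs$BASELINE)) stop("baseline = 'data' needs a BASELINE column")
      obs$BASELINE
    },
    global = rep(spec$baseline_value, N),
    zero = rep(0, N))

  ## observation x dose-event pair expansion (same subject)
  dsub <- match(dos$ID, ids)
  p_oidx <- integer(0); p_d <- integer(0)
  for (s in seq_len(S)) {
    oi <- which(sidx == s); di <- which(dsub == s)
    if (length(oi) && length(di)) {
      p_oidx <- c(p_oidx, rep(oi, each = length(di)))
      p_d <- c(p_d, rep(di, times = length(oi)))
    }
  }
  dur <- dos$DUR[p_d]
  if (any(!is.finite(dur)) || any(dur <= 0)) stop("dose rows need DUR > 0")
  eng <- list2env(list(
    S = S, N = N, ids = ids, sidx = sidx,
    t_obs = obs$TIME, dv = obs$DV, baseline = baseline_obs,
    p_oidx = p_oidx, p_s = sidx[p_oidx],
    p_rate = dos$AMT[p_d] * spec$salt_factor / dur,
    p_t0 = dos$TIME[p_d], p_dur = dur,
    p_t = obs$TIME[p_oidx]
  ), parent = emptyenv())

  ## subject-level covariate design, split by parameter and form.
  ## log CL_typ = log tvCL + sum_pow coef * log(x/ref) + sum_prop x*log1p(coef)
  first <- match(ids, d$ID)
  for (par in c("CL", "V")) {
    Xp <- NULL; Xb <- NULL; pnm <- character(0); bnm <- character(0)
    for (e in spec$effects) {
      if (e$parameter != par) next
      x <- d[[e$covariate]][first]
      if (is.null(x) || any(!is.finite(x)))
        stop("covariate column missing or non-finite: ", e$covariate)
      if (e$form == "power") {
        if (any(x <= 0)) stop("non-positive values in power covariate ", e$covariate)
        Xp <- cbind(Xp, log(x / e$ref)); pnm <- c(pnm, e$name)
      } else {
        if (!all(x %in% c(0, 1)))
          stop("proportional covariate must be binary 0/1: ", e$covariate)
        Xb <- cbind(Xb, x); bnm <- c(bnm, e$name)
      }
    }
    if (!is.null(Xp)) colnames(Xp) <- pnm
    if (!is.null(Xb)) colnames(Xb) <- bnm
    assign(paste0("Xpow_", par), Xp, envir = eng)
    assign(paste0("Xprop_", par), Xb, envir = eng)
  }
  eng$eta <- matrix(0, S, 2)                 # warm-started EBEs
  eng
}

## typical CL/V per subject for a theta vector
.typical_cl_v <- function(eng, theta) {
  logCL <- rep(log(theta[["tvCL"]]), eng$S)
  logV <- rep(log(theta[["tvV"]]), eng$S)
  add_terms <- function(lg, Xp, Xb) {
    if (!is.null(Xp)) lg <- lg + drop(Xp %*% theta[colnames(Xp)])
    if (!is.null(Xb)) lg <- lg + drop(Xb %*% log1p(theta[colnames(Xb)]))
    lg
  }
  list(CL = exp(add_terms(logCL, eng$Xpow_CL, eng$Xprop_CL)),
       V = exp(add_terms(logV, eng$Xpow_V, eng$Xprop_V)))
}

## predictions and sensitivities to (log CL, log V) for per-subject CL, V
.predict <- function(eng, CL, V, grad = FALSE) {
  k <- CL / V
  cl_p <- CL[eng$p_s]; k_p <- k[eng$p_s]
  if (grad) {
    g <- .event_conc_grad(eng$p_t, eng$p_rate, eng$p_t0, eng$p_dur, cl_p, k_p)
    rs <- rowsum(cbind(g$c, g$dca, g$dcdb), eng$p_oidx)
    M <- matrix(0, eng$N, 3)
    M[as.integer(rownames(rs)), ] <- rs
    list(f = eng$baseline + M[, 1], Ga = M[, 2], Gb = M[, 3])
  } else {
    cc <- .event_conc(eng$p_t, eng$p_rate, eng$p_t0, eng$p_dur, cl_p, k_p)
    rs <- rowsum(cc, eng$p_oidx)
    above <- numeric(eng$N)
    above[as.integer(rownames(rs))] <- rs
    list(f = eng$baseline + above)
  }
}

.sigma2 <- function(sigma, f) {
  switch(sigma$kind,
    additive = rep(sigma$stdev0^2, length(f)),
    proportional = pmax(sigma$cv0 * f, 1e-6)^2,
    combined = sigma$stdev0^2 + (sigma$cv0 * f)^2)
}

## per-subject joint -2 log-likelihood pieces at given etas
.joint_parts <- function(eng, tv, eta, omega2, sigma, grad = FALSE) {
  CL <- tv$CL * exp(eta[, 1]); V <- tv$V * exp(eta[, 2])
  pr <- .predict(eng, CL, V, grad = grad)
  r <- eng$dv - pr$f
  s2 <- .sigma2(sigma, pr$f)
  res_i <- drop(rowsum(log(2 * pi * s2) + r^2 / s2, eng$sidx))
  act <- omega2 > 0
  prior_i <- 0
  for (j in 1:2) if (act[j])
    prior_i <- prior_i + log(2 * pi * omega2[j]) + eta[, j]^2 / omega2[j]
  out <- list(joint = res_i + prior_i, r = r, s2 = s2, f = pr$f, act = act)
  if (grad) { out$Ga <- pr$Ga; out$Gb <- pr$Gb }
  out
}

## vectorized damped Gauss-Newton search for the conditional eta modes
.inner_modes <- function(eng, tv, omega2, sigma, max_iter = 50, tol = 1e-8) {
  eta <- eng$eta
  act <- omega2 > 0
  eta[, !act] <- 0
  if (!any(act)) {
    jp <- .joint_parts(eng, tv, eta, omega2, sigma, grad = TRUE)
    return(list(eta = eta, parts = jp))
  }
  jp <- .joint_parts(eng, tv, eta, omega2, sigma, grad = TRUE)
  for (it in seq_len(max_iter)) {
    w <- 1 / jp$s2
    gr1 <- drop(rowsum(-2 * jp$r * jp$Ga * w, eng$sidx))
    gr2 <- drop(rowsum(-2 * jp$r * jp$Gb * w, eng$sidx))
    if (act[1]) gr1 <- gr1 + 2 * eta[, 1] / omega2[1]
    if (act[2]) gr2 <- gr2 + 2 * eta[, 2] / omega2[2]
    h11 <- 2 * (drop(rowsum(jp$Ga^2 * w, eng$sidx)) + if (act[1]) 1 / omega2[1] else 0)
    h22 <- 2 * (drop(rowsum(jp$Gb^2 * w, eng$sidx)) + if (act[2]) 1 / omega2[2] else 0)
    h12 <- 2 * drop(rowsum(jp$Ga * jp$Gb * w, eng$sidx))
    st1 <- st2 <- numeric(eng$S)
    if (all(act)) {
      det <- h11 * h22 - h12^2
      bad <- det < 1e-10 | h11 <= 0 | h22 <= 0
      if (any(bad)) {            # ridge the rare indefinite subjects
        h11[bad] <- h11[bad] + 1; h22[bad] <- h22[bad] + 1
        det[bad] <- h11[bad] * h22[bad] - h12[bad]^2
      }
      st1 <- (h22 * gr1 - h12 * gr2) / det
      st2 <- (h11 * gr2 - h12 * gr1) / det
    } else if (act[1]) st1 <- gr1 / h11 else st2 <- gr2 / h22
    if (max(abs(c(st1, st2))) < tol) break
    ## masked backtracking line search on the exact joint objective
    sc <- rep(1, eng$S)
    for (ls in 1:12) {
      eta_try <- eta
      eta_try[, 1] <- eta[, 1] - sc * st1
      eta_try[, 2] <- eta[, 2] - sc * st2
      jp_try <- .joint_parts(eng, tv, eta_try, omega2, sigma, grad = TRUE)
      worse <- jp_try$joint > jp$joint + 1e-10
      if (!any(worse)) break
      sc[worse] <- sc[worse] / 2
      if (ls == 12) {            # give up on stragglers: freeze their eta
        eta_try[worse, ] <- eta[worse, , drop = FALSE]
        jp_try <- .joint_parts(eng, tv, eta_try, omega2, sigma, grad = TRUE)
      }
    }
    moved <- max(abs(sc * c(st1, st2)))
    eta <- eta_try; jp <- jp_try
    if (moved < tol) break
  }
  eng$eta <- eta                             # warm start for the next call
  list(eta = eta, parts = jp)
}

## FOCE objective: Laplace value with Gauss-Newton curvature at the mode
.foce_ofv <- function(eng, tv, omega2, sigma) {
  md <- .inner_modes(eng, tv, omega2, sigma)
  jp <- md$parts
  act <- jp$act
  q <- sum(act)
  if (q == 0) return(list(ofv = sum(jp$joint), md = md))
  w <- 1 / jp$s2
  a11 <- drop(rowsum(jp$Ga^2 * w, eng$sidx)) + if (act[1]) 1 / omega2[1] else 0
  a22 <- drop(rowsum(jp$Gb^2 * w, eng$sidx)) + if (act[2]) 1 / omega2[2] else 0
  a12 <- drop(rowsum(jp$Ga * jp$Gb * w, eng$sidx))
  logdet <- if (all(act)) log(pmax(a11 * a22 - a12^2, 1e-300))
            else if (act[1]) log(pmax(a11, 1e-300)) else log(pmax(a22, 1e-300))
  list(ofv = sum(jp$joint + logdet - q * log(2 * pi)), md = md)
}

## ---- parameter packing ---------------------------------------------------

.par_info <- function(spec, omega2_init, sigma_init, fix_sigma = FALSE) {
  nm <- c("tvCL", "tvV", vapply(spec$effects, `[[`, character(1), "name"))
  trans <- c("log", "log",
             vapply(spec$effects, function(e)
               if (e$form == "power") "id" else "atanh", character(1)))
  if (omega2_init[1] > 0) { nm <- c(nm, "omega2CL"); trans <- c(trans, "log") }
  if (omega2_init[2] > 0) { nm <- c(nm, "omega2V"); trans <- c(trans, "log") }
  if (!fix_sigma) {
    if (sigma_init$kind %in% c("additive", "combined")) {
      nm <- c(nm, "stdev0"); trans <- c(trans, "log")
    }
    if (sigma_init$kind %in% c("proportional", "combined")) {
      nm <- c(nm, "cv0"); trans <- c(trans, "log")
    }
  }
  list(names = nm, trans = trans)
}

.to_trans <- function(x, trans) {
  out <- x
  out[trans == "log"] <- log(x[trans == "log"])
  out[trans == "atanh"] <- atanh(x[trans == "atanh"])
  out
}
.from_trans <- function(u, trans) {
  out <- u
  out[trans == "log"] <- exp(u[trans == "log"])
  out[trans == "atanh"] <- tanh(u[trans == "atanh"])
  out
}

.split_par <- function(p, info, spec, omega2_fixed, sigma_fixed = NULL) {
  th_names <- c("tvCL", "tvV", vapply(spec$effects, `[[`, character(1), "name"))
  theta <- p[th_names]
  omega2 <- omega2_fixed
  if ("omega2CL" %in% info$names) omega2[1] <- p[["omega2CL"]]
  if ("omega2V" %in% info$names) omega2[2] <- p[["omega2V"]]
  sigma <- if (is.null(sigma_fixed)) list(kind = spec$error$kind) else sigma_fixed
  if ("stdev0" %in% info$names) sigma$stdev0 <- p[["stdev0"]]
  if ("cv0" %in% info$names) sigma$cv0 <- p[["cv0"]]
  list(theta = theta, omega2 = omega2, sigma = sigma)
}

## ---- public operations ---------------------------------------------------

#' Joint -2 log-likelihood of one subject's data and random effects
#'
#' The conditional density of the observations given `eta` times the
#' normal prior of `eta`, on the -2 log scale: the quantity minimized over
#' `eta` in the FOCE inner step.
#'
#' @param subject_data dataset rows (dose + observation) for one subject.
#' @param eta numeric length-2, `(etaCL, etaV)`.
#' @param theta named fixed-effect vector (see [typical_values()]).
#' @param omega2 length-2 variances `(CL, V)`; a zero entry drops that
#'   random effect (its eta is ignored and no prior term enters).
#' @param sigma residual model list (`kind`, `stdev0`, `cv0`).
#' @param spec a [model_spec()].
#' @return scalar -2 log joint density.
#' @export
individual_joint_neg2ll <- function(subject_data, eta, theta, omega2, sigma,
                                    spec) {
  eng <- .build_engine(subject_data, spec)
  if (eng$S != 1) stop("subject_data must contain exactly one subject")
  tv <- .typical_cl_v(eng, theta)
  em <- matrix(eta, 1, 2)
  em[1, omega2 <= 0] <- 0
  as.numeric(.joint_parts(eng, tv, em, omega2, sigma)$joint)
}

#' AIC and BIC from an objective function value
#'
#' `AIC = OFV + 2p`, `BIC = OFV + p log(n)` with `p` estimated parameters
#' and `n` observations; OFV is the -2 log-likelihood approximation.
#'
#' @param ofv objective function value.
#' @param p number of estimated parameters (>= 0).
#' @param n number of observations (>= 1).
#' @return named numeric `c(AIC, BIC)`.
#' @export
information_criteria <- function(ofv, p, n) {
  stopifnot(p >= 0, n >= 1)
  c(AIC = ofv + 2 * p, BIC = ofv + p * log(n))
}

#' Eta shrinkage from empirical Bayes estimates
#'
#' `100 (1 - SD(EBE)/omega)` per random effect; sparse designs pull the
#' EBEs toward zero, inflating shrinkage.
#'
#' @param etas matrix of EBEs, one row per subject, one column per effect.
#' @param omega2 vector of population variances matching the columns.
#' @return percent shrinkage per column, clipped to `[0, 100]` (a value
#'   below 0, possible when the EBE spread exceeds omega, is clipped with a
#'   warning).
#' @export
eta_shrinkage <- function(etas, omega2) {
  etas <- as.matrix(etas)
  if (nrow(etas) < 2) stop("shrinkage needs at least 2 subjects")
  out <- rep(NA_real_, length(omega2))
  for (j in seq_along(omega2)) {
    if (omega2[j] <= 0) { warning("omega = 0: shrinkage undefined"); next }
    shr <- 100 * (1 - stats::sd(etas[, j]) / sqrt(omega2[j]))
    if (shr < 0) { warning("EBE spread exceeds omega; shrinkage clipped at 0")
                   shr <- 0 }
    out[j] <- min(shr, 100)
  }
  out
}

#' Fit the population model by FOCE
#'
#' Maximizes the FOCE/Laplace-approximated marginal likelihood: for each
#' candidate `(theta, omega, sigma)` the conditional mode of each subject's
#' random effects is found by damped Gauss-Newton (analytic prediction
#' sensitivities), and the marginal -2 log-likelihood is approximated with
#' the Gauss-Newton curvature at the mode. Deterministic given `inits` and
#' `options`.
#'
#' @param dataset event dataset (see [read_dataset()] / [generate_study()]);
#'   internal units (hours, mg/L, labelled grams).
#' @param spec a [model_spec()].
#' @param inits optional named list overriding default initial values:
#'   `theta` (named), `omega2` (length-2 `c(CL, V)`; set an entry to 0 to
#'   fix that random effect out of the model), `sigma` (list).
#' @param options list: `compute_se` (default TRUE), `max_iter` outer
#'   iteration cap (500), `rel_tol` relative OFV tolerance (1e-10).
#' @return an object of class `"mg_fit"`: `theta`, `omega2`, `sigma`, `OFV`,
#'   `AIC`, `BIC`, `etas`, `shrinkage_pct`, `se`, `cv_pct`, `converged`,
#'   `n_obs`, `n_subjects`, `n_par`, plus the spec and dataset for
#'   downstream diagnostics.
#' @export
foce_fit <- function(dataset, spec, inits = NULL, options = list()) {
  opt <- utils::modifyList(list(compute_se = TRUE, max_iter = 500,
                                rel_tol = 1e-8, fix_sigma = FALSE), options)
  eng <- .build_engine(dataset, spec)
  if (eng$S < 1) stop("no subjects")

  ## default inits: neutral coefficients, coarse scale guesses
  eff_names <- vapply(spec$effects, `[[`, character(1), "name")
  theta0 <- c(tvCL = 3, tvV = 20, stats::setNames(rep(0, length(eff_names)), eff_names))
  omega20 <- c(CL = 0.1, V = 0.1)
  sigma0 <- list(kind = spec$error$kind, stdev0 = 2, cv0 = 0.2)
  if (!is.null(inits$theta)) theta0[names(inits$theta)] <- inits$theta
  if (!is.null(inits$omega2)) omega20[] <- inits$omega2
  if (!is.null(inits$sigma)) sigma0 <- utils::modifyList(sigma0, inits$sigma)
  sigma0 <- sigma0[c("kind", intersect(c("stdev0", "cv0"), names(sigma0)))]

  info <- .par_info(spec, omega20, sigma0, fix_sigma = opt$fix_sigma)
  nat0 <- c(theta0, if (omega20[1] > 0) c(omega2CL = unname(omega20[1])),
            if (omega20[2] > 0) c(omega2V = unname(omega20[2])),
            if (sigma0$kind %in% c("additive", "combined")) c(stdev0 = sigma0$stdev0),
            if (sigma0$kind %in% c("proportional", "combined")) c(cv0 = sigma0$cv0))
  nat0 <- nat0[info$names]
  u0 <- .to_trans(nat0, info$trans)

  nat_ofv <- function(nat) {
    pp <- .split_par(nat, info, spec, omega20, sigma0)
    if (pp$theta[["tvCL"]] <= 0 || pp$theta[["tvV"]] <= 0) return(1e10)
    tv <- try(.typical_cl_v(eng, pp$theta), silent = TRUE)
    if (inherits(tv, "try-error") || any(!is.finite(tv$CL)) ||
        any(!is.finite(tv$V)) || any(tv$CL <= 0) || any(tv$V <= 0)) return(1e10)
    v <- .foce_ofv(eng, tv, pp$omega2, pp$sigma)$ofv
    if (!is.finite(v)) 1e10 else v
  }
  obj <- function(u) nat_ofv(stats::setNames(.from_trans(u, info$trans), info$names))

  ofv0 <- obj(u0)
  if (!is.finite(ofv0) || ofv0 >= 1e10)
    stop("objective is not finite at the initial values")

  ctl <- list(iter.max = opt$max_iter, eval.max = 4 * opt$max_iter,
              rel.tol = opt$rel_tol)
  res <- stats::nlminb(u0, obj, control = ctl)
  nat <- stats::setNames(.from_trans(res$par, info$trans), info$names)
  pp <- .split_par(nat, info, spec, omega20, sigma0)

  ## final inner pass at the optimum (refresh EBEs and OFV)
  tv <- .typical_cl_v(eng, pp$theta)
  fo <- .foce_ofv(eng, tv, pp$omega2, pp$sigma)
  ofv <- min(fo$ofv, ofv0)
  p_n <- length(info$names)
  ic <- information_criteria(ofv, p_n, eng$N)

  etas <- fo$md$eta
  dimnames(etas) <- list(eng$ids, c("CL", "V"))
  shr <- rep(NA_real_, 2)
  if (eng$S >= 2)
    shr <- suppressWarnings(eta_shrinkage(etas, pp$omega2))

  fit <- structure(list(
    theta = pp$theta, omega2 = pp$omega2, sigma = pp$sigma,
    OFV = ofv, AIC = unname(ic["AIC"]), BIC = unname(ic["BIC"]),
    etas = etas, shrinkage_pct = stats::setNames(shr, c("CL", "V")),
    se = NULL, cv_pct = NULL,
    converged = (res$convergence == 0) && is.finite(ofv),
    n_obs = eng$N, n_subjects = eng$S, n_par = p_n,
    par_names = info$names, par_info = info, spec = spec, dataset = dataset,
    nlminb_message = res$message
  ), class = "mg_fit")

  if (opt$compute_se) {
    se <- try(.fit_se(nat, nat_ofv), silent = TRUE)
    if (!inherits(se, "try-error")) {
      fit$se <- se
      fit$cv_pct <- 100 * se / abs(nat)
    } else warning("standard errors unavailable (Hessian not invertible)")
  }
  fit$estimates <- nat
  fit
}

## SE from the inverse numeric Hessian (central differences) of OFV/2
.fit_se <- function(nat, nat_ofv) {
  p <- length(nat)
  h <- pmax(abs(nat), 0.01) * 1e-3
  H <- matrix(NA_real_, p, p)
  f0 <- nat_ofv(nat)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- nat; xp[i] <- xp[i] + h[i]
        xm <- nat; xm[i] <- xm[i] - h[i]
        H[i, i] <- (nat_ofv(xp) - 2 * f0 + nat_ofv(xm)) / h[i]^2
      } else {
        xpp <- nat; xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
        xpm <- nat; xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
        xmp <- nat; xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
        xmm <- nat; xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
        H[i, j] <- H[j, i] <-
          (nat_ofv(xpp) - nat_ofv(xpm) - nat_ofv(xmp) + nat_ofv(xmm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  ## Var = [H(-logL)]^-1 = [H(OFV)/2]^-1
  V <- 2 * solve(H)
  se <- sqrt(pmax(diag(V), 0))
  stats::setNames(se, names(nat))
}

#' Standard errors of a fitted model
#'
#' Square roots of the diagonal of the inverse numerical Hessian (central
#' differences) of half the objective function at the optimum, on the
#' natural parameter scale; `CV% = 100 se / |estimate|`.
#'
#' @param fit an `"mg_fit"` (with `compute_se = TRUE` these are already
#'   attached; this recomputes them).
#' @return data.frame with `parameter`, `estimate`, `se`, `cv_pct`.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "mg_fit"))
  eng <- .build_engine(fit$dataset, fit$spec)
  info <- fit$par_info
  nat <- fit$estimates
  nat_ofv <- function(natv) {
    pp <- .split_par(natv, info, fit$spec, fit$omega2, fit$sigma)
    tv <- .typical_cl_v(eng, pp$theta)
    .foce_ofv(eng, tv, pp$omega2, pp$sigma)$ofv
  }
  se <- .fit_se(nat, nat_ofv)
  data.frame(parameter = names(nat), estimate = unname(nat),
             se = unname(se), cv_pct = unname(100 * se / abs(nat)))
}

#' @export
print.mg_fit <- function(x, ...) {
  cat("FOCE fit:", x$n_subjects, "subjects,", x$n_obs, "observations\n")
  cat(sprintf("OFV %.3f  AIC %.3f  BIC %.3f  (%d parameters, converged: %s)\n",
              x$OFV, x$AIC, x$BIC, x$n_par, x$converged))
  est <- x$estimates
  tab <- data.frame(estimate = est)
  if (!is.null(x$se)) { tab$se <- x$se; tab$cv_pct <- x$cv_pct }
  print(round(tab, 4))
  cat(sprintf("eta shrinkage (%%): CL %.1f, V %.1f\n",
              x$shrinkage_pct[1], x$shrinkage_pct[2]))
  invisible(x)
}

#' Flat parameter table of a fit
#'
#' @param fit an `"mg_fit"`.
#' @return data.frame with estimate, se, CV%, and shrinkage for the
#'   variance rows; suitable for CSV export.
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "mg_fit"))
  est <- fit$estimates
  d <- data.frame(parameter = names(est), estimate = unname(est),
                  se = NA_real_, cv_pct = NA_real_, shrinkage_pct = NA_real_)
  if (!is.null(fit$se)) { d$se <- unname(fit$se); d$cv_pct <- unname(fit$cv_pct) }
  d$shrinkage_pct[d$parameter == "omega2CL"] <- fit$shrinkage_pct["CL"]
  d$shrinkage_pct[d$parameter == "omega2V"] <- fit$shrinkage_pct["V"]
  d
}
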