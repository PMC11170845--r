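#' Likelihood-ratio threshold for covariate inclusion/elimination
#'
#' Upper-`alpha` quantile of the chi-square distribution: the drop (or
#' rise) in OFV a nested one-parameter extension must achieve. At 1 df the
#' forward criterion alpha = 0.01 gives 6.63 and the backward criterion
#' alpha = 0.001 gives 10.83.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return scalar critical value of the change in OFV.
#' @examples
#' lrt_threshold(0.01, 1)   # 6.63
#' lrt_threshold(0.001, 1)  # 10.83
#' @export
lrt_threshold <- function(alpha, df = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (!is.finite(df) || df < 1) stop("df must be >= 1")
  stats::qchisq(1 - alpha, df)
}

## decision rules, factored out so boundary semantics are testable directly
.accept_forward <- function(delta_ofv, threshold) {
  is.finite(delta_ofv) & delta_ofv >= threshold    # >= : inclusive
}
.retain_backward <- function(delta_ofv, threshold) {
  is.finite(delta_ofv) & delta_ofv >= threshold
}

## fit current spec + extra effects; returns fit or NULL on failure
.try_fit <- function(dataset, spec, effects, inits, options) {
  spec2 <- spec
  spec2$effects <- effects
  f <- try(foce_fit(dataset, spec2,
                    inits = inits,
                    options = utils::modifyList(options, list(compute_se = FALSE))),
           silent = TRUE)
  if (inherits(f, "try-error") || !f$converged) NULL else f
}

.effect_label <- function(e) paste0(e$covariate, "->", e$parameter)

#' One forward-selection step
#'
#' Fits the current model extended by each remaining candidate in turn and
#' accepts the candidate with the largest drop in OFV, provided that drop
#' meets the forward threshold (inclusive). Ties are broken by candidate
#' label order. Candidates whose fit fails to converge are skipped and
#' logged.
#'
#' @param fit current fitted model (`"mg_fit"`).
#' @param candidates list of [covariate_effect()] not yet in the model.
#' @param dataset event dataset.
#' @param threshold forward OFV-drop criterion (default
#'   `lrt_threshold(0.01, 1)` = 6.63).
#' @param options estimation options passed through to [foce_fit()].
#' @return list: `accepted` (index into `candidates`, or `NA`), `fit` (the
#'   accepted extended fit, or `NULL`), `trace` (one data.frame row per
#'   candidate tried).
#' @export
forward_step <- function(fit, candidates, dataset,
                         threshold = lrt_threshold(0.01, 1),
                         options = list()) {
  stopifnot(inherits(fit, "mg_fit"))
  inits <- list(theta = fit$theta, omega2 = fit$omega2,
                sigma = fit$sigma[setdiff(names(fit$sigma), "kind")])
  rows <- list(); fits <- vector("list", length(candidates))
  for (j in seq_along(candidates)) {
    cand <- candidates[[j]]
    f <- .try_fit(dataset, fit$spec, c(fit$spec$effects, list(cand)),
                  inits, options)
    fits[[j]] <- f
    rows[[j]] <- data.frame(
      candidate = .effect_label(cand),
      ofv_base = fit$OFV,
      ofv_new = if (is.null(f)) NA_real_ else f$OFV,
      delta_ofv = if (is.null(f)) NA_real_ else fit$OFV - f$OFV,
      converged = !is.null(f))
  }
  trace <- do.call(rbind, rows)
  ok <- .accept_forward(trace$delta_ofv, threshold)
  accepted <- NA_integer_
  if (any(ok)) {
    ## largest delta wins; ties by label order
    cand_ord <- order(-trace$delta_ofv, trace$candidate)
    accepted <- cand_ord[ok[cand_ord]][1]
  }
  trace$decision <- "rejected"
  trace$decision[!trace$converged] <- "skipped (no convergence)"
  if (!is.na(accepted)) trace$decision[accepted] <- "accepted"
  list(accepted = accepted,
       fit = if (is.na(accepted)) NULL else fits[[accepted]],
       trace = trace)
}

#' Backward elimination
#'
#' Starting from the full forward model, repeatedly removes the effect
#' whose removal raises the OFV the least, until every remaining effect's
#' removal would raise the OFV by at least the backward threshold.
#'
#' @param fit fitted full model after forward selection.
#' @param dataset event dataset.
#' @param threshold backward OFV-rise criterion (default
#'   `lrt_threshold(0.001, 1)` = 10.83).
#' @param removable optional character vector of effect names eligible for
#'   elimination (default: all effects in the model).
#' @param options estimation options.
#' @return list: `fit` (final model), `trace` (data.frame of every removal
#'   tried, with decisions).
#' @export
backward_step <- function(fit, dataset,
                          threshold = lrt_threshold(0.001, 1),
                          removable = NULL, options = list()) {
  stopifnot(inherits(fit, "mg_fit"))
  trace <- list(); step <- 0L
  repeat {
    effs <- fit$spec$effects
    if (length(effs) == 0) break
    elig <- if (is.null(removable)) seq_along(effs)
            else which(vapply(effs, `[[`, character(1), "name") %in% removable)
    if (length(elig) == 0) break
    inits <- list(theta = fit$theta, omega2 = fit$omega2,
                  sigma = fit$sigma[setdiff(names(fit$sigma), "kind")])
    step <- step + 1L
    deltas <- rep(NA_real_, length(elig)); fits <- vector("list", length(elig))
    for (m in seq_along(elig)) {
      f <- .try_fit(dataset, fit$spec, effs[-elig[m]], inits, options)
      fits[[m]] <- f
      if (!is.null(f)) deltas[m] <- f$OFV - fit$OFV    # rise on removal
    }
    lab <- vapply(effs[elig], .effect_label, character(1))
    retained <- .retain_backward(deltas, threshold)
    trace[[step]] <- data.frame(step = step, candidate = lab,
                                ofv_base = fit$OFV,
                                ofv_new = vapply(fits, function(f)
                                  if (is.null(f)) NA_real_ else f$OFV, numeric(1)),
                                delta_ofv = deltas,
                                decision = ifelse(is.na(deltas), "skipped (no convergence)",
                                           ifelse(retained, "retained", "removable")))
    drop_idx <- which(!retained & !is.na(deltas))
    if (length(drop_idx) == 0) break
    ## remove the effect whose loss costs least
    m <- drop_idx[order(deltas[drop_idx], lab[drop_idx])][1]
    trace[[step]]$decision[m] <- "removed"
    fit <- fits[[m]]
  }
  list(fit = fit, trace = if (length(trace)) do.call(rbind, trace)
                          else data.frame())
}

#' Full stepwise covariate modeling
#'
#' Forward inclusion (one candidate per step, largest qualifying OFV drop,
#' threshold 6.63) until no candidate qualifies, then backward elimination
#' (threshold 10.83) over the newly added effects. Deterministic given the
#' dataset and options.
#'
#' @param dataset event dataset.
#' @param base_spec base [model_spec()] (its effects, if any, are kept and
#'   not eligible for elimination).
#' @param candidates list of [covariate_effect()] to screen.
#' @param forward_threshold,backward_threshold OFV criteria.
#' @param inits,options passed to the base fit / refits.
#' @return list of class `"mg_scm"`: `final_fit`, `base_fit`, `trace`
#'   (data.frame: phase, step, candidate, OFVs, delta, decision).
#' @export
run_scm <- function(dataset, base_spec, candidates,
                    forward_threshold = lrt_threshold(0.01, 1),
                    backward_threshold = lrt_threshold(0.001, 1),
                    inits = NULL, options = list()) {
  base_fit <- foce_fit(dataset, base_spec, inits = inits,
                       options = utils::modifyList(options, list(compute_se = FALSE)))
  fit <- base_fit
  remaining <- candidates
  trace <- list(); step <- 0L
  while (length(remaining) > 0) {
    step <- step + 1L
    fs <- forward_step(fit, remaining, dataset, forward_threshold, options)
    tr <- fs$trace
    tr$phase <- "forward"; tr$step <- step
    trace[[length(trace) + 1L]] <- tr
    if (is.na(fs$accepted)) break
    fit <- fs$fit
    remaining <- remaining[-fs$accepted]
  }
  added <- setdiff(vapply(fit$spec$effects, `[[`, character(1), "name"),
                   vapply(base_spec$effects, `[[`, character(1), "name"))
  if (length(added) > 0) {
    bs <- backward_step(fit, dataset, backward_threshold,
                        removable = added, options = options)
    if (nrow(bs$trace)) {
      tr <- bs$trace; tr$phase <- "backward"
      trace[[length(trace) + 1L]] <- tr
    }
    fit <- bs$fit
  }
  cols <- c("phase", "step", "candidate", "ofv_base", "ofv_new",
            "delta_ofv", "decision")
  trace <- if (length(trace)) {
    tr <- do.call(rbind, lapply(trace, function(d) d[, intersect(cols, names(d))]))
    tr
  } else data.frame()
  structure(list(final_fit = fit, base_fit = base_fit, trace = trace),
            class = "mg_scm")
}

#' @export
print.mg_scm <- function(x, ...) {
  eff <- vapply(x$final_fit$spec$effects, .effect_label, character(1))
  cat("Stepwise covariate modeling\n")
  cat("  base OFV:", round(x$base_fit$OFV, 3),
      " final OFV:", round(x$final_fit$OFV, 3), "\n")
  cat("  final effects:", if (length(eff)) paste(eff, collapse = ", ")
                          else "(none)", "\n")
  invisible(x)
}
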