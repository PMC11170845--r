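#!/usr/bin/env Rscript
## Model evaluation for the final fit: goodness-of-fit quantities
## (PRED/IPRED/CWRES), a 200-replicate nonparametric bootstrap (subject
## resampling) and a 500-replicate visual predictive check. All plot data
## are written as CSV; figures go to results/ as PNG when ggplot2 is
## available.

library(mgppk)

spec <- final_model_spec(ref_ccr = 182.18, ref_bmi = 29.13)
d <- read_dataset("results/synthetic_study.csv")
fit <- foce_fit(d, spec, options = list(compute_se = FALSE))

## goodness of fit -----------------------------------------------------------
g <- gof_table(fit)
write.csv(g, "results/gof_table.csv", row.names = FALSE)
cat(sprintf("CWRES: mean %.3f, sd %.3f, %.1f%% within +-2\n",
            mean(g$CWRES), sd(g$CWRES), 100 * mean(abs(g$CWRES) <= 2)))

## bootstrap -----------------------------------------------------------------
boot <- bootstrap_model(d, spec, B = 200, seed = 2,
                        inits = list(theta = fit$theta, omega2 = fit$omega2,
                                     sigma = list(stdev0 = fit$sigma$stdev0)))
print(boot)
write.csv(boot$summary, "results/bootstrap_summary.csv", row.names = FALSE)

## visual predictive check ---------------------------------------------------
v <- vpc(fit, n_sim = 500, seed = 3)
print(v)
write.csv(v$bands, "results/vpc_bands.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  gg <- ggplot(g, aes(PRED, DV)) + geom_point(alpha = 0.6) +
    geom_abline(linetype = 2) +
    labs(x = "Population prediction (mg/L)", y = "Observed (mg/L)")
  ggsave("results/gof_dv_vs_pred.png", gg, width = 5, height = 4, dpi = 150)
  gg <- ggplot(g, aes(TIME, CWRES)) + geom_point(alpha = 0.6) +
    geom_hline(yintercept = c(-2, 0, 2), linetype = c(3, 2, 3)) +
    labs(x = "Time (h)", y = "CWRES")
  ggsave("results/gof_cwres_vs_time.png", gg, width = 5, height = 4, dpi = 150)
  vb <- v$bands
  gg <- ggplot(vb, aes(time, observed, group = percentile)) +
    geom_ribbon(aes(ymin = sim_lo, ymax = sim_hi), alpha = 0.25) +
    geom_line(aes(y = sim_mid), linetype = 2) + geom_point() +
    labs(x = "Time (h)", y = "Serum magnesium (mg/L)",
         title = "VPC: observed percentiles vs simulated bands")
  ggsave("results/vpc.png", gg, width = 6, height = 4, dpi = 150)
}
cat("written: results/gof_table.csv, results/bootstrap_summary.csv, results/vpc_bands.csv\n")
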