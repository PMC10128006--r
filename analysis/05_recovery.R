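#!/usr/bin/env Rscript
# Parameter-recovery validation of the fitting pipeline on synthetic data.
#
# Generates endpoint observations from known reaction extents (the control
# quad-culture reference scenario with the redundant lactate-shuttle route
# inactive), refits them, and summarises per-reaction bias and RMSE over
# 100 seeded generate-fit cycles at the replicate-error noise scale. A
# second scenario places truth on the degenerate stratum to show that only
# the route *sum* is recoverable there.

suppressPackageStartupMessages(library(synflux))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(noise = 0.02, replicates = 3, seed = 1)
rec <- recovery_experiment(cfg, n_runs = 100)
cat("identifiable reference scenario (noise 0.02 mmol, 100 runs):\n")
print(rec, digits = 3)
cat(sprintf("max |bias| = %.4f mmol\n", max(abs(rec$bias))))
write.csv(rec, "results/recovery.csv", row.names = FALSE)

# degenerate truth: both fermenter routes and the lactate shuttle active
cfg_deg <- generator_config(
  extents = c(rc_lactate = 0.4, rc_acetogenesis = 0.6, dv_lactate_h2 = 0.5,
              mh_methanogenesis = 0.49, mc_methanogenesis = 0.99),
  noise = 0.02, replicates = 3, seed = 1)
rec_deg <- recovery_experiment(cfg_deg, n_runs = 100)
est <- attr(rec_deg, "estimates")
route_sum <- est[, "rc_acetogenesis"] + est[, "dv_lactate_h2"] / 2
true_sum <- 0.6 + 0.5 / 2
cat(sprintf("\ndegenerate scenario: individual route biases %s mmol,\n",
            paste(sprintf("%+.3f", rec_deg$bias[2:3]), collapse = " / ")))
cat(sprintf("but the acetogenic-equivalent route sum is recovered: bias %+.4f mmol\n",
            mean(route_sum) - true_sum))
cat("wrote results/recovery.csv\n")
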