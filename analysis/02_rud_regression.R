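#!/usr/bin/env Rscript
# Step 2: regress RUD on the scenario factors.
#
# OLS of per-run RUD on camera-layout indicators (reference: one fixed
# camera), demand per 1000 VPH, the group-B and group-C shares and the
# telematics rate. The interesting contrasts: how small the extra fixed
# cameras' coefficients are next to the point-to-point (average) layout,
# and the opposite signs of the violator shares versus enforcement factors.
#
# Usage: Rscript analysis/02_rud_regression.R
#                [--in results/scenario_results.csv]
#                [--out results/table1_regression.csv]

library(secsim)

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
in_csv <- get_arg("--in", "results/scenario_results.csv")
out_csv <- get_arg("--out", "results/table1_regression.csv")
if (!file.exists(in_csv))
  stop("no results at ", in_csv, "; run analysis/01_simulate_grid.R first")

res <- read.csv(in_csv, stringsAsFactors = FALSE)
fit <- fit_rud_regression(res)
print(fit)

co <- setNames(fit$table$coefficient, fit$table$variable)
message(sprintf(
  "point-to-point enforcement is %.1f times the three-camera effect",
  abs(co[["sec_P2P"]] / co[["sec_FIX3"]])))

write_regression_csv(fit, out_csv)
message("wrote ", out_csv)
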