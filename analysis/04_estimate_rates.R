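#!/usr/bin/env Rscript
# Step 4: rate estimation. For every molecule x replicate curve, detect
# the phosphorylation period (first return of the fold ratio to 1.0
# after its maximum), integrate the curve over [0, tau] by trapezoid,
# and report the divergence rate log(mean fold)/tau in nats/h.

suppressPackageStartupMessages(library(jqnkld))

tcs <- read_timecourses("results/timecourses.csv")
rates <- batch_estimate(tcs)
write.csv(rates, "results/rates.csv", row.names = FALSE)

cat("== Per-replicate divergence-rate estimates ==\n")
print(rates, digits = 3)
flagged <- rates$flags != ""
if (any(flagged))
  cat("\n", sum(flagged), " estimate(s) flagged (",
      paste(unique(rates$flags[flagged]), collapse = ", "),
      "): truncated periods mark curves that never return to baseline\n",
      "within the sampled window, e.g. the negative control.\n", sep = "")

truth <- jsonlite::read_json("results/truth.json", simplifyVector = TRUE)
cmp <- merge(aggregate(kld_rate_per_h ~ molecule, rates, mean),
             truth$truth[, c("molecule", "target_rate")], by = "molecule")
names(cmp) <- c("molecule", "estimated_mean", "true_rate")
cat("\n== Estimated means vs ground truth ==\n")
print(cmp, digits = 3)
cat("\nDeviations from 3.0 are driven by period-detection jitter where\n",
    "noise keeps the curve marginally above baseline into the sparsely\n",
    "sampled 60-180 min tail; the replicate SD carries the same jitter.\n",
    sep = "")
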