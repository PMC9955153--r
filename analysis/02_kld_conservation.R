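#!/usr/bin/env Rscript
# Step 2: the information-theoretic core. On the cascade's steady
# state, maximizing the KLD of the signalling state under a
# signal-duration budget makes lambda_oi * log(rho_i(t)/rho_i) the same
# at every node: the divergence rate -gamma = D/tau is conserved along
# the cascade. Also verifies the multinomial/Stirling identity behind
# the divergence and the entropy mapping Delta S = D.

suppressPackageStartupMessages(library(jqnkld))
dir.create("results", showWarnings = FALSE)

ss <- {
  labels <- c("ASK1", "MKK4", "MKK3", "p38", "ATF2")
  routing <- matrix(0, 5, 5); routing[cbind(1:4, 2:5)] <- 0.6
  steady_state(cascade_spec(labels, c(0.20, 0.15, 0.15, 0.10, 0.10),
                            c(1.5, 1.3, 1.3, 1.1, 1.0), routing))
}

tau <- 2 * sum(ss$rho * ss$tau_o)     # stimulated: twice the resting budget
opt <- maximize_kld(unname(ss$rho), unname(ss$tau_o), tau)
pernode <- data.frame(
  node = ss$spec$labels,
  rho = unname(ss$rho),
  rho_t = opt$rho_t,
  fold = opt$rho_t / unname(ss$rho),
  rate_check = -(1 / unname(ss$tau_o)) * log(opt$rho_t / unname(ss$rho)))
cat("== Budget-constrained KLD extremum ==\n")
print(pernode, digits = 6)
cat("gamma (common across nodes): ", format(-opt$kld_rate, digits = 10),
    "\nconserved KLD rate -gamma:   ", format(opt$kld_rate, digits = 10),
    "\nD / tau:                     ",
    format(opt$divergence / opt$tau, digits = 10),
    "\nstationarity residual:       ",
    format(opt$stationarity_residual, digits = 3), "\n", sep = "")
write.csv(pernode, "results/kld_conservation.csv", row.names = FALSE)

cat("\n== Stirling identity: log multinomial state probability vs -aD ==\n")
set.seed(42)
stir <- do.call(rbind, lapply(c(10, 100, 1000, 10000), function(a) {
  f <- c(0.4, 0.3, 0.2, 0.1)
  counts <- round(a * f); counts[1] <- a - sum(counts[-1])
  r <- log_state_probability(counts, rho = c(0.2, 0.15, 0.1, 0.05),
                             a = a)
  data.frame(a = a, exact = r$exact, stirling = r$stirling,
             per_customer_gap = r$per_customer_gap)
}))
print(stir, digits = 4)
cat("The per-customer gap shrinks like log(a)/a: the divergence is the\n",
    "large-a exponent of the state probability.\n", sep = "")
write.csv(stir, "results/stirling_identity.csv", row.names = FALSE)

cat("\n== Thermodynamic mapping ==\n")
ds <- total_entropy_change(opt$rho_t, unname(ss$rho))
cat("Delta S = ", format(ds, digits = 12), " (k_B);  D = ",
    format(opt$divergence, digits = 12), ";  -gamma*tau = ",
    format(-opt$gamma * opt$tau, digits = 12), "\n", sep = "")
cat("All three coincide: the information gain is the thermodynamic\n",
    "entropy change of the signalling transition.\n", sep = "")
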