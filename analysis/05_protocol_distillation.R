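#!/usr/bin/env Rscript
# Stage 5 — distilling the per-state optimal policy into the triage protocol.
#
# Labels every (ED state, patient stratum) pair with the theoretically
# optimal routing decision, fits a depth-<=4 decision tree on a training
# split of states using only (ESI, complaint category, saturation flag), and
# scores its agreement with the optimal policy on held-out states.

library(vppflow)

lab <- read.csv("results/labeled_encounters.csv", stringsAsFactors = FALSE)
clean_lab <- lab
model <- fit_bed_need_model(clean_lab[!clean_lab$gold_test, ], seed = 2)
conf <- risk_confusion(lab$risk[lab$bed_need], lab$risk[!lab$bed_need])
calib <- calibrate_ed_states(lab, n_beds = 56)

dist <- distill_protocol(lab, model, calib, cost_spec(), conf, seed = 5)
out <- protocol_tree_render(dist$tree, path = "results/protocol.json")
writeLines(out$text, "results/protocol.txt")
jsonlite::write_json(list(heldout_agreement = dist$heldout_agreement,
                          training_agreement =
                            dist$tree$training_agreement),
                     "results/protocol_agreement.json", auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("training agreement: %.3f; held-out agreement: %.3f\n",
            dist$tree$training_agreement, dist$heldout_agreement))
cat("\ndistilled protocol:\n")
writeLines(out$text)

# the deployed protocol function on a few probes
probe <- data.frame(esi = c(4, 3, 3, 2, 2),
                    complaint = c("chest", "urinary", "chest", "chest",
                                  "chest"),
                    saturated = c(FALSE, FALSE, FALSE, FALSE, TRUE))
probe$decision <- protocol_decision(probe$esi, probe$complaint,
                                    probe$saturated)
print(probe)
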