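test_that("saturation rule: full beds plus a strict waiting-room excess", {
  expect_false(saturation_rule(0, 56, 56))
  expect_true(saturation_rule(1000, 56, 56))
  expect_false(saturation_rule(14, 56, 56))   # exactly at 0.25 * 56
  expect_true(saturation_rule(15, 56, 56))
  expect_false(saturation_rule(15, 55, 56))   # a free bed: not saturated
  expect_error(saturation_rule(-1, 10, 56), "non-negative")
  expect_equal(saturation_rule(c(0, 20), c(56, 56), 56), c(FALSE, TRUE))
})

calib <- local({
  enc <- generate_encounters(small_config(seed = 31, n = 3000))
  calibrate_ed_states(enc, n_beds = 56)
})

test_that("state grid size is the product of the configured axes", {
  g <- enumerate_ed_states(calib)
  expect_equal(nrow(g), 4 * 3 * 3)
  expect_true(any(g$saturated) && any(!g$saturated))
  g1 <- enumerate_ed_states(calib, demand_mult = 1, coverage = 0.8,
                            congestion = "quiet")
  expect_equal(nrow(g1), 1)
  expect_true(all(g$lambda_total > 0 & g$mu_main > 0))
  expect_error(calibrate_ed_states(generate_encounters(small_config(n = 0))),
               "empty")
})

test_that("per-state optimal labels respect the threshold and infeasibility", {
  strata <- data.frame(esi = c(5, 4, 3, 2), complaint = "other",
                       risk = c(0.1, 0.2, 0.7, 0.97), n = 1)
  conf <- beta_confusion(3, prevalence = 0.7)
  st <- enumerate_ed_states(calib, demand_mult = 1, coverage = 0.75,
                            congestion = c("quiet", "crowded"))
  ex <- optimal_labels_for_states(st, strata, cost_spec(), conf)
  expect_equal(nrow(ex), nrow(st) * nrow(strata))
  expect_true(all(ex$label[ex$risk <= ex$tau_star] == "vpp_eligible"))
  expect_true(all(ex$label[ex$risk > ex$tau_star] == "main_ed"))
  # an overloaded grid with no stable split labels everything main ED
  hopeless <- st[1, ]
  hopeless$lambda_total <- 100
  expect_message(
    ex2 <- optimal_labels_for_states(hopeless, strata, cost_spec(), conf),
    "stable")
  expect_true(all(ex2$label == "main_ed"))
  expect_equal(attr(ex2, "infeasible_states"), hopeless$state_id)
})

test_that("saturation expands eligibility relative to matched states", {
  lab <- small_labeled(seed = 31, n = 6000)
  m <- fit_bed_need_model(lab[!lab$gold_test, ], seed = 31)
  lab$risk <- predict_risk(m, lab)
  conf <- risk_confusion(lab$risk[lab$bed_need], lab$risk[!lab$bed_need])
  strata <- patient_strata(lab, m)
  states <- enumerate_ed_states(calib)
  ex <- optimal_labels_for_states(states, strata, cost_spec(), conf)
  ag <- aggregate(label ~ state_id,
                  data = transform(ex, label = label == "vpp_eligible"),
                  FUN = sum)
  states$n_eligible <- ag$label[match(states$state_id, ag$state_id)]
  # compare crowded (saturated) to the matched busy (unsaturated) state
  key <- function(d) paste(d$demand_mult, d$coverage)
  sat <- states[states$congestion == "crowded", ]
  busy <- states[states$congestion == "busy", ]
  matched <- busy$n_eligible[match(key(sat), key(busy))]
  expect_true(all(sat$n_eligible > matched))
})

test_that("distillation recovers a planted rule and is deterministic", {
  grid <- expand.grid(esi = 1:5,
                      complaint = c("chest", "skin", "other"),
                      saturated = c(FALSE, TRUE), rep = 1:4)
  grid$label <- factor(ifelse(grid$esi >= 4, "vpp_eligible", "main_ed"),
                       levels = c("main_ed", "vpp_eligible"))
  tr <- distill_decision_tree(grid, max_depth = 3)
  expect_equal(as.character(tr$fit$frame$var[1]), "esi")
  expect_equal(tr$training_agreement, 1)
  tr2 <- distill_decision_tree(grid, max_depth = 3)
  expect_identical(predict(tr, grid), predict(tr2, grid))
})

test_that("deeper protocols fit two-factor labels better than stumps", {
  grid <- expand.grid(esi = 1:5,
                      complaint = c("chest", "skin", "urinary", "other"),
                      saturated = c(FALSE, TRUE), rep = 1:3)
  grid$label <- factor(
    ifelse(grid$esi >= 4 | grid$saturated, "vpp_eligible", "main_ed"),
    levels = c("main_ed", "vpp_eligible"))
  a1 <- distill_decision_tree(grid, max_depth = 1)$training_agreement
  a3 <- distill_decision_tree(grid, max_depth = 3)$training_agreement
  expect_lt(a1, a3)
  expect_equal(a3, 1)
})

test_that("degenerate distillation inputs are handled", {
  grid <- data.frame(esi = 1:4, complaint = "other", saturated = FALSE,
                     label = factor("main_ed",
                                    levels = c("main_ed", "vpp_eligible")))
  expect_warning(tr <- distill_decision_tree(grid), "single-label")
  expect_equal(unique(as.character(predict(tr, grid))), "main_ed")
  # tied leaves resolve to the conservative main-ED routing
  tie <- data.frame(esi = c(3, 3), complaint = "other",
                    saturated = FALSE,
                    label = factor(c("main_ed", "vpp_eligible"),
                                   levels = c("main_ed", "vpp_eligible")))
  trt <- distill_decision_tree(tie)
  expect_equal(as.character(predict(trt, tie[1, ])), "main_ed")
})

test_that("agreement rate scores protocols against optimal labels", {
  grid <- expand.grid(esi = 1:5, complaint = c("chest", "skin"),
                      saturated = c(FALSE, TRUE))
  grid$label <- factor(ifelse(grid$esi >= 4, "vpp_eligible", "main_ed"),
                       levels = c("main_ed", "vpp_eligible"))
  tr <- distill_decision_tree(grid)
  expect_equal(agreement_rate(tr, grid), 1)
  flipped <- grid
  flipped$label <- factor(
    ifelse(grid$label == "main_ed", "vpp_eligible", "main_ed"),
    levels = c("main_ed", "vpp_eligible"))
  expect_equal(agreement_rate(tr, flipped), 0)
  expect_error(agreement_rate(tr, grid[0, ]), "no examples")
})

test_that("the published protocol matches its decision table exhaustively", {
  complaints <- c("abdominal", "chest", "respiratory", "neurological",
                  "musculoskeletal", "skin", "urinary", "eye", "other")
  tab <- expand.grid(esi = 1:5, complaint = complaints,
                     saturated = c(FALSE, TRUE), stringsAsFactors = FALSE)
  got <- protocol_decision(tab$esi, tab$complaint, tab$saturated)
  want <- ifelse(
    tab$saturated, "vpp_eligible",
    ifelse(tab$esi %in% 4:5, "vpp_eligible",
           ifelse(tab$esi == 3 &
                    tab$complaint %in% c("skin", "urinary", "eye"),
                  "vpp_eligible", "main_ed")))
  expect_equal(got, want)
  # monotone expansion: saturation never revokes eligibility
  unsat <- got[!tab$saturated]
  sat <- got[tab$saturated]
  expect_true(all(sat[unsat == "vpp_eligible"] == "vpp_eligible"))
  expect_error(protocol_decision(6, "skin", FALSE), "esi")
  expect_error(protocol_decision(0, "skin", FALSE), "esi")
})

test_that("protocol trees serialise to JSON and a text diagram", {
  grid <- expand.grid(esi = 1:5, complaint = c("chest", "skin"),
                      saturated = c(FALSE, TRUE))
  grid$label <- factor(ifelse(grid$esi >= 4 | grid$saturated,
                              "vpp_eligible", "main_ed"),
                       levels = c("main_ed", "vpp_eligible"))
  tr <- distill_decision_tree(grid)
  out <- protocol_tree_render(tr)
  parsed <- jsonlite::fromJSON(out$json, simplifyVector = FALSE)
  expect_true(!is.null(parsed$split))
  expect_gt(length(out$text), 2)
})
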