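enc44 <- generate_encounters(ed_generator_config(seed = 44))

test_that("log-LOS model recovers the planted multiplicative effect", {
  est <- fit_log_los_model(enc44)
  expect_true(est$ci95[1] <= log(0.9585) && log(0.9585) <= est$ci95[2])
  expect_lt(est$p_value, 0.01)
  # arithmetic identities of the estimate object
  expect_equal(est$pct_change, 100 * (exp(est$coef) - 1))
  expect_true(est$ci95[1] <= est$coef && est$coef <= est$ci95[2])
  expect_error(fit_log_los_model(enc44[enc44$period == "pre", ]), "post")
})

test_that("ESI coding and physician-effect variants agree on clean data", {
  cat_ <- fit_log_los_model(enc44, esi_coding = "categorical")
  con_ <- fit_log_los_model(enc44, esi_coding = "continuous")
  expect_lt(abs(cat_$coef - con_$coef), cat_$se)
  fe <- fit_log_los_model(enc44, physician_effects = "fixed")
  re <- fit_log_los_model(enc44, physician_effects = "random")
  expect_lt(abs(fe$coef - re$coef), fe$se)
})

test_that("adjustment moves a confounded contrast toward the truth", {
  # post-period case mix confounded toward low acuity: drop a third of the
  # truly bed-needing post rows
  set.seed(8)
  conf <- enc44[!(enc44$period == "post" & enc44$true_bed_need &
                    runif(nrow(enc44)) < 1 / 3), ]
  truth <- log(0.9585)
  unadj <- fit_log_los_model(conf, covariates = character(0))
  adj <- fit_log_los_model(conf, covariates = "patient")
  expect_lt(abs(adj$coef - truth), abs(unadj$coef - truth))
})

test_that("a null intervention stays null", {
  nul <- generate_encounters(ed_generator_config(seed = 45,
                                                 intervention_effect = 1))
  est <- fit_log_los_model(nul)
  expect_gt(est$p_value, 0.05)
})

test_that("return-rate models detect planted effects and stay null otherwise", {
  ret <- fit_return_models(enc44)
  expect_gt(ret$return_72h$p_value, 0.05)
  expect_gt(ret$return_72h_admit$p_value, 0.05)
  # plant a doubled post-period return rate
  set.seed(9)
  planted <- enc44
  post <- planted$period == "post"
  extra <- post & !planted$return_72h & runif(nrow(planted)) < 0.04
  planted$return_72h <- planted$return_72h | extra
  pr <- fit_return_models(planted)$return_72h
  expect_gt(pr$coef, 0)
  expect_lt(pr$p_value, 0.01)
  # zero-variance outcome errors by name
  broken <- enc44
  broken$return_72h_admit <- FALSE
  expect_error(fit_return_models(broken), "return_72h_admit")
})

test_that("with no covariates the return model reduces to a two-proportion contrast", {
  est <- fit_return_models(enc44, covariates = character(0))$return_72h
  d <- enc44[enc44$period != "edu", ]
  p1 <- mean(d$return_72h[d$period == "pre"])
  p2 <- mean(d$return_72h[d$period == "post"])
  expect_equal(est$coef, qlogis(p2) - qlogis(p1), tolerance = 1e-8)
})

test_that("the descriptive table reproduces the headline LOS arithmetic", {
  pre <- enc44[enc44$period == "pre", ]
  post <- enc44[enc44$period == "post", ]
  # pin the two arm means exactly at the published values
  pre$los <- pre$los - mean(pre$los) + 258.74
  post$los <- post$los - mean(post$los) + 247.99
  tab <- summarize_table1(pre, post)
  expect_equal(attr(tab, "los_diff_minutes"), 10.75, tolerance = 1e-9)
  expect_equal(round(attr(tab, "los_diff_pct"), 2), 4.15)
  expect_lt(tab$p_value[tab$variable == "ED length of stay (min)"], 0.001)
})

test_that("identical cohorts show zero differences and null tests", {
  pre <- enc44[enc44$period == "pre", ]
  tab <- summarize_table1(pre, pre)
  expect_equal(attr(tab, "los_diff_minutes"), 0)
  expect_true(all(tab$p_value[!is.na(tab$p_value)] > 0.05))
  one <- summarize_table1(pre[1, ], pre[2, ])
  expect_true(any(grepl("SD undefined", one$pre)))
  expect_error(summarize_table1(pre[, 1:3], pre), "schema")
})

test_that("test selection switches to Fisher exactly below the 10 cell threshold", {
  # smallest cell 9 -> Fisher
  expect_equal(select_small_cell_test(9, 100, 50, 100)$test, "Fisher")
  # smallest cell exactly 10 -> chi-square
  expect_equal(select_small_cell_test(10, 100, 50, 100)$test, "chi-square")
  # the threshold looks at every cell, including complements
  expect_equal(select_small_cell_test(95, 100, 50, 100)$test, "Fisher")
  expect_true(is.na(select_small_cell_test(0, 0, 5, 10)$test))
})

test_that("the reconstructed low-acuity stratum matches its exact test", {
  # pre 7/35 vs post 19/23 routed: two-sided p by hypergeometric enumeration
  res <- select_small_cell_test(7, 35, 19, 23)
  expect_equal(res$test, "Fisher")
  expect_equal(res$p_value, 3.015594938e-06, tolerance = 1e-9)
  expect_lt(res$p_value, 0.001)
  # symmetric identical proportions: p = 1
  sym <- select_small_cell_test(5, 8, 5, 8)
  expect_equal(sym$p_value, 1)
})

test_that("the routing table stratifies ESI 3 by complaint and runs per-stratum tests", {
  pre <- enc44[enc44$period == "pre", ]
  post <- enc44[enc44$period == "post", ]
  tab <- vpp_routing_table2(pre, post)
  expect_equal(tab$esi_stratum,
               c("1", "2", "3 - other", "3 - skin/urinary/eye", "4", "5"))
  expect_equal(tab$n_pre + tab$n_post,
               as.vector(table(factor(
                 ifelse(rbind(pre, post)$esi != 3,
                        as.character(rbind(pre, post)$esi),
                        ifelse(rbind(pre, post)$complaint %in%
                                 c("skin", "urinary", "eye"),
                               "3 - skin/urinary/eye", "3 - other")),
                 levels = tab$esi_stratum))))
  big <- tab$esi_stratum %in% c("3 - other", "4")
  expect_true(all(tab$test[big] == "chi-square"))
  expect_true(all(tab$p_value[big] < 0.001))
})

test_that("printed-percentage denominators are reconstructed exactly", {
  expect_equal(reconstruct_denominators(7, 20.00)$n, 35)
  expect_equal(reconstruct_denominators(19, 82.61)$n, 23)
  r <- reconstruct_denominators(139, 18.08)
  expect_equal(r$n, 769)
  expect_true(r$unique_within_10pct)
  expect_error(reconstruct_denominators(3, 99.97, search_max = 50), "no")
})

test_that("the robustness grid brackets the planted effect", {
  rob <- robustness_suite(enc44)
  expect_equal(nrow(rob), 5)
  expect_true(all(rob$pct_change > -6 & rob$pct_change < -3))
  rng <- attr(rob, "minutes_change_range")
  expect_true(rng[1] <= rng[2])
  one <- robustness_suite(enc44, specs = list(list(covariates = "patient")))
  expect_equal(nrow(one), 1)
})
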