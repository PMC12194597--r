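pop <- local({
  set.seed(1)
  data.frame(risk = c(runif(60, 0, 0.4), runif(40, 0.6, 1)),
             bed_need = rep(c(FALSE, TRUE), c(60, 40)),
             esi = rep(c(5, 4, 3, 2), 25))
})

test_that("no arrivals means no patients served", {
  sc <- sim_scenario("no_vpp", queue_params(0, 10, 10, 5), horizon = 10,
                     n_replications = 1)
  res <- simulate_scenario(sc)
  expect_equal(res$reps$n_arrivals, 0)
})

test_that("replications are reproducible per seed", {
  sc <- sim_scenario("vpp", queue_params(6, 16, 9, 6), horizon = 50,
                     n_replications = 1, seeds = 42, population = pop,
                     tau = 0.5)
  a <- simulate_scenario(sc)$patients
  b <- simulate_scenario(sc)$patients
  expect_identical(a, b)
})

test_that("patient flow is conserved in every replication", {
  for (design in c("no_vpp", "vpp", "fast_track", "physician_in_triage")) {
    sc <- sim_scenario(design, queue_params(6, 16, 9, 6), horizon = 100,
                       n_replications = 2, seeds = c(1, 2),
                       population = pop, tau = 0.5)
    res <- simulate_scenario(sc)
    expect_equal(res$reps$n_arrivals,
                 res$reps$n_departed_in_horizon +
                   res$reps$n_in_system_at_horizon,
                 info = design)
  }
})

test_that("simulated M/M/1 queue wait agrees with the closed form", {
  # lambda = 0.5/min, mu = 1/min: Wq = 1 minute
  val <- validate_against_analytic(
    data.frame(lambda = 0.5, mu = 1, theta = NA_real_),
    n_patients = 2e4, n_reps = 3, seed = 5, max_misses = 0)
  expect_true(attr(val, "pass"))
  expect_equal(val$sim_wait, 1, tolerance = 0.1)
})

test_that("Little's law holds on a long stable run", {
  sc <- sim_scenario("no_vpp", queue_params(5, 16, 8, 6), horizon = 4000,
                     warmup = 400, n_replications = 1, seeds = 3)
  p <- simulate_scenario(sc)$patients
  keep <- p$arrival >= 400 & p$arrival <= 3600
  t_grid <- seq(400, 3600, by = 0.25)
  in_sys <- findInterval(t_grid, sort(p$arrival)) -
    findInterval(t_grid, sort(p$departure))
  L <- mean(in_sys)
  lambda_eff <- sum(keep) / 3200
  W <- mean(p$wait[keep] + p$service[keep])
  expect_lt(abs(L - lambda_eff * W) / L, 0.05)
})

test_that("mean wait is non-decreasing in the arrival rate", {
  waits <- vapply(c(4, 6, 7.5), function(lam) {
    sc <- sim_scenario("no_vpp", queue_params(lam, 16, 9, 6),
                       horizon = 3000, n_replications = 3,
                       seeds = c(1, 2, 3))
    simulate_scenario(sc)$summary["mean_wait", "mean"]
  }, numeric(1))
  expect_true(all(diff(waits) > 0))
})

test_that("unstable scenarios run to completion but are flagged", {
  sc <- sim_scenario("no_vpp", queue_params(12, 16, 9, 6), horizon = 500,
                     n_replications = 1, seeds = 1)
  res <- simulate_scenario(sc)
  expect_true(res$reps$growing_queue)
})

test_that("type-I misroutes re-queue at the main ED after vertical assessment", {
  sc <- sim_scenario("vpp", queue_params(6, 16, 9, 6), horizon = 200,
                     n_replications = 1, seeds = 9, population = pop,
                     tau = 0.9)
  p <- simulate_scenario(sc)$patients
  rq <- p[p$requeued, ]
  expect_gt(nrow(rq), 0)
  expect_true(all(rq$stream == "vpp"))
  # a re-queued patient accrues both services, so spends longer than the
  # vertical assessment alone
  expect_true(all(rq$departure - rq$arrival >= rq$wait + rq$service - 1e-9))
})

test_that("analytic validation rejects a wrong formula and empty grids", {
  expect_error(validate_against_analytic(NULL), "empty")
  grid <- data.frame(lambda = 0.6, mu = 0.8, theta = 0.5)
  val <- validate_against_analytic(grid, n_patients = 2e4, n_reps = 3,
                                   seed = 17)
  expect_true(val$covered)
  # dropping the 1/theta residual-vacation term misses the interval
  wrong <- val$analytic_wait - 1 / grid$theta
  expect_false(wrong >= val$ci_lo && wrong <= val$ci_hi)
})

test_that("design comparison is seed-stable and flags capacity mismatch", {
  base <- queue_params(6, 6, 10, 6)
  scA <- sim_scenario("vpp", base, horizon = 300, n_replications = 2,
                      seeds = c(1, 2), population = pop, tau = 0.5)
  scB <- sim_scenario("fast_track", base, horizon = 300,
                      n_replications = 2, seeds = c(1, 2), population = pop)
  tab <- compare_flow_designs(list(scA, scB))
  expect_equal(nrow(tab), 2)
  expect_true(all(diff(tab$mean_time_in_system) >= 0))
  # identical scenario under two runs: identical summaries
  tab2 <- compare_flow_designs(list(scA, scA))
  expect_equal(tab2$mean_wait[1], tab2$mean_wait[2])
  uneven <- sim_scenario("no_vpp", queue_params(6, 6, 12, 6), horizon = 300,
                         n_replications = 2, seeds = c(1, 2))
  expect_warning(compare_flow_designs(list(scA, uneven)), "capacity")
})

test_that("an idle fast track wastes capacity when low-acuity arrivals vanish", {
  high_acuity <- data.frame(risk = runif(50, 0.3, 1),
                            bed_need = TRUE, esi = rep(1:3, length.out = 50))
  prm <- queue_params(6, 4, 6, 6)
  ft <- sim_scenario("fast_track", prm, horizon = 500, n_replications = 3,
                     seeds = 1:3, population = high_acuity)
  vp <- sim_scenario("vpp", prm, horizon = 500, n_replications = 3,
                     seeds = 1:3, population = high_acuity, tau = 0.45)
  rft <- simulate_scenario(ft)
  rvp <- simulate_scenario(vp)
  expect_equal(sum(rft$patients$stream == "fast_track"), 0)
  expect_gte(rft$summary["mean_time_in_system", "mean"],
             rvp$summary["mean_time_in_system", "mean"])
})
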