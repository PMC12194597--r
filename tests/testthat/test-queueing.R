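test_that("M/M/1 closed forms match the textbook identities", {
  m <- mm1_metrics(0.5, 1)
  expect_equal(m$mean_wait_in_queue, 1)
  expect_equal(m$utilization, 0.5)
  expect_equal(m$mean_number_in_system, 1)
  z <- mm1_metrics(0, 1)
  expect_equal(unlist(z), c(utilization = 0, mean_wait_in_queue = 0,
                            mean_number_in_system = 0))
  expect_error(mm1_metrics(1, 1), "unstable")
  expect_error(mm1_metrics(2, 1, stream = "main"), "main")
  expect_error(mm1_metrics(0.5, 0), "positive")
})

test_that("vacation queue adds the mean residual vacation and collapses as theta grows", {
  v <- mm1_vacation_metrics(0.5, 1, 2)
  expect_equal(v$mean_wait_in_queue, 1.5)
  big <- mm1_vacation_metrics(0.5, 1, 1e9)
  base <- mm1_metrics(0.5, 1)
  expect_lt(abs(big$mean_wait_in_queue - base$mean_wait_in_queue), 1e-6)
  expect_error(mm1_vacation_metrics(0.5, 1, 0), "theta")
  # wait strictly decreasing in theta on a grid
  thetas <- c(0.25, 0.5, 1, 2, 4, 8, 16)
  w <- vapply(thetas, function(t) {
    mm1_vacation_metrics(0.7, 1, t)$mean_wait_in_queue
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("routing cost handles degenerate splits and responds to penalties", {
  conf <- beta_confusion(1)
  params <- queue_params(5, 14, 9, 4)
  expect_error(routing_cost(1.2, params, cost_spec(), conf), "tau")
  # tau = 0: nobody vertical; cost = main wait + c2 * P(no-bed-need)
  c0 <- routing_cost(0, params, cost_spec(c_type1 = 30, c_type2 = 15), conf)
  manual <- mm1_metrics(5, 9)$mean_wait_in_queue * 60 +
    15 * (1 - conf$prevalence_bed)
  expect_equal(c0, manual)
  # tau = 1 with zero bed-need prevalence: the vertical stream's wait only
  conf0 <- beta_confusion(2, prevalence = 0)
  c1 <- routing_cost(1, params, cost_spec(), conf0)
  expect_equal(c1, mm1_vacation_metrics(5, 14, 4)$mean_wait_in_queue * 60)
  # unstable split flagged as infinite
  tight <- queue_params(12, 3, 9, 4)
  expect_true(is.infinite(routing_cost(1, tight, cost_spec(), conf)))
  # cost non-decreasing in each penalty at fixed tau
  for (tau in c(0.2, 0.5, 0.8)) {
    base <- routing_cost(tau, params, cost_spec(10, 10), conf)
    expect_gte(routing_cost(tau, params, cost_spec(40, 10), conf), base)
    expect_gte(routing_cost(tau, params, cost_spec(10, 40), conf), base)
  }
})

test_that("optimal threshold matches an exhaustive fine-grid oracle", {
  set.seed(99)
  taus <- seq(0, 1, by = 1e-4)
  for (i in 1:20) {
    conf <- beta_confusion(100 + i, n_bed = 250, n_nobed = 180,
                           prevalence = runif(1, 0.3, 0.8))
    params <- queue_params(runif(1, 3, 9), runif(1, 8, 18),
                           runif(1, 6, 14), runif(1, 2, 10))
    cost <- cost_spec(runif(1, 0, 60), runif(1, 0, 40))
    costs <- vapply(taus, routing_cost, numeric(1), params = params,
                    cost = cost, confusion = conf)
    sol <- optimal_threshold(params, cost, conf)
    brute <- taus[which.min(costs)]
    # within one grid step of the oracle, unless the optimizer found a
    # plateau narrower than the oracle grid (then it must be strictly
    # better)
    expect_true(abs(sol$tau - brute) <= 1e-3 ||
                  sol$expected_cost < min(costs) - 1e-12)
    expect_lte(sol$expected_cost, min(costs) + 1e-9)
  }
})

test_that("degenerate prevalence and infeasible systems resolve as specified", {
  # all patients need beds and misrouting is expensive: route nobody vertical
  conf <- beta_confusion(5, prevalence = 1)
  sol <- optimal_threshold(queue_params(2, 6, 8, 4),
                           cost_spec(c_type1 = 60, c_type2 = 0), conf)
  expect_equal(sol$tau, 0)
  # no stable threshold at all
  expect_error(optimal_threshold(queue_params(30, 5, 5, 4), cost_spec(),
                                 beta_confusion(6)),
               "stable")
})

test_that("the optimal threshold shifts with ED conditions and penalties", {
  conf <- beta_confusion(7, n_bed = 500, n_nobed = 350, prevalence = 0.7)
  cost <- cost_spec()
  lo <- optimal_threshold(queue_params(4, 16, 7, 6), cost, conf)
  hi <- optimal_threshold(queue_params(9, 16, 7.5, 6), cost, conf)
  expect_false(isTRUE(all.equal(lo$tau, hi$tau)))
  # raising the type-I penalty never raises the threshold; raising the
  # type-II penalty never lowers it (verified against the same grid oracle)
  params <- queue_params(5, 14, 9, 4)
  t1 <- vapply(c(5, 20, 60), function(c1) {
    optimal_threshold(params, cost_spec(c_type1 = c1, c_type2 = 15),
                      conf)$tau
  }, numeric(1))
  expect_true(all(diff(t1) <= 1e-9))
  t2 <- vapply(c(5, 20, 60), function(c2) {
    optimal_threshold(params, cost_spec(c_type1 = 30, c_type2 = c2),
                      conf)$tau
  }, numeric(1))
  expect_true(all(diff(t2) >= -1e-9))
})
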