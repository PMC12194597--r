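# Single-stream FIFO queue simulators. Times are in the unit implied by the
# rates passed in (hours throughout the package API).

# Lindley recursion, vectorised: waiting times of n M/M/1 customers
sim_mm1_waits <- function(n, lambda, mu) {
  ia <- stats::rexp(n, lambda)
  s <- stats::rexp(n, mu)
  if (n == 1) return(list(wait = 0, arrival = ia, service = s))
  u <- s[-n] - ia[-1]
  cs <- cumsum(u)
  wait <- c(0, cs - pmin(cummin(cs), 0))
  list(wait = wait, arrival = cumsum(ia), service = s)
}

# Per-customer recursion for the M/M/1 queue with multiple exponential
# vacations. When a service completion leaves the queue empty the server
# takes successive Exp(theta) vacations; because vacation completions then
# form a Poisson process, the first completion after the next arrival sits an
# Exp(theta) residual beyond it, which is drawn directly.
sim_mm1_vacation_waits <- function(n, lambda, mu, theta) {
  arr <- cumsum(stats::rexp(n, lambda))
  s <- stats::rexp(n, mu)
  resid <- stats::rexp(n, theta)
  wait <- numeric(n)
  d_prev <- 0
  for (k in seq_len(n)) {
    begin <- if (arr[k] <= d_prev) d_prev else arr[k] + resid[k]
    wait[k] <- begin - arr[k]
    d_prev <- begin + s[k]
  }
  list(wait = wait, arrival = arr, service = s)
}

# FIFO single-server queue for given arrival instants; returns waits and
# departures. Used for the main-ED stream, including merged re-queues.
fifo_waits <- function(arrival, mu, vacation_theta = NULL) {
  n <- length(arrival)
  if (n == 0) return(list(wait = numeric(0), departure = numeric(0),
                          service = numeric(0)))
  ord <- order(arrival)
  arr <- arrival[ord]
  s <- stats::rexp(n, mu)
  wait <- numeric(n)
  d_prev <- 0
  if (is.null(vacation_theta)) {
    for (k in seq_len(n)) {
      begin <- max(arr[k], d_prev)
      wait[k] <- begin - arr[k]
      d_prev <- begin + s[k]
    }
  } else {
    resid <- stats::rexp(n, vacation_theta)
    for (k in seq_len(n)) {
      begin <- if (arr[k] <= d_prev) d_prev else arr[k] + resid[k]
      wait[k] <- begin - arr[k]
      d_prev <- begin + s[k]
    }
  }
  dep <- arr + wait + s
  # return in the original (input) order
  inv <- order(ord)
  list(wait = wait[inv], departure = dep[inv], service = s[inv])
}

#' Define a simulation scenario
#'
#' @param design One of `"vpp"`, `"no_vpp"`, `"fast_track"`,
#'   `"physician_in_triage"`.
#' @param params A [queue_params()]; `mu_main` is the main-ED rate, `mu_vpp`
#'   the dedicated stream's rate (VPP, fast-track window, or triage stage
#'   depending on the design), `theta` the VPP vacation rate.
#' @param horizon Horizon in hours; arrivals are generated over it.
#' @param warmup Warmup in hours excluded from summaries (< horizon).
#' @param n_replications Number of independent replications (>= 1).
#' @param seeds Integer seeds, one per replication.
#' @param population Data frame with one row per potential patient profile:
#'   `risk` (score in [0,1]), `bed_need` (logical), `esi`. Sampled with
#'   replacement for each arrival. Required for vpp/fast_track routing.
#' @param tau Routing threshold for the vpp design (risk <= tau goes
#'   vertical).
#' @param rework_prob Probability a physician-in-triage patient needs a
#'   repeat main-ED workup.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(design = c("vpp", "no_vpp", "fast_track",
                                    "physician_in_triage"),
                         params, horizon, warmup = 0.2 * horizon,
                         n_replications = 1,
                         seeds = seq_len(n_replications),
                         population = NULL, tau = 0.5, rework_prob = 0.25) {
  design <- match.arg(design)
  stopifnot(inherits(params, "queue_params"), horizon > 0,
            warmup < horizon, n_replications >= 1,
            length(seeds) == n_replications)
  if (design %in% c("vpp", "fast_track") && is.null(population)) {
    stop("designs with routing need a population profile table")
  }
  structure(list(design = design, params = params, horizon = horizon,
                 warmup = warmup, n_replications = n_replications,
                 seeds = seeds, population = population, tau = tau,
                 rework_prob = rework_prob),
            class = "sim_scenario")
}

simulate_one_rep <- function(scenario, seed) {
  set.seed(seed)
  p <- scenario$params
  horizon <- scenario$horizon
  n_arr <- stats::rpois(1, p$lambda_total * horizon)
  if (n_arr == 0) {
    return(data.frame(arrival = numeric(0), stream = character(0),
                      wait = numeric(0), service = numeric(0),
                      departure = numeric(0), requeued = logical(0)))
  }
  arrival <- sort(stats::runif(n_arr, 0, horizon))
  pop <- scenario$population
  prof <- if (!is.null(pop)) pop[sample.int(nrow(pop), n_arr,
                                            replace = TRUE), , drop = FALSE]
  des <- scenario$design

  if (des == "no_vpp") {
    q <- fifo_waits(arrival, p$mu_main)
    return(data.frame(arrival = arrival, stream = "main", wait = q$wait,
                      service = q$service, departure = q$departure,
                      requeued = FALSE))
  }

  if (des == "vpp") {
    to_vpp <- prof$risk <= scenario$tau
    v <- fifo_waits(arrival[to_vpp], p$mu_vpp, vacation_theta = p$theta)
    # type-I misroutes: truly bed-needing patients re-queue at the main ED
    # after their vertical assessment
    requeue <- to_vpp & prof$bed_need
    requeue_at <- v$departure[prof$bed_need[to_vpp]]
    main_arr <- c(arrival[!to_vpp], requeue_at)
    m <- fifo_waits(main_arr, p$mu_main)
    out <- data.frame(arrival = arrival, stream = ifelse(to_vpp, "vpp",
                                                         "main"),
                      wait = NA_real_, service = NA_real_,
                      departure = NA_real_, requeued = requeue)
    out$wait[to_vpp] <- v$wait
    out$service[to_vpp] <- v$service
    out$departure[to_vpp] <- v$departure
    n_main_direct <- sum(!to_vpp)
    out$wait[!to_vpp] <- m$wait[seq_len(n_main_direct)]
    out$service[!to_vpp] <- m$service[seq_len(n_main_direct)]
    out$departure[!to_vpp] <- m$departure[seq_len(n_main_direct)]
    if (any(requeue)) {
      ridx <- which(requeue)
      mr <- seq_len(sum(requeue)) + n_main_direct
      out$wait[ridx] <- out$wait[ridx] + m$wait[mr]
      out$service[ridx] <- out$service[ridx] + m$service[mr]
      out$departure[ridx] <- m$departure[mr]
    }
    return(out)
  }

  if (des == "fast_track") {
    to_ft <- prof$esi >= 4
    f <- fifo_waits(arrival[to_ft], p$mu_vpp)
    m <- fifo_waits(arrival[!to_ft], p$mu_main)
    out <- data.frame(arrival = arrival,
                      stream = ifelse(to_ft, "fast_track", "main"),
                      wait = NA_real_, service = NA_real_,
                      departure = NA_real_, requeued = FALSE)
    out$wait[to_ft] <- f$wait; out$service[to_ft] <- f$service
    out$departure[to_ft] <- f$departure
    out$wait[!to_ft] <- m$wait; out$service[!to_ft] <- m$service
    out$departure[!to_ft] <- m$departure
    return(out)
  }

  # physician_in_triage: an upfront triage-physician stage for every arrival
  # (rate mu_vpp), then the main queue; a rework fraction repeats the main
  # service
  t1 <- fifo_waits(arrival, p$mu_vpp)
  m <- fifo_waits(t1$departure, p$mu_main)
  rework <- stats::runif(n_arr) < scenario$rework_prob
  extra <- ifelse(rework, stats::rexp(n_arr, p$mu_main), 0)
  data.frame(arrival = arrival, stream = "triage_then_main",
             wait = t1$wait + m$wait,
             service = t1$service + m$service + extra,
             departure = m$departure + extra,
             requeued = rework)
}

#' Run a discrete-event simulation scenario
#'
#' Simulates the configured patient-flow design replication by replication
#' (exponential inter-arrival, service and vacation draws), excluding
#' arrivals during the warmup from the summaries. Unstable scenarios run to
#' completion but are flagged via the `growing_queue` column (wait trend over
#' the run).
#'
#' @param scenario A [sim_scenario()].
#' @return Object of class `sim_result`: `patients` (per-patient records of
#'   the last replication), `reps` (per-replication summaries), `summary`
#'   (across-replication means with 95% CI).
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  reps <- vector("list", scenario$n_replications)
  pat <- NULL
  for (r in seq_len(scenario$n_replications)) {
    pat <- simulate_one_rep(scenario, scenario$seeds[r])
    keep <- pat$arrival >= scenario$warmup
    kept <- pat[keep, , drop = FALSE]
    half <- floor(nrow(kept) / 2)
    reps[[r]] <- data.frame(
      rep = r,
      n_arrivals = nrow(pat),
      n_departed_in_horizon = sum(pat$departure <= scenario$horizon),
      n_in_system_at_horizon = sum(pat$departure > scenario$horizon),
      mean_wait = mean(kept$wait),
      mean_time_in_system = mean(kept$wait + kept$service),
      growing_queue = half > 1 &&
        mean(kept$wait[seq_len(half)]) * 1.5 <
          mean(kept$wait[seq(half + 1, nrow(kept))])
    )
  }
  reps <- do.call(rbind, reps)
  ci <- function(x) {
    m <- mean(x)
    if (length(x) < 2) return(c(mean = m, lo = m, hi = m))
    half <- stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
    c(mean = m, lo = m - half, hi = m + half)
  }
  structure(list(
    patients = pat, reps = reps,
    summary = rbind(mean_wait = ci(reps$mean_wait),
                    mean_time_in_system = ci(reps$mean_time_in_system))
  ), class = "sim_result")
}

#' Validate the closed-form queue formulas against simulation
#'
#' For each grid point, simulates `n_reps` independent replications of
#' `n_patients` customers of the single queue (plain M/M/1 when `theta` is
#' `NA`, M/M/1 with exponential vacations otherwise), discards the first
#' `warmup_frac` of customers, and checks whether the analytic mean queueing
#' delay falls in the across-replication 95% t-interval.
#'
#' @param grid Data frame with columns `lambda`, `mu`, `theta` (NA = no
#'   vacations); every point must be stable.
#' @param n_patients Customers per replication.
#' @param n_reps Replications per point.
#' @param seed Base seed.
#' @param warmup_frac Initial fraction of customers discarded.
#' @param max_misses Maximum uncovered points for an overall pass.
#' @return Data frame report with analytic and simulated waits, CI bounds and
#'   `covered`; attribute `pass` (logical).
#' @export
validate_against_analytic <- function(grid, n_patients = 1e5, n_reps = 3,
                                      seed = 1L, warmup_frac = 0.2,
                                      max_misses = 1) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty parameter grid")
  out <- grid
  out$analytic_wait <- NA_real_
  out$sim_wait <- NA_real_
  out$ci_lo <- NA_real_
  out$ci_hi <- NA_real_
  drop <- seq_len(ceiling(warmup_frac * n_patients))
  for (i in seq_len(nrow(grid))) {
    lam <- grid$lambda[i]; mu <- grid$mu[i]; th <- grid$theta[i]
    out$analytic_wait[i] <- if (is.na(th)) {
      mm1_metrics(lam, mu)$mean_wait_in_queue
    } else {
      mm1_vacation_metrics(lam, mu, th)$mean_wait_in_queue
    }
    means <- vapply(seq_len(n_reps), function(r) {
      set.seed(seed + 1000L * i + r)
      w <- if (is.na(th)) {
        sim_mm1_waits(n_patients, lam, mu)$wait
      } else {
        sim_mm1_vacation_waits(n_patients, lam, mu, th)$wait
      }
      mean(w[-drop])
    }, numeric(1))
    out$sim_wait[i] <- mean(means)
    half <- stats::qt(0.975, n_reps - 1) * stats::sd(means) / sqrt(n_reps)
    out$ci_lo[i] <- out$sim_wait[i] - half
    out$ci_hi[i] <- out$sim_wait[i] + half
  }
  out$covered <- out$analytic_wait >= out$ci_lo & out$analytic_wait <= out$ci_hi
  attr(out, "pass") <- sum(!out$covered) <= max_misses
  out
}

#' Compare patient-flow designs under a shared arrival process
#'
#' Runs each scenario and returns a table ranked by mean time in system. The
#' comparison is meant to be resource-neutral: scenarios whose total service
#' capacity (`mu_main + mu_vpp`) differs from the first scenario's get a
#' warning recorded in the report attribute `capacity_warning`.
#'
#' @param scenarios List of [sim_scenario()] objects.
#' @return Data frame, one row per scenario, ranked by mean time in system.
#' @export
compare_flow_designs <- function(scenarios) {
  stopifnot(length(scenarios) >= 1)
  cap <- vapply(scenarios, function(s) {
    p <- s$params
    if (s$design == "no_vpp") p$mu_main else p$mu_main + p$mu_vpp
  }, numeric(1))
  warn <- NULL
  if (length(unique(round(cap, 8))) > 1) {
    warn <- paste("scenarios differ in total service capacity:",
                  paste(round(cap, 3), collapse = ", "))
    warning(warn)
  }
  rows <- lapply(seq_along(scenarios), function(i) {
    s <- scenarios[[i]]
    res <- simulate_scenario(s)
    data.frame(design = s$design,
               mean_wait = res$summary["mean_wait", "mean"],
               wait_lo = res$summary["mean_wait", "lo"],
               wait_hi = res$summary["mean_wait", "hi"],
               mean_time_in_system =
                 res$summary["mean_time_in_system", "mean"],
               tis_lo = res$summary["mean_time_in_system", "lo"],
               tis_hi = res$summary["mean_time_in_system", "hi"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_time_in_system), ]
  rownames(out) <- NULL
  attr(out, "capacity_warning") <- warn
  out
}
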