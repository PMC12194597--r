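#' Closed-form performance measures for an M/M/1 queue
#'
#' Standard steady-state identities for a single-server Markovian queue with
#' Poisson arrivals at rate `lambda` and exponential service at rate `mu`
#' (both in the same time unit, per hour throughout this package).
#'
#' @param lambda Arrival rate (>= 0).
#' @param mu Service rate (> 0).
#' @param stream Label used in error messages when the stream is unstable.
#' @return A list with `utilization` (rho = lambda/mu), `mean_wait_in_queue`
#'   (Wq = lambda / (mu * (mu - lambda))) and `mean_number_in_system`
#'   (L = lambda / (mu - lambda)), all in the units implied by the rates.
#' @examples
#' mm1_metrics(0.5, 1)  # Wq = 1
#' @export
mm1_metrics <- function(lambda, mu, stream = "queue") {
  stopifnot(is.numeric(lambda), is.numeric(mu), length(lambda) == 1L,
            length(mu) == 1L)
  if (lambda < 0) stop("arrival rate must be non-negative")
  if (mu <= 0) stop("service rate must be strictly positive")
  if (lambda >= mu) {
    stop(sprintf("stream '%s' is unstable: lambda = %g >= mu = %g",
                 stream, lambda, mu))
  }
  if (lambda == 0) {
    return(list(utilization = 0, mean_wait_in_queue = 0,
                mean_number_in_system = 0))
  }
  list(
    utilization           = lambda / mu,
    mean_wait_in_queue    = lambda / (mu * (mu - lambda)),
    mean_number_in_system = lambda / (mu - lambda)
  )
}

#' Closed-form measures for an M/M/1 queue with multiple exponential vacations
#'
#' Models a server that, whenever it empties the queue, leaves on successive
#' vacations of independent Exp(`theta`) length until it returns to find work
#' waiting (the "multiple vacations" discipline). Here the vacations stand for
#' the intermittent availability of the physician who staffs the vertical
#' pathway between main-ED duties. By the classical decomposition result the
#' stationary queueing delay is the ordinary M/M/1 delay plus the mean
#' residual vacation, which for exponential vacations is
#' E[V^2] / (2 E[V]) = 1/theta:
#'   Wq = lambda / (mu * (mu - lambda)) + 1 / theta.
#'
#' @inheritParams mm1_metrics
#' @param theta Vacation rate (> 0); vacation durations are Exp(theta).
#' @return List with `utilization`, `mean_wait_in_queue`,
#'   `mean_number_in_system` (via Little's law with W = Wq + 1/mu).
#' @examples
#' mm1_vacation_metrics(0.5, 1, 2)  # Wq = 1 + 0.5
#' @export
mm1_vacation_metrics <- function(lambda, mu, theta, stream = "vacation queue") {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("vacation rate theta must be strictly positive")
  }
  base <- mm1_metrics(lambda, mu, stream = stream)
  wq <- base$mean_wait_in_queue + 1 / theta
  list(
    utilization           = base$utilization,
    mean_wait_in_queue    = wq,
    mean_number_in_system = lambda * (wq + 1 / mu)
  )
}

#' Queue parameters for the two-stream routing model
#'
#' Bundles the rates of the routing system: total Poisson arrival rate, the
#' service rate of the vertical pathway (a single server with exponential
#' vacations), the service rate of the main ED (a single aggregated server),
#' and the vacation rate. A risk-score distribution over arriving patients is
#' carried separately as a `risk_confusion` object.
#'
#' @param lambda_total Total arrival rate, patients/hour.
#' @param mu_vpp VPP service rate, patients/hour.
#' @param mu_main Main-ED service rate, patients/hour.
#' @param theta Vacation rate of the VPP server, 1/hour.
#' @return An object of class `queue_params`.
#' @export
queue_params <- function(lambda_total, mu_vpp, mu_main, theta) {
  stopifnot(lambda_total >= 0, mu_vpp > 0, mu_main > 0, theta > 0)
  structure(list(lambda_total = lambda_total, mu_vpp = mu_vpp,
                 mu_main = mu_main, theta = theta),
            class = "queue_params")
}

#' Misclassification cost specification
#'
#' Time penalties (minutes per misrouted patient) attached to the two routing
#' errors: type I sends a patient who ultimately needs a bed to the vertical
#' pathway (wasted vertical assessment plus a re-queue at the main ED);
#' type II keeps a vertically dischargeable patient in the main-ED bed stream
#' (opportunity cost of a bed slot). Stream waits are weighted by
#' `wait_weight_vpp` / `wait_weight_main` (dimensionless, default 1).
#'
#' @param c_type1 Minutes penalty per type-I misroute (>= 0).
#' @param c_type2 Minutes penalty per type-II misroute (>= 0).
#' @param wait_weight_vpp,wait_weight_main Weights on the stream mean waits.
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(c_type1 = 30, c_type2 = 15,
                      wait_weight_vpp = 1, wait_weight_main = 1) {
  stopifnot(c_type1 >= 0, c_type2 >= 0,
            wait_weight_vpp >= 0, wait_weight_main >= 0)
  structure(list(c_type1 = c_type1, c_type2 = c_type2,
                 wait_weight_vpp = wait_weight_vpp,
                 wait_weight_main = wait_weight_main),
            class = "cost_spec")
}

#' Operating characteristic of the risk score
#'
#' Captures what the routing rule "send to VPP iff risk score <= tau" does to
#' each class: `F_bed(tau)` is the fraction of bed-needing patients routed to
#' the VPP (the type-I rate at tau) and `F_nobed(tau)` the fraction of
#' vertically dischargeable patients routed there (1 - F_nobed is the type-II
#' rate). Built from empirical score vectors by class.
#'
#' @param scores_bed Risk scores of patients who truly require a bed.
#' @param scores_nobed Risk scores of patients who do not.
#' @param prevalence_bed P(requires bed) among arrivals; defaults to the
#'   empirical share implied by the two vectors.
#' @return An object of class `risk_confusion` with elements `F_bed`,
#'   `F_nobed` (vectorised step functions of tau) and `prevalence_bed`.
#' @export
risk_confusion <- function(scores_bed, scores_nobed,
                           prevalence_bed = length(scores_bed) /
                             (length(scores_bed) + length(scores_nobed))) {
  stopifnot(length(scores_bed) > 0, length(scores_nobed) > 0,
            all(scores_bed >= 0 & scores_bed <= 1),
            all(scores_nobed >= 0 & scores_nobed <= 1),
            prevalence_bed >= 0, prevalence_bed <= 1)
  sb <- sort(scores_bed)
  sn <- sort(scores_nobed)
  structure(list(
    F_bed   = function(tau) findInterval(tau, sb) / length(sb),
    F_nobed = function(tau) findInterval(tau, sn) / length(sn),
    prevalence_bed = prevalence_bed,
    breaks = sort(unique(c(sb, sn)))
  ), class = "risk_confusion")
}

#' Expected per-patient cost of a routing threshold
#'
#' Routes arrivals with risk score <= `tau` to the vertical pathway and the
#' rest to the main ED, then scores the split as
#' share_vpp * W_vpp + share_main * W_main
#' + c_type1 * P(type I) + c_type2 * P(type II),
#' with W_vpp from the vacation queue and W_main from the plain M/M/1 (waits
#' converted to minutes). P(type I) = prevalence * F_bed(tau);
#' P(type II) = (1 - prevalence) * (1 - F_nobed(tau)). If either stream is
#' unstable at the induced split the cost is `Inf` with attribute
#' `unstable` naming the stream.
#'
#' @param tau Risk threshold in [0, 1].
#' @param params A `queue_params`.
#' @param cost A `cost_spec`.
#' @param confusion A `risk_confusion`.
#' @return Expected cost in minutes per patient (possibly `Inf`).
#' @export
routing_cost <- function(tau, params, cost, confusion) {
  stopifnot(inherits(params, "queue_params"), inherits(cost, "cost_spec"),
            inherits(confusion, "risk_confusion"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau > 1) {
    stop("tau must be a single number in [0, 1]")
  }
  p <- confusion$prevalence_bed
  f_bed <- confusion$F_bed(tau)
  f_nobed <- confusion$F_nobed(tau)
  share_vpp <- p * f_bed + (1 - p) * f_nobed
  share_main <- 1 - share_vpp
  lam_v <- params$lambda_total * share_vpp
  lam_m <- params$lambda_total * share_main
  if (lam_v >= params$mu_vpp) {
    return(structure(Inf, unstable = "vpp"))
  }
  if (lam_m >= params$mu_main) {
    return(structure(Inf, unstable = "main"))
  }
  w_v <- if (share_vpp > 0) {
    mm1_vacation_metrics(lam_v, params$mu_vpp, params$theta)$mean_wait_in_queue
  } else 0
  w_m <- if (share_main > 0) {
    mm1_metrics(lam_m, params$mu_main)$mean_wait_in_queue
  } else 0
  # rates are per hour; costs are minutes, so waits convert via * 60
  cost$wait_weight_vpp * share_vpp * w_v * 60 +
    cost$wait_weight_main * share_main * w_m * 60 +
    cost$c_type1 * p * f_bed +
    cost$c_type2 * (1 - p) * (1 - f_nobed)
}

#' Optimal routing threshold on the risk score
#'
#' Minimises [routing_cost()] over tau in [0, 1]. The cost is a step function
#' of tau — it changes only where tau crosses an observed score value — so
#' the dense grid (step `grid_step`, default 0.001) is refined by evaluating
#' every empirical score breakpoint of the confusion object, which makes the
#' search exact over continuous tau. Ties are broken toward the smaller tau,
#' i.e. toward routing fewer patients to the vertical pathway.
#'
#' @inheritParams routing_cost
#' @param grid_step Grid resolution (<= 0.001 recommended).
#' @return An object of class `threshold_solution`: `tau`, `expected_cost`
#'   (minutes/patient), `share_vpp`, `utilization_vpp`, `utilization_main`,
#'   `stable` (logical).
#' @export
optimal_threshold <- function(params, cost, confusion, grid_step = 0.001) {
  stopifnot(grid_step > 0, grid_step <= 0.01)
  taus <- sort(unique(c(seq(0, 1, by = grid_step), confusion$breaks)))
  costs <- vapply(taus, routing_cost, numeric(1),
                  params = params, cost = cost, confusion = confusion)
  if (all(!is.finite(costs))) {
    stop("no routing threshold yields a stable two-stream system")
  }
  best <- which(costs == min(costs))[1L]  # ties -> smaller tau
  tau_star <- taus[best]
  cst <- routing_cost(tau_star, params, cost, confusion)
  p <- confusion$prevalence_bed
  share_vpp <- p * confusion$F_bed(tau_star) +
    (1 - p) * confusion$F_nobed(tau_star)
  structure(list(
    tau = tau_star,
    expected_cost = as.numeric(cst),
    share_vpp = share_vpp,
    utilization_vpp = params$lambda_total * share_vpp / params$mu_vpp,
    utilization_main = params$lambda_total * (1 - share_vpp) / params$mu_main,
    stable = is.finite(cst)
  ), class = "threshold_solution")
}
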