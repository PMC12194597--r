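#' Institutional ED saturation rule
#'
#' The ED counts as saturated when every treatment space is occupied and the
#' waiting count strictly exceeds a configured fraction of bed capacity
#' (default 0.25, i.e. > 14 waiting for 56 beds). Exactly at the threshold is
#' not saturated. Pure and vectorised.
#'
#' @param n_waiting Waiting-room count (>= 0).
#' @param n_in_treatment In-treatment count (>= 0).
#' @param n_beds Bed capacity.
#' @param waiting_ratio Threshold fraction of `n_beds`.
#' @return Logical vector.
#' @export
saturation_rule <- function(n_waiting, n_in_treatment, n_beds,
                            waiting_ratio = 0.25) {
  if (any(n_waiting < 0) || any(n_in_treatment < 0)) {
    stop("counts must be non-negative")
  }
  n_in_treatment >= n_beds & n_waiting > waiting_ratio * n_beds
}

#' Calibrate the ED-state grid inputs from encounter data
#'
#' Extracts from a (synthetic) encounter table the base quantities the state
#' grid needs: the average arrival rate and the bed count, together with the
#' vertical-pathway service parameters. The vertical assessment is quick
#' (default ~4 minutes, `mu_vpp` = 16/h) and the staffing physician returns
#' from main-ED duties at vacation rate `theta` = 6/h (10-minute mean
#' absences).
#'
#' @param encounters Encounter table (non-empty).
#' @param n_beds Bed capacity.
#' @param mu_vpp,theta Vertical-pathway service and vacation rates (/hour).
#' @return List of class `ed_state_calibration`.
#' @export
calibrate_ed_states <- function(encounters, n_beds = 56,
                                mu_vpp = 16, theta = 6) {
  if (nrow(encounters) == 0) stop("empty calibration data")
  hours <- diff(range(encounters$arrival_time)) / 60
  structure(list(
    base_lambda = nrow(encounters) / max(hours, 1),
    n_beds = n_beds, mu_vpp = mu_vpp, theta = theta
  ), class = "ed_state_calibration")
}

#' Enumerate a grid of calibrated ED states
#'
#' Crosses three axes: a demand multiplier on the base arrival rate, a main-ED
#' staffing coverage level expressed as the nominal utilisation it targets
#' (staffing follows scheduled demand, so higher demand states also carry more
#' physicians), and a congestion level (`quiet`, `busy`, `crowded`) setting
#' the instantaneous census. Crowded states have every bed full and a long
#' queue, which (a) flags them saturated under [saturation_rule()] and (b)
#' inflates the effective near-term arrival rate by the waiting backlog.
#'
#' @param calib An [calibrate_ed_states()] result.
#' @param demand_mult Demand multipliers.
#' @param coverage Target nominal main-ED utilisations (staffing axis).
#' @param congestion Congestion level names (subset of quiet/busy/crowded).
#' @param backlog_gain Effective-arrival inflation per waiting patient per
#'   bed.
#' @param per_physician_rate Main-ED patients/hour a physician carries.
#' @return Data frame, one row per state, with per-state queue rates; grid
#'   size is the product of the axis lengths.
#' @export
enumerate_ed_states <- function(calib,
                                demand_mult = c(0.8, 1.0, 1.2, 1.45),
                                coverage = c(0.70, 0.75, 0.80),
                                congestion = c("quiet", "busy", "crowded"),
                                backlog_gain = 1.0,
                                per_physician_rate = 1.2) {
  stopifnot(inherits(calib, "ed_state_calibration"))
  cong_spec <- list(
    quiet   = c(treat_frac = 0.60, wait_frac = 0.00),
    busy    = c(treat_frac = 1.00, wait_frac = 0.10),
    crowded = c(treat_frac = 1.00, wait_frac = 0.80)
  )
  stopifnot(all(congestion %in% names(cong_spec)))
  grid <- expand.grid(demand_mult = demand_mult, coverage = coverage,
                      congestion = congestion, stringsAsFactors = FALSE)
  nb <- calib$n_beds
  cs <- do.call(rbind, cong_spec[grid$congestion])
  grid$n_in_treatment <- round(cs[, "treat_frac"] * nb)
  grid$n_waiting <- round(cs[, "wait_frac"] * nb)
  grid$saturated <- saturation_rule(grid$n_waiting, grid$n_in_treatment, nb)
  nominal <- calib$base_lambda * grid$demand_mult
  grid$lambda_total <- nominal * (1 + backlog_gain * grid$n_waiting / nb)
  grid$mu_main <- nominal / grid$coverage
  grid$physicians <- pmax(1, round(grid$mu_main / per_physician_rate))
  grid$nurses <- 2L * grid$physicians
  grid$mu_vpp <- calib$mu_vpp
  grid$theta <- calib$theta
  grid$state_id <- seq_len(nrow(grid))
  grid
}

#' Patient strata with representative risk scores
#'
#' One stratum per (ESI, complaint) cell, with the stratum risk set to the
#' mean predicted bed-need score of the cohort members in the cell (empty
#' cells fall back to the ESI-level mean).
#'
#' @param cohort Preprocessed cohort with predictors.
#' @param model A fitted `bed_need_model`.
#' @return Data frame with `esi`, `complaint`, `risk`, `n`.
#' @export
patient_strata <- function(cohort, model) {
  cohort$risk <- predict_risk(model, cohort)
  cells <- expand.grid(esi = 1:5,
                       complaint = sort(unique(cohort$complaint)),
                       stringsAsFactors = FALSE)
  esi_mean <- tapply(cohort$risk, cohort$esi, mean)
  cells$risk <- NA_real_
  cells$n <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- cohort$esi == cells$esi[i] & cohort$complaint == cells$complaint[i]
    cells$n[i] <- sum(sel)
    cells$risk[i] <- if (any(sel)) mean(cohort$risk[sel]) else
      unname(esi_mean[as.character(cells$esi[i])])
  }
  cells
}

#' Theoretically optimal routing labels across ED states
#'
#' For every state in the grid, solves the misclassification-aware routing
#' threshold via [optimal_threshold()] under that state's rates, then labels
#' each patient stratum `vpp_eligible` iff its representative risk score is at
#' or below the state's optimal threshold. States where no threshold yields a
#' stable system are labelled all-`main_ed` and noted.
#'
#' @param states Output of [enumerate_ed_states()].
#' @param strata Output of [patient_strata()].
#' @param cost A [cost_spec()].
#' @param confusion A [risk_confusion()] for the arriving population.
#' @return Data frame of labelled examples (state fields x stratum fields,
#'   `tau_star`, `label`); attribute `infeasible_states` lists any states
#'   without a stable threshold.
#' @export
optimal_labels_for_states <- function(states, strata, cost, confusion) {
  stopifnot(nrow(states) > 0, nrow(strata) > 0)
  infeasible <- integer(0)
  out <- vector("list", nrow(states))
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    params <- queue_params(st$lambda_total, st$mu_vpp, st$mu_main, st$theta)
    tau <- tryCatch(optimal_threshold(params, cost, confusion)$tau,
                    error = function(e) NA_real_)
    if (is.na(tau)) {
      infeasible <- c(infeasible, st$state_id)
      tau <- -1  # nothing eligible
    }
    ex <- strata
    ex$state_id <- st$state_id
    ex$saturated <- st$saturated
    ex$demand_mult <- st$demand_mult
    ex$coverage <- st$coverage
    ex$congestion <- st$congestion
    ex$tau_star <- tau
    ex$label <- factor(ifelse(ex$risk <= tau, "vpp_eligible", "main_ed"),
                       levels = c("main_ed", "vpp_eligible"))
    out[[i]] <- ex
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(infeasible)) {
    message("states without a stable routing threshold (all main_ed): ",
            paste(infeasible, collapse = ", "))
  }
  attr(res, "infeasible_states") <- infeasible
  res
}

#' Distill optimal routing labels into an interpretable protocol tree
#'
#' Fits a shallow classification tree on (ESI, complaint category, saturation
#' flag) only — the risk score itself is excluded so the result reads as a
#' triage-desk protocol. Leaves with tied class counts resolve to `main_ed`
#' (the conservative routing). The fit is deterministic for fixed inputs.
#'
#' @param examples Labelled examples from [optimal_labels_for_states()].
#' @param max_depth Maximum tree depth (<= 4 keeps the protocol readable).
#' @return Object of class `protocol_tree` with the `rpart` fit and the
#'   training agreement.
#' @export
distill_decision_tree <- function(examples, max_depth = 4) {
  stopifnot(nrow(examples) > 0, max_depth >= 1)
  examples$saturated <- factor(examples$saturated, levels = c(FALSE, TRUE))
  examples$complaint <- factor(examples$complaint)
  if (length(unique(examples$label)) < 2) {
    warning("single-label examples: returning a one-leaf protocol")
    tr <- structure(list(
      fit = NULL, max_depth = max_depth,
      constant = as.character(unique(examples$label)),
      complaint_levels = levels(examples$complaint)
    ), class = "protocol_tree")
    tr$training_agreement <- 1
    return(tr)
  }
  fit <- rpart::rpart(
    label ~ esi + complaint + saturated, data = examples,
    method = "class",
    control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                   minsplit = 4, minbucket = 2, xval = 0)
  )
  tr <- structure(list(
    fit = fit, max_depth = max_depth,
    complaint_levels = levels(examples$complaint)
  ), class = "protocol_tree")
  tr$training_agreement <- agreement_rate(tr, examples)
  tr
}

#' @export
predict.protocol_tree <- function(object, newdata, ...) {
  if (!is.null(object$constant)) {
    return(factor(rep(object$constant, nrow(newdata)),
                  levels = c("main_ed", "vpp_eligible")))
  }
  newdata$saturated <- factor(newdata$saturated, levels = c(FALSE, TRUE))
  newdata$complaint <- factor(newdata$complaint,
                              levels = object$complaint_levels)
  stats::predict(object$fit, newdata = newdata, type = "class")
}

#' Agreement between a protocol tree and the optimal labels
#'
#' @param tree A `protocol_tree`.
#' @param examples Labelled examples (ideally held-out states).
#' @return Fraction in [0, 1] of examples where the tree reproduces the
#'   theoretically optimal routing label.
#' @export
agreement_rate <- function(tree, examples) {
  stopifnot(inherits(tree, "protocol_tree"))
  if (nrow(examples) == 0) stop("no examples to score")
  mean(predict(tree, examples) == examples$label)
}

#' The deployed fixed routing protocol
#'
#' The fixed operational protocol (not the refitted tree): patients
#' with ESI 4 or 5 are VPP-eligible; ESI 3 with a skin, urinary or eye
#' complaint is VPP-eligible; during ED saturation every waiting-room patient
#' is VPP-eligible; everyone else goes to the main ED. Vectorised.
#'
#' @param esi Integer ESI in 1-5.
#' @param complaint Complaint category.
#' @param saturated Logical saturation flag.
#' @return Character vector in `{vpp_eligible, main_ed}`.
#' @export
protocol_decision <- function(esi, complaint, saturated) {
  if (any(!esi %in% 1:5)) stop("esi must be in 1..5")
  eligible <- saturated |
    esi %in% c(4, 5) |
    (esi == 3 & complaint %in% c("skin", "urinary", "eye"))
  ifelse(eligible, "vpp_eligible", "main_ed")
}

#' Serialise a protocol tree as nested if/else JSON and a text diagram
#'
#' @param tree A `protocol_tree`.
#' @param path Optional file to write JSON to.
#' @return Invisibly, a list with `json` (character) and `text` (character
#'   vector, the rendered diagram).
#' @export
protocol_tree_render <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "protocol_tree"))
  fit <- tree$fit
  fr <- fit$frame
  labs <- labels(fit)
  nodes <- as.integer(rownames(fr))
  build <- function(node) {
    i <- match(node, nodes)
    if (fr$var[i] == "<leaf>") {
      return(list(decision = attr(fit, "ylevels")[fr$yval[i]]))
    }
    kids <- c(2L * node, 2L * node + 1L)
    list(split = labs[match(kids[1], nodes)],
         if_true = build(kids[1]),
         if_false = build(kids[2]))
  }
  structure_list <- build(1L)
  json <- jsonlite::toJSON(structure_list, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  txt <- utils::capture.output(print(fit))
  invisible(list(json = as.character(json), text = txt))
}
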