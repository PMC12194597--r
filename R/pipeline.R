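#' Run the end-to-end study replica
#'
#' Orchestrates the full pipeline — synthetic data, labeling, risk-model fit,
#' routing-threshold solution, policy distillation, simulation validation and
#' before/after evaluation — writing each stage's artifacts and a manifest
#' with seeds, config hash and per-file checksums. One seed governs all
#' stages through per-stage derived seeds (`seed + stage index`), so a run is
#' reproducible from the manifest alone.
#'
#' @param config An [ed_generator_config()]; its own seed is overridden by
#'   the derived stage seed.
#' @param stages Subset of
#'   `c("synth", "label", "fit", "solve", "distill", "simulate", "evaluate")`
#'   (dependencies are checked, not auto-run).
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if needed).
#' @return The manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = ed_generator_config(),
                         stages = c("synth", "label", "fit", "solve",
                                    "distill", "simulate", "evaluate"),
                         seed = 1L, out_dir = "results/pipeline") {
  all_stages <- c("synth", "label", "fit", "solve", "distill", "simulate",
                  "evaluate")
  stopifnot(all(stages %in% all_stages))
  stages <- all_stages[all_stages %in% stages]
  deps <- list(label = "synth", fit = "label", solve = "fit",
               distill = "solve", simulate = "solve", evaluate = "label")
  for (s in stages) {
    for (d in deps[[s]]) {
      if (!d %in% stages) {
        stop(sprintf("stage '%s' requires stage '%s'", s, d))
      }
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  log_line <- function(stage, msg, level = "INFO") {
    cat(jsonlite::toJSON(list(stage = stage, level = level, message = msg,
                              time = format(Sys.time())),
                         auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  stage_seed <- function(s) seed + match(s, all_stages)
  outputs <- list()
  record <- function(stage, file) {
    outputs[[stage]] <<- c(outputs[[stage]], file)
  }
  env <- new.env()

  if ("synth" %in% stages) {
    cfg <- config
    cfg$seed <- stage_seed("synth")
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
    env$encounters <- generate_encounters(cfg)
    utils::write.csv(env$encounters, file.path(out_dir, "encounters.csv"),
                     row.names = FALSE)
    env$states <- generate_ed_state_series(cfg, horizon = 7 * 1440)
    utils::write.csv(env$states, file.path(out_dir, "ed_state_series.csv"),
                     row.names = FALSE)
    env$config <- cfg
    record("synth", c("config.yaml", "encounters.csv", "ed_state_series.csv"))
    log_line("synth", sprintf("generated %d encounters (seed %d)",
                              nrow(env$encounters), cfg$seed))
  }

  if ("label" %in% stages) {
    clean <- preprocess(env$encounters)
    labeled <- assign_bed_need_labels(clean)
    env$labeled <- flag_gold_test_set(labeled, seed = stage_seed("label"))
    rep <- labeling_report(env$labeled)
    rep$dropped <- as.list(attr(clean, "drop_log"))
    jsonlite::write_json(rep, file.path(out_dir, "labeling_report.json"),
                         auto_unbox = TRUE)
    record("label", "labeling_report.json")
    log_line("label", sprintf("labeled %d rows; bed prevalence %.3f",
                              rep$n, rep$prevalence_bed))
  }

  if ("fit" %in% stages) {
    s <- stage_seed("fit")
    train <- env$labeled[!env$labeled$gold_test, , drop = FALSE]
    env$model <- fit_bed_need_model(train, seed = s)
    env$labeled$risk <- predict_risk(env$model, env$labeled)
    auc <- evaluate_auc_bootstrap(env$labeled, n_boot = 5, seed = s)
    imp <- feature_importance(env$model)
    jsonlite::write_json(auc[c("auc", "mean_auc", "sd_auc", "n_boot")],
                         file.path(out_dir, "auc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(imp, file.path(out_dir, "feature_importance.csv"),
                     row.names = FALSE)
    record("fit", c("auc_report.json", "feature_importance.csv"))
    log_line("fit", sprintf("mean gold-standard AUC %.3f (SD %.3f)",
                            auc$mean_auc, auc$sd_auc))
  }

  if ("solve" %in% stages) {
    env$calib <- calibrate_ed_states(env$encounters,
                                     n_beds = env$config$n_beds)
    env$confusion <- risk_confusion(
      env$labeled$risk[env$labeled$bed_need],
      env$labeled$risk[!env$labeled$bed_need])
    env$cost <- cost_spec()
    base <- queue_params(env$calib$base_lambda,
                         env$calib$mu_vpp,
                         env$calib$base_lambda / 0.8,
                         env$calib$theta)
    sol <- optimal_threshold(base, env$cost, env$confusion)
    jsonlite::write_json(unclass(sol),
                         file.path(out_dir, "threshold_solution.json"),
                         auto_unbox = TRUE, digits = NA)
    record("solve", "threshold_solution.json")
    log_line("solve", sprintf("baseline optimal threshold %.3f", sol$tau))
    env$base_tau <- sol$tau
  }

  if ("distill" %in% stages) {
    s <- stage_seed("distill")
    dist <- distill_protocol(env$labeled, env$model, env$calib, env$cost,
                             env$confusion, seed = s)
    env$tree <- dist$tree
    out <- protocol_tree_render(dist$tree,
                                path = file.path(out_dir, "protocol.json"))
    writeLines(out$text, file.path(out_dir, "protocol.txt"))
    jsonlite::write_json(list(heldout_agreement = dist$heldout_agreement,
                              training_agreement =
                                dist$tree$training_agreement),
                         file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    record("distill", c("protocol.json", "protocol.txt", "agreement.json"))
    log_line("distill", sprintf("held-out protocol agreement %.4f",
                                dist$heldout_agreement))
    env$agreement <- dist$heldout_agreement
  }

  if ("simulate" %in% stages) {
    s <- stage_seed("simulate")
    grid <- default_validation_grid()
    val <- validate_against_analytic(grid, n_patients = 2e4, n_reps = 3,
                                     seed = s)
    utils::write.csv(val, file.path(out_dir, "des_validation.csv"),
                     row.names = FALSE)
    record("simulate", "des_validation.csv")
    log_line("simulate", sprintf("analytic waits CI-covered at %d/%d points",
                                 sum(val$covered), nrow(val)))
  }

  if ("evaluate" %in% stages) {
    pre <- env$labeled[env$labeled$period == "pre", ]
    post <- env$labeled[env$labeled$period == "post", ]
    t1 <- summarize_table1(pre, post)
    t2 <- vpp_routing_table2(pre, post)
    eff <- fit_log_los_model(env$labeled)
    ret <- fit_return_models(env$labeled)
    rob <- robustness_suite(env$labeled)
    utils::write.csv(t1, file.path(out_dir, "table1.csv"), row.names = FALSE)
    utils::write.csv(t2, file.path(out_dir, "table2.csv"), row.names = FALSE)
    utils::write.csv(rob, file.path(out_dir, "robustness.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(log_los = unclass(eff),
           return_72h = unclass(ret$return_72h),
           return_72h_admit = unclass(ret$return_72h_admit),
           los_diff_minutes = attr(t1, "los_diff_minutes"),
           los_diff_pct = attr(t1, "los_diff_pct")),
      file.path(out_dir, "effects.json"), auto_unbox = TRUE, digits = NA)
    record("evaluate", c("table1.csv", "table2.csv", "robustness.csv",
                         "effects.json"))
    log_line("evaluate",
             sprintf("adjusted post effect %.2f min (%.2f%%)",
                     eff$minutes_change, eff$pct_change))
  }

  files <- unlist(outputs, use.names = FALSE)
  manifest <- list(
    seed = seed,
    stage_seeds = stats::setNames(lapply(stages, stage_seed), stages),
    config_hash = as.character(tools::md5sum(
      file.path(out_dir, "config.yaml"))),
    artifacts = lapply(stats::setNames(files, files), function(f) {
      as.character(tools::md5sum(file.path(out_dir, f)))
    }),
    protocol_agreement = if (!is.null(env$agreement)) env$agreement,
    versions = list(vppflow = as.character(utils::packageVersion("vppflow")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timestamp = format(Sys.time())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Default grid for the analytic-vs-simulation cross-validation
#'
#' Twelve stable (lambda, mu, theta) points spanning light to heavy load for
#' both the plain M/M/1 (theta = NA) and the vacation queue.
#'
#' @return Data frame with columns `lambda`, `mu`, `theta`.
#' @export
default_validation_grid <- function() {
  rbind(
    data.frame(lambda = c(0.3, 0.5, 0.7, 0.85, 0.6, 0.9),
               mu = c(1, 1, 1, 1, 0.8, 1.2), theta = NA_real_),
    data.frame(lambda = c(0.3, 0.5, 0.7, 0.85, 0.6, 0.9),
               mu = c(1, 1, 1, 1, 0.8, 1.2),
               theta = c(2, 2, 1, 4, 0.5, 8))
  )
}

#' Distill the routing protocol from the fitted pipeline objects
#'
#' Convenience wrapper tying the policy stage together: builds the patient
#' strata and the calibrated state grid, computes per-state optimal labels,
#' splits the states into a distillation set and a held-out set, fits the
#' protocol tree on the former and scores agreement on the latter.
#'
#' @param labeled Labeled cohort with a `risk` column.
#' @param model Fitted `bed_need_model`.
#' @param calib An `ed_state_calibration`.
#' @param cost A [cost_spec()].
#' @param confusion A [risk_confusion()].
#' @param heldout_frac Fraction of states held out (by state, not row).
#' @param seed RNG seed for the state split.
#' @param max_depth Tree depth cap.
#' @return List with `tree`, `heldout_agreement`, `examples`,
#'   `heldout_examples`, `states`.
#' @export
distill_protocol <- function(labeled, model, calib, cost, confusion,
                             heldout_frac = 1 / 3, seed = 1L,
                             max_depth = 4) {
  states <- enumerate_ed_states(calib)
  strata <- patient_strata(labeled, model)
  examples <- optimal_labels_for_states(states, strata, cost, confusion)
  set.seed(seed)
  ho_states <- sample(states$state_id,
                      size = max(1, round(heldout_frac * nrow(states))))
  ho <- examples$state_id %in% ho_states
  tree <- distill_decision_tree(examples[!ho, , drop = FALSE],
                                max_depth = max_depth)
  list(tree = tree,
       heldout_agreement = agreement_rate(tree, examples[ho, , drop = FALSE]),
       examples = examples[!ho, , drop = FALSE],
       heldout_examples = examples[ho, , drop = FALSE],
       states = states)
}
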