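#' Fit the bed-need risk classifier
#'
#' Trains a random-forest (bagged-tree ensemble) classifier of the binary
#' "requires an ED bed" label on triage-time features only: ESI, complaint
#' category, age, and standardised vital signs. Post-hoc fields (procedures,
#' disposition, LOS) are never predictors — the model must be usable at
#' triage, before any of those exist.
#'
#' @param train Labeled, preprocessed table with a `bed_need` column.
#' @param features Character vector of predictor columns.
#' @param num_trees Number of trees (default 200).
#' @param max_depth Maximum tree depth; 0 (default) = unlimited.
#' @param seed RNG seed; the fit and its predictions are reproducible.
#' @return An object of class `bed_need_model`.
#' @export
fit_bed_need_model <- function(train,
                               features = c("esi", "complaint", "age",
                                            "hr_z", "sbp_z", "rr_z",
                                            "temp_z", "spo2_z"),
                               num_trees = 200, max_depth = 0, seed = 1L) {
  miss <- setdiff(c(features, "bed_need"), names(train))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  y <- factor(train$bed_need, levels = c(FALSE, TRUE),
              labels = c("nobed", "bed"))
  if (nlevels(droplevels(y)) < 2) {
    stop("training labels are single-class: all '",
         as.character(unique(y)), "'")
  }
  dat <- train[, features, drop = FALSE]
  dat$complaint <- factor(dat$complaint)
  dat$.y <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = num_trees, max.depth = max_depth,
    probability = TRUE, importance = "impurity",
    respect.unordered.factors = "order",
    seed = seed, num.threads = 1
  )
  structure(list(
    fit = fit, features = features,
    complaint_levels = levels(dat$complaint),
    meta = list(seed = seed, n = nrow(train), num_trees = num_trees,
                label_tiers = if ("label_tier" %in% names(train))
                  as.list(table(train$label_tier)) else NULL)
  ), class = "bed_need_model")
}

#' Predict the personalised bed-need risk score
#'
#' @param model A fitted [fit_bed_need_model()] object.
#' @param newdata Data frame with the training feature columns.
#' @return Numeric vector in [0, 1]: predicted probability that the patient
#'   requires an ED bed (low scores mark vertical-pathway candidates).
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "bed_need_model"))
  miss <- setdiff(model$features, names(newdata))
  if (length(miss)) {
    stop("newdata is missing feature(s): ", paste(miss, collapse = ", "))
  }
  dat <- newdata[, model$features, drop = FALSE]
  dat$complaint <- factor(dat$complaint, levels = model$complaint_levels)
  if (anyNA(dat$complaint)) {
    stop("complaint level(s) unseen in training: ",
         paste(unique(newdata$complaint[is.na(dat$complaint)]),
               collapse = ", "))
  }
  p <- stats::predict(model$fit, data = dat, num.threads = 1)$predictions
  unname(p[, "bed"])
}

#' Bootstrap evaluation of AUC on the gold-standard test set
#'
#' Repeats `n_boot` resampled train/evaluate rounds: each round fits the
#' model on a bootstrap resample of the non-gold rows and computes the AUC of
#' the resulting risk score on the untouched gold-standard test rows (flagged
#' by [flag_gold_test_set()]; never resampled, never trained on).
#'
#' @param data Labeled table with a logical `gold_test` column.
#' @param n_boot Number of bootstrap iterations (default 5).
#' @param seed Base seed; iteration b uses `seed + b`.
#' @param ... Passed to [fit_bed_need_model()].
#' @return List of class `auc_report`: `auc` (per-iteration vector),
#'   `mean_auc`, `sd_auc` (0 with `sd_undefined = TRUE` when n_boot = 1),
#'   `n_boot`.
#' @export
evaluate_auc_bootstrap <- function(data, n_boot = 5, seed = 1L, ...) {
  if (!"gold_test" %in% names(data)) stop("data lacks a gold_test flag")
  test <- data[data$gold_test, , drop = FALSE]
  pool <- data[!data$gold_test, , drop = FALSE]
  if (nrow(test) == 0) stop("gold-standard test subset is empty")
  stopifnot(n_boot >= 1)
  aucs <- vapply(seq_len(n_boot), function(b) {
    set.seed(seed + b)
    idx <- sample.int(nrow(pool), replace = TRUE)
    m <- fit_bed_need_model(pool[idx, , drop = FALSE], seed = seed + b, ...)
    s <- predict_risk(m, test)
    as.numeric(pROC::auc(pROC::roc(response = test$bed_need, predictor = s,
                                   levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE)))
  }, numeric(1))
  structure(list(
    auc = aucs, mean_auc = mean(aucs),
    sd_auc = if (n_boot == 1) 0 else stats::sd(aucs),
    sd_undefined = n_boot == 1, n_boot = n_boot,
    n_test = nrow(test)
  ), class = "auc_report")
}

#' Feature importances of a fitted risk model
#'
#' Mean decrease in impurity (the default `ranger` impurity importance),
#' normalised to sum to one and sorted decreasing.
#'
#' @param model A `bed_need_model`.
#' @return Data frame with columns `feature` and `importance`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "bed_need_model"))
  imp <- ranger::importance(model$fit)
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
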