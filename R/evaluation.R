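#' Multivariable log-LOS regression for the before/after contrast
#'
#' Fits `log(los)` on a post-period indicator plus selected control groups:
#' `"patient"` (age, ESI, complaint category), `"operational"` (disposition,
#' procedures, and optionally physician assignment), and `"saturation"`
#' (physicians and nurses on duty at arrival, patients in treatment and
#' waiting, and the arrival shift). Educational-period rows are excluded by
#' default; with `include_edu = TRUE` they enter through a separate period
#' dummy. Calendar covariates are deliberately absent; the congestion and
#' staffing controls stand in for them.
#'
#' @param encounters Encounter table with `los`, `period` and the control
#'   columns.
#' @param covariates Character subset of
#'   `c("patient", "operational", "saturation")`; empty = unadjusted.
#' @param esi_coding `"categorical"` (factor) or `"continuous"`.
#' @param physician_effects `"none"`, `"fixed"` (factor dummies) or
#'   `"random"` (random intercept via `lme4`).
#' @param include_edu Keep educational-period rows with their own dummy.
#' @return Object of class `effect_estimate`: `coef` (log scale), `se`,
#'   `ci95`, `p_value`, `pct_change` = 100*(exp(coef)-1), `minutes_change`
#'   at the pre-period mean LOS, `spec_id`, `n`.
#' @export
fit_log_los_model <- function(encounters,
                              covariates = c("patient", "operational",
                                             "saturation"),
                              esi_coding = c("categorical", "continuous"),
                              physician_effects = c("none", "fixed",
                                                    "random"),
                              include_edu = FALSE) {
  esi_coding <- match.arg(esi_coding)
  physician_effects <- match.arg(physician_effects)
  stopifnot(all(covariates %in% c("patient", "operational", "saturation")))
  dat <- if (include_edu) encounters else
    encounters[encounters$period != "edu", , drop = FALSE]
  if (!any(dat$period == "post")) stop("no post-period rows")
  dat$post <- as.integer(dat$period == "post")
  dat$log_los <- log(dat$los)

  terms <- "post"
  if (include_edu) terms <- c(terms, "I(period == 'edu')")
  if ("patient" %in% covariates) {
    esi_term <- if (esi_coding == "categorical") "factor(esi)" else "esi"
    terms <- c(terms, "age", esi_term, "factor(complaint)")
  }
  if ("operational" %in% covariates) {
    terms <- c(terms, "factor(disposition)", "proc_iv", "proc_ct_con",
               "proc_ct_noncon", "proc_xray", "proc_us")
    if (physician_effects == "fixed") terms <- c(terms, "factor(physician)")
  }
  if ("saturation" %in% covariates) {
    terms <- c(terms, "physicians_on_duty", "nurses_on_duty",
               "n_in_treatment", "n_waiting", "factor(shift)")
  }
  rhs <- paste(terms, collapse = " + ")

  if (physician_effects == "random" && "operational" %in% covariates) {
    fml <- stats::as.formula(paste("log_los ~", rhs, "+ (1 | physician)"))
    fit <- lme4::lmer(fml, data = dat, REML = TRUE)
    cf <- summary(fit)$coefficients
    est <- cf["post", "Estimate"]; se <- cf["post", "Std. Error"]
    pval <- 2 * stats::pnorm(-abs(est / se))
  } else {
    fml <- stats::as.formula(paste("log_los ~", rhs))
    fit <- stats::lm(fml, data = dat)
    aliased <- is.na(stats::coef(fit))
    if (any(aliased)) {
      warning("collinear terms dropped: ",
              paste(names(aliased)[aliased], collapse = ", "))
    }
    cf <- summary(fit)$coefficients
    est <- cf["post", "Estimate"]; se <- cf["post", "Std. Error"]
    pval <- cf["post", "Pr(>|t|)"]
  }
  pre_mean <- mean(dat$los[dat$period == "pre"])
  ci <- est + c(-1, 1) * stats::qnorm(0.975) * se
  structure(list(
    coef = est, se = se, ci95 = ci, p_value = pval,
    pct_change = 100 * (exp(est) - 1),
    minutes_change = pre_mean * (exp(est) - 1),
    ci95_pct = 100 * (exp(ci) - 1),
    spec_id = paste0("covars=", paste(covariates, collapse = "+"),
                     ";esi=", esi_coding, ";phys=", physician_effects),
    n = nrow(dat)
  ), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "post-period effect: %+.4f log units (SE %.4f, p = %.3g)\n  %+.2f%% ; %+.2f min at the pre-period mean\n  spec: %s (n = %d)\n",
    x$coef, x$se, x$p_value, x$pct_change, x$minutes_change, x$spec_id, x$n))
  invisible(x)
}

#' Before/after models of the 72-hour return outcomes
#'
#' Logistic regressions of the 72-hour ED return indicator and the 72-hour
#' return-with-admission indicator on the post-period dummy plus the same
#' control groups as [fit_log_los_model()].
#'
#' @inheritParams fit_log_los_model
#' @return Named list of two `effect_estimate` objects (log-odds scale, with
#'   `pct_change` replaced by the odds ratio).
#' @export
fit_return_models <- function(encounters,
                              covariates = c("patient", "saturation"),
                              esi_coding = c("categorical", "continuous")) {
  esi_coding <- match.arg(esi_coding)
  dat <- encounters[encounters$period != "edu", , drop = FALSE]
  if (!any(dat$period == "post")) stop("no post-period rows")
  dat$post <- as.integer(dat$period == "post")
  terms <- "post"
  if ("patient" %in% covariates) {
    esi_term <- if (esi_coding == "categorical") "factor(esi)" else "esi"
    terms <- c(terms, "age", esi_term, "factor(complaint)")
  }
  if ("saturation" %in% covariates) {
    terms <- c(terms, "physicians_on_duty", "n_in_treatment", "n_waiting",
               "factor(shift)")
  }
  rhs <- paste(terms, collapse = " + ")
  one <- function(outcome) {
    y <- dat[[outcome]]
    if (length(unique(y)) < 2) {
      stop("outcome '", outcome, "' has zero variance")
    }
    fit <- stats::glm(stats::as.formula(paste(outcome, "~", rhs)),
                      data = dat, family = stats::binomial())
    cf <- summary(fit)$coefficients
    est <- cf["post", "Estimate"]; se <- cf["post", "Std. Error"]
    ci <- est + c(-1, 1) * stats::qnorm(0.975) * se
    structure(list(coef = est, se = se, ci95 = ci,
                   p_value = cf["post", "Pr(>|z|)"],
                   odds_ratio = exp(est), spec_id = paste0("logit:", outcome),
                   n = nrow(dat)), class = "effect_estimate")
  }
  list(return_72h = one("return_72h"),
       return_72h_admit = one("return_72h_admit"))
}

welch_or_na <- function(x, y) {
  if (length(x) < 2 || length(y) < 2 || (stats::sd(x) == 0 &&
                                         stats::sd(y) == 0)) {
    return(NA_real_)
  }
  stats::t.test(x, y)$p.value
}

prop_test_p <- function(k1, n1, k2, n2) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Pre/post descriptive comparison table
#'
#' Cohort-characteristics table in the usual before/after layout: mean (SD)
#' and a Welch comparison for continuous variables, percentage and a Pearson
#' chi-square for proportions. The LOS row also reports the difference in
#' minutes and as a percentage of the pre-period mean. Single-row inputs get
#' their means with the SD flagged undefined.
#'
#' @param pre,post Encounter tables for the two periods.
#' @return Data frame of class `comparison_table` with columns `variable`,
#'   `pre`, `post`, `test`, `p_value`; attributes `los_diff_minutes` and
#'   `los_diff_pct`.
#' @export
summarize_table1 <- function(pre, post) {
  stopifnot(nrow(pre) > 0, nrow(post) > 0)
  need <- c("los", "age", "esi", "sex", "race", "disposition",
            "return_72h", "return_72h_admit", "proc_iv", "proc_ct_con",
            "proc_ct_noncon", "proc_xray", "proc_us")
  miss <- setdiff(need, intersect(names(pre), names(post)))
  if (length(miss)) stop("schema mismatch; missing: ",
                         paste(miss, collapse = ", "))
  msd <- function(x) sprintf("%.2f (%s)", mean(x),
                             if (length(x) < 2) "SD undefined"
                             else sprintf("%.2f", stats::sd(x)))
  pct <- function(x) sprintf("%.2f%%", 100 * mean(x))
  cont_row <- function(var, x, y) {
    data.frame(variable = var, pre = msd(x), post = msd(y), test = "Welch t",
               p_value = welch_or_na(x, y), stringsAsFactors = FALSE)
  }
  prop_row <- function(var, x, y) {
    data.frame(variable = var, pre = pct(x), post = pct(y),
               test = "chi-square",
               p_value = prop_test_p(sum(x), length(x), sum(y), length(y)),
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    cont_row("ED length of stay (min)", pre$los, post$los),
    prop_row("Discharged", pre$disposition == "discharged",
             post$disposition == "discharged"),
    prop_row("ED return within 72 h", pre$return_72h, post$return_72h),
    prop_row("ED return within 72 h with admit", pre$return_72h_admit,
             post$return_72h_admit),
    prop_row("Female", pre$sex == "female", post$sex == "female"),
    cont_row("Age (years)", pre$age, post$age),
    prop_row("White", pre$race == "white", post$race == "white"),
    cont_row("ESI", pre$esi, post$esi),
    prop_row("IV", pre$proc_iv, post$proc_iv),
    prop_row("CT with IV contrast", pre$proc_ct_con, post$proc_ct_con),
    prop_row("CT without IV contrast", pre$proc_ct_noncon,
             post$proc_ct_noncon),
    prop_row("X-ray", pre$proc_xray, post$proc_xray),
    prop_row("Ultrasound", pre$proc_us, post$proc_us)
  )
  diff_min <- mean(pre$los) - mean(post$los)
  attr(rows, "los_diff_minutes") <- diff_min
  attr(rows, "los_diff_pct") <- 100 * diff_min / mean(pre$los)
  class(rows) <- c("comparison_table", class(rows))
  rows
}

#' Small-cell test selection rule
#'
#' Pearson's chi-square unless any cell of the 2x2 routed/not-routed by
#' period table is smaller than 10 (strict), in which case Fisher's exact
#' test.
#'
#' @param vpp_pre,n_pre,vpp_post,n_post Stratum counts.
#' @return List with `test` ("chi-square"/"Fisher"/NA) and `p_value`.
#' @export
select_small_cell_test <- function(vpp_pre, n_pre, vpp_post, n_post) {
  if (n_pre == 0 || n_post == 0) {
    return(list(test = NA_character_, p_value = NA_real_))
  }
  tab <- matrix(c(vpp_pre, n_pre - vpp_pre, vpp_post, n_post - vpp_post),
                2, 2, byrow = TRUE)
  if (any(tab < 10)) {
    list(test = "Fisher", p_value = stats::fisher.test(tab)$p.value)
  } else {
    list(test = "chi-square",
         p_value = suppressWarnings(
           stats::chisq.test(tab, correct = FALSE)$p.value))
  }
}

#' VPP routing proportions by acuity stratum, pre vs post
#'
#' ESI strata with ESI 3 split into skin/urinary/eye versus other
#' complaints. Reports the number and percentage of each stratum's patients
#' routed through the vertical pathway in the two periods, with the
#' small-cell test rule of [select_small_cell_test()]. Empty strata are
#' emitted with zero counts and no test.
#'
#' @param pre,post Encounter tables for the two periods (need `esi`,
#'   `complaint`, `seen_in_vpp`).
#' @return Data frame of class `comparison_table`.
#' @export
vpp_routing_table2 <- function(pre, post) {
  sue <- c("skin", "urinary", "eye")
  stratum_of <- function(d) {
    ifelse(d$esi != 3, as.character(d$esi),
           ifelse(d$complaint %in% sue, "3 - skin/urinary/eye",
                  "3 - other"))
  }
  pre$stratum <- stratum_of(pre)
  post$stratum <- stratum_of(post)
  strata <- c("1", "2", "3 - other", "3 - skin/urinary/eye", "4", "5")
  rows <- lapply(strata, function(s) {
    p1 <- pre[pre$stratum == s, , drop = FALSE]
    p2 <- post[post$stratum == s, , drop = FALSE]
    k1 <- sum(p1$seen_in_vpp); k2 <- sum(p2$seen_in_vpp)
    tst <- select_small_cell_test(k1, nrow(p1), k2, nrow(p2))
    data.frame(
      esi_stratum = s,
      pre = sprintf("%d (%.2f%%)", k1,
                    if (nrow(p1)) 100 * k1 / nrow(p1) else 0),
      post = sprintf("%d (%.2f%%)", k2,
                     if (nrow(p2)) 100 * k2 / nrow(p2) else 0),
      n_pre = nrow(p1), n_post = nrow(p2),
      test = tst$test, p_value = tst$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", class(out))
  out
}

#' Reconstruct a stratum denominator from a printed count and percentage
#'
#' Finds the smallest denominator `n` (up to `search_max`) for which
#' `count / n`, expressed as a percentage rounded half-up to two decimals,
#' equals the printed percentage, and reports whether that `n` is unique
#' within +/-10%.
#'
#' @param count Numerator (>= 0).
#' @param printed_pct Printed percentage, two decimals, in (0, 100].
#' @param search_max Largest denominator considered.
#' @return List with `n`, `unique_within_10pct`, `matches`.
#' @export
reconstruct_denominators <- function(count, printed_pct, search_max = 20000) {
  stopifnot(count >= 0, printed_pct > 0, printed_pct <= 100)
  round2 <- function(x) floor(x * 100 + 0.5) / 100
  cand <- max(count, 1):search_max
  hit <- cand[round2(100 * count / cand) == printed_pct]
  if (length(hit) == 0) {
    stop(sprintf("no denominator <= %d matches %d (%.2f%%)",
                 search_max, count, printed_pct))
  }
  n <- hit[1]
  list(n = n,
       unique_within_10pct = !any(hit != n & hit >= 0.9 * n & hit <= 1.1 * n),
       matches = hit)
}

#' Robustness grid of log-LOS specifications
#'
#' Refits [fit_log_los_model()] across a list of specifications and
#' summarises the spread of the implied effect.
#'
#' @param encounters Encounter table.
#' @param specs List of argument lists for [fit_log_los_model()]; the default
#'   grid spans unadjusted through fully adjusted and both ESI codings.
#' @return Data frame, one row per specification; attributes
#'   `minutes_change_range` and `pct_change_range`.
#' @export
robustness_suite <- function(encounters, specs = NULL) {
  if (is.null(specs)) {
    specs <- list(
      list(covariates = character(0)),
      list(covariates = "patient"),
      list(covariates = c("patient", "operational")),
      list(covariates = c("patient", "operational", "saturation")),
      list(covariates = c("patient", "operational", "saturation"),
           esi_coding = "continuous")
    )
  }
  stopifnot(length(specs) >= 1)
  rows <- lapply(specs, function(a) {
    est <- do.call(fit_log_los_model, c(list(encounters), a))
    data.frame(spec_id = est$spec_id, coef = est$coef, se = est$se,
               p_value = est$p_value, pct_change = est$pct_change,
               minutes_change = est$minutes_change, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "minutes_change_range") <- range(out$minutes_change)
  attr(out, "pct_change_range") <- range(out$pct_change)
  out
}
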