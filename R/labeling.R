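#' Default chief-complaint mapping table
#'
#' Maps raw complaint strings to the fixed category set used throughout the
#' package. Shipped as an editable CSV in `inst/extdata/complaint_map.csv`.
#' Note that visual-field-cut presentations map to `neurological`, not `eye`,
#' because of their stroke potential.
#'
#' @return Data frame with columns `raw` and `category`.
#' @export
complaint_map <- function() {
  path <- system.file("extdata", "complaint_map.csv", package = "vppflow")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Preprocess raw encounter records
#'
#' Applies the cleaning steps assumed by the labeling and modelling stages:
#' removes duplicate `encounter_id`s (keeping the first), drops rows with
#' missing ESI, complaint, vitals, disposition or LOS (the drops are counted
#' in the attached run log), z-standardises each vital (columns ending in
#' `_z`), and maps complaint values outside the canonical category set via the
#' mapping table, routing unmappable values to `"other"` with a warning.
#'
#' Standardisation statistics are taken from `stats` when supplied (e.g. the
#' training split's means/SDs, so a test split is standardised on the training
#' scale) and computed from the data otherwise. A zero-variance vital
#' standardises to 0 rather than NaN.
#'
#' @param raw Data frame conforming to the encounter schema.
#' @param vital_cols Names of the vital-sign columns.
#' @param map Complaint mapping table (`raw`, `category`); default shipped map.
#' @param stats Optional list with `mean` and `sd` named vectors over
#'   `vital_cols`.
#' @return Cleaned data frame with `<vital>_z` columns; attributes
#'   `drop_log` (named counts) and `vital_stats` (the statistics used).
#' @export
preprocess <- function(raw, vital_cols = c("hr", "sbp", "rr", "temp", "spo2"),
                       map = complaint_map(), stats = NULL) {
  stopifnot(is.data.frame(raw))
  log <- c(duplicates = 0L, missing = 0L, remapped = 0L)

  dup <- duplicated(raw$encounter_id)
  log["duplicates"] <- sum(dup)
  out <- raw[!dup, , drop = FALSE]

  need <- c("esi", "complaint", "disposition", "los", vital_cols)
  complete <- stats::complete.cases(out[, need, drop = FALSE])
  log["missing"] <- sum(!complete)
  out <- out[complete, , drop = FALSE]

  canonical <- unique(map$category)
  unknown <- !(out$complaint %in% canonical)
  if (any(unknown)) {
    idx <- match(out$complaint[unknown], map$raw)
    mapped <- map$category[idx]
    still <- is.na(mapped)
    if (any(still)) {
      warning(sprintf("%d complaint value(s) not in the mapping table; routed to 'other'",
                      sum(still)))
      mapped[still] <- "other"
    }
    out$complaint[unknown] <- mapped
    log["remapped"] <- sum(unknown)
  }

  if (is.null(stats)) {
    stats <- list(mean = vapply(out[vital_cols], mean, numeric(1)),
                  sd = vapply(out[vital_cols], stats::sd, numeric(1)))
  }
  for (v in vital_cols) {
    s <- stats$sd[[v]]
    m <- stats$mean[[v]]
    out[[paste0(v, "_z")]] <- if (is.na(s) || s == 0) {
      rep(0, nrow(out))
    } else {
      (out[[v]] - m) / s
    }
  }
  attr(out, "drop_log") <- log
  attr(out, "vital_stats") <- stats
  rownames(out) <- NULL
  out
}

#' Assign tiered bed-need labels
#'
#' Implements the tiered outcome definition of "requires an ED bed". Tiers
#' are assigned by the first matching rule, in order:
#' \enumerate{
#'   \item `gold_no_bed` — seen in the vertical pathway and discharged
#'     (no bed was ever assigned): observed, not synthetic.
#'   \item `synth_esi3_no_bed` — ESI 3, discharged, no imaging (CT with or
#'     without contrast, X-ray, ultrasound), no IV therapy, LOS strictly
#'     under 120 minutes.
#'   \item `synth_esi45_no_bed` — ESI 4 or 5 with no IV medications/fluids.
#'   \item `bed` — everything else.
#' }
#' The binary label `bed_need` is `TRUE` iff the tier is `bed`.
#'
#' @param clean A preprocessed encounter table.
#' @return The table with columns `label_tier` (factor in rule order) and
#'   `bed_need` (logical).
#' @export
assign_bed_need_labels <- function(clean) {
  req <- c("esi", "disposition", "los", "seen_in_vpp", "proc_iv",
           "proc_ct_con", "proc_ct_noncon", "proc_xray", "proc_us")
  miss <- setdiff(req, names(clean))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  imaging <- clean$proc_ct_con | clean$proc_ct_noncon | clean$proc_xray |
    clean$proc_us
  tier <- rep("bed", nrow(clean))
  rule2 <- clean$esi %in% c(4, 5) & !clean$proc_iv
  tier[rule2] <- "synth_esi45_no_bed"
  rule1 <- clean$esi == 3 & clean$disposition == "discharged" &
    !imaging & !clean$proc_iv & clean$los < 120
  tier[rule1] <- "synth_esi3_no_bed"
  gold <- clean$seen_in_vpp & clean$disposition == "discharged"
  tier[gold] <- "gold_no_bed"
  clean$label_tier <- factor(tier, levels = c("gold_no_bed",
                                              "synth_esi3_no_bed",
                                              "synth_esi45_no_bed", "bed"))
  clean$bed_need <- tier == "bed"
  clean
}

#' Flag the gold-standard held-out evaluation subset
#'
#' Marks rows reserved for test-set use only: all `gold_no_bed` cases
#' (patients discharged directly from the vertical pathway — the only labels
#' observed rather than rule-synthesised) as the negative "no bed" class, and
#' an equal-size random sample of unambiguous bed cases (ESI <= 2 who were
#' admitted) as the positive class.
#'
#' @param labeled Output of [assign_bed_need_labels()].
#' @param seed RNG seed for the bed-case sample.
#' @return The table with a logical `gold_test` column.
#' @export
flag_gold_test_set <- function(labeled, seed = 1L) {
  stopifnot("label_tier" %in% names(labeled))
  gold_neg <- which(labeled$label_tier == "gold_no_bed")
  pool_pos <- which(labeled$esi <= 2 & labeled$disposition == "admitted")
  if (length(gold_neg) == 0) stop("no gold-standard (VPP-discharged) cases")
  set.seed(seed)
  k <- min(length(gold_neg), length(pool_pos))
  pos <- sample(pool_pos, k)
  labeled$gold_test <- FALSE
  labeled$gold_test[c(gold_neg, pos)] <- TRUE
  labeled
}

#' Tier counts for a labeling run
#'
#' @param labeled Output of [assign_bed_need_labels()].
#' @return Named list of tier counts plus the binary prevalence, suitable for
#'   JSON serialisation.
#' @export
labeling_report <- function(labeled) {
  counts <- as.list(table(labeled$label_tier))
  counts$n <- nrow(labeled)
  counts$prevalence_bed <- mean(labeled$bed_need)
  counts
}
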