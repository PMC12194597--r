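# Shared fixtures, built in code at test time.

# A reduced-horizon configuration that keeps module tests quick while
# preserving the generator's structure (three periods, all feature types).
small_config <- function(seed = 1L, n = 4000, ...) {
  ed_generator_config(n_encounters = n, horizon_days = 30,
                      cutover_days = c(12, 19), seed = seed, ...)
}

# Generate -> clean -> label -> flag in one step.
small_labeled <- function(seed = 1L, n = 4000, ...) {
  enc <- generate_encounters(small_config(seed = seed, n = n, ...))
  flag_gold_test_set(assign_bed_need_labels(preprocess(enc)), seed = seed)
}

# A deterministic confusion object from beta-distributed class scores.
beta_confusion <- function(seed, n_bed = 300, n_nobed = 200,
                           prevalence = n_bed / (n_bed + n_nobed)) {
  set.seed(seed)
  risk_confusion(stats::rbeta(n_bed, 4, 1.5), stats::rbeta(n_nobed, 1.5, 4),
                 prevalence_bed = prevalence)
}
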