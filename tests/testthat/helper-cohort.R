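# Builds a small harmonized case table in code; every schema field gets a
# sensible default and any field can be overridden (recycled to n).
make_records <- function(n, ...) {
  over <- list(...)
  base <- list(
    record_id = sprintf("R%03d", seq_len(n)),
    source = "literature",
    species_common = "Green iguana",
    species_scientific = "Iguana iguana",
    age_months = NA_real_,
    life_stage = "adult",
    sex = "female",
    diagnosis = "fibroma",
    malignancy = "benign",
    metastasis = "unknown",
    tumor_location = "skin",
    treatment = "no_treatment",
    outcome = "alive",
    survival_months = 1
  )
  for (f in names(over)) base[[f]] <- rep_len(over[[f]], n)
  as.data.frame(lapply(base, rep_len, n), stringsAsFactors = FALSE)
}

make_cohort <- function(n, ...) asCohort(make_records(n, ...))

fixture_path <- function() {
  system.file("extdata", "printed_cohort_synthetic.csv",
              package = "sauronc", mustWork = TRUE)
}

# global-null generator settings: no predictor moves the outcome
null_config <- function(n = 274, seed = 1) {
  syntheticConfig(n_records = n, true_effects = list(), baseline_p = 0.5,
                  seed = seed)
}
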