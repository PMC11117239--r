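## Synthetic cohort generator.
##
## Emulates the structure of a two-source retrospective lizard oncology
## cohort: a literature arm and a clinical-registry (ESCRA) arm with
## unknown-heavy categorical marginals, a binary outcome linked to predictor
## levels, and right-censored survival times.

# common-name lookup for display; anything absent falls back to the
# scientific name itself (species_scientific is the modeling key).
species_common_names <- c(
  "Iguana iguana" = "Green iguana",
  "Pogona vitticeps" = "Central bearded dragon",
  "Varanus exanthematicus" = "Savannah monitor",
  "Uromastyx acanthinura" = "Spiny-tailed lizard",
  "Chamaeleo calyptratus" = "Veiled chameleon",
  "Heloderma suspectum" = "Gila monster",
  "Eublepharis macularius" = "Leopard gecko",
  "Lacerta viridis" = "European green lizard",
  "Varanus komodoensis" = "Komodo dragon",
  "Varanus acanthurus" = "Spiny-tailed monitor",
  "Furcifer pardalis" = "Panther chameleon",
  "Leiolopisma telfairii" = "Round island skink",
  "Tiliqua nigrolutea" = "Blotched blue-tongued lizard",
  "Anolis carolinensis" = "Green anole"
)

norm1 <- function(x) x / sum(x)

default_literature_frequencies <- function() {
  list(
    species_scientific = norm1(c(
      "Iguana iguana" = 55, "Pogona vitticeps" = 32,
      "Varanus exanthematicus" = 10, "Uromastyx acanthinura" = 10,
      "Chamaeleo calyptratus" = 8, "Heloderma suspectum" = 5,
      "Eublepharis macularius" = 5, "Lacerta viridis" = 4,
      "Varanus komodoensis" = 3, "Varanus acanthurus" = 3,
      "Heloderma exasperatum" = 2, "Eumeces laticeps" = 2,
      "Shinisaurus crocodilurus" = 2, "Cnemidophorus uniparens" = 2,
      "Hydrosaurus amboinensis" = 2, "Anolis carolinensis" = 2,
      "Heloderma horridum" = 2, "Furcifer pardalis" = 2,
      "Leiolopisma telfairii" = 2, "other species" = 66) / 219),
    sex = c(male = 40, female = 41, unknown = 138) / 219,
    life_stage = c(adult = 52, juvenile = 6, unknown = 161) / 219,
    diagnosis = norm1(c(
      "lymphoma" = 18, "squamous cell carcinoma" = 13,
      "chromatophoroma" = 10, "teratoma" = 10,
      "biliary adenocarcinoma" = 6, "fibroma" = 6, "leukemia" = 5,
      "osteosarcoma" = 5, "leiomyosarcoma" = 5, "melanophoroma" = 5,
      "cholangiocarcinoma" = 4, "parathyroid adenoma" = 4,
      "carcinoma" = 3, "gastric carcinoid" = 3,
      "granulosa cell tumor" = 3, "hepatocellular carcinoma" = 3,
      "islet cell carcinoma" = 3, "myxoma" = 3, "papilloma" = 3,
      "thyroid carcinoma" = 3, "chondrosarcoma" = 2,
      "colon adenocarcinoma" = 2, "fibropapilloma" = 2,
      "hemangiosarcoma" = 2, "hepatoma" = 2,
      "interstitial cell adenoma" = 2, "pancreatic adenocarcinoma" = 2,
      "renal adenoma" = 2, "undifferentiated sarcoma" = 2,
      "other neoplasm" = 86) / 219),
    malignancy = c(malignant = 133, benign = 58, undetermined = 28) / 219,
    metastasis = c(present = 13, absent = 50, unknown = 156) / 219,
    tumor_location = norm1(c(
      "liver" = 15, "skin" = 20, "gastrointestinal" = 12,
      "hematopoietic/lymphatic" = 10, "jaw" = 6, "abdominal organ" = 6,
      "skin/scales (head region)" = 6, "bone marrow" = 4, "kidney" = 4,
      "pancreas" = 4, "arm/leg" = 4, "other location" = 100,
      "unknown" = 28) / 219),
    treatment = norm1(c(
      surgery_only = 25, chemotherapy_only = 3, radiation_only = 2,
      surgery_and_chemotherapy = 1, no_treatment = 161,
      unknown_treatment = 27) / 219)
  )
}

default_escra_frequencies <- function() {
  list(
    species_scientific = norm1(c(
      "Pogona vitticeps" = 25, "Furcifer pardalis" = 4,
      "Eublepharis macularius" = 4, "Iguana iguana" = 3,
      "Chamaeleo calyptratus" = 3, "Tiliqua nigrolutea" = 2,
      "other species" = 14) / 55),
    sex = c(male = 26, female = 20, unknown = 9) / 55,
    life_stage = c(adult = 42, juvenile = 0, unknown = 13) / 55,
    diagnosis = norm1(c(
      "squamous cell carcinoma" = 8, "spindle cell sarcoma" = 4,
      "leukemia" = 2, "lymphosarcoma" = 2, "myxosarcoma" = 2,
      "chromatophoroma" = 2, "papilloma" = 2, "sarcoma" = 2,
      "other neoplasm" = 31) / 55),
    malignancy = c(malignant = 40, benign = 7, undetermined = 8) / 55,
    metastasis = c(present = 5, absent = 7, unknown = 43) / 55,
    tumor_location = norm1(c(
      "skin" = 6, "skin/scales (head region)" = 6,
      "gastrointestinal" = 5, "other location" = 28,
      "unknown" = 10) / 55),
    treatment = norm1(c(
      surgery_only = 17, chemotherapy_only = 1, surgery_and_radiation = 1,
      no_treatment = 30, unknown_treatment = 6) / 55)
  )
}

#' Build a synthetic-cohort configuration
#'
#' The defaults encode the study conditions the generator emulates: a
#' 219-record literature arm and a 55-record registry arm whose categorical
#' marginals follow the published frequency tables (including the dominant
#' unknown mass, e.g. 138/219 literature cases of unknown sex), a logistic
#' link from predictor levels to the probability of a non-neoplastic
#' outcome, and exponential event times whose group means make untreated
#' and malignant cases die faster than treated and benign ones.
#'
#' @param n_records number of records to generate.
#' @param source_split probability a record is a literature case
#'   (default 219/274).
#' @param level_frequencies per-source, per-variable categorical
#'   distributions (named probability vectors summing to 1).
#' @param baseline_p probability of a non-neoplastic outcome at reference
#'   levels (all effects zero).
#' @param true_effects named list (by variable) of named numeric vectors
#'   (by level): additive effects on the linear predictor. Positive values
#'   push toward the non-neoplastic outcome.
#' @param outcome_link `"logistic"` (effects on the log-odds scale) or
#'   `"linear_probability"` (effects added to `baseline_p`, clamped to
#'   `[0, 1]`).
#' @param survival_means_months per-malignancy named list with entries
#'   `untreated`, `treated`, `nonneoplastic`: exponential event-time means.
#' @param censor_prob probability that a non-neoplastic-outcome record is
#'   still alive (right-censored).
#' @param censor_mean_months exponential mean of censoring times.
#' @param seed integer root seed; per-stage substreams are derived from it
#'   deterministically.
#' @return A `synthetic_config` list.
#' @export
syntheticConfig <- function(n_records = 274,
                            source_split = 219 / 274,
                            level_frequencies = list(
                              literature = default_literature_frequencies(),
                              escra = default_escra_frequencies()),
                            baseline_p = 0.5,
                            true_effects = list(
                              treatment = c(no_treatment = -0.8,
                                            surgery_only = 0.8,
                                            radiation_only = 0.5),
                              malignancy = c(malignant = -0.5,
                                             benign = 0.5),
                              metastasis = c(present = -0.4)),
                            outcome_link = c("logistic",
                                             "linear_probability"),
                            survival_means_months = list(
                              malignant = c(untreated = 3, treated = 12,
                                            nonneoplastic = 6),
                              benign = c(untreated = 8, treated = 24,
                                         nonneoplastic = 12),
                              undetermined = c(untreated = 5, treated = 15,
                                               nonneoplastic = 8)),
                            censor_prob = 0.4,
                            censor_mean_months = 12,
                            seed = 1L) {
  outcome_link <- match.arg(outcome_link)
  cfg <- list(n_records = as.integer(n_records),
              source_split = source_split,
              level_frequencies = level_frequencies,
              baseline_p = baseline_p, true_effects = true_effects,
              outcome_link = outcome_link,
              survival_means_months = survival_means_months,
              censor_prob = censor_prob,
              censor_mean_months = censor_mean_months,
              seed = as.integer(seed))
  validateSyntheticConfig(cfg)
  structure(cfg, class = "synthetic_config")
}

validateSyntheticConfig <- function(cfg) {
  if (cfg$n_records < 0) stop("n_records must be nonnegative")
  probs <- c(cfg$source_split, cfg$baseline_p, cfg$censor_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (src in names(cfg$level_frequencies)) {
    for (v in names(cfg$level_frequencies[[src]])) {
      p <- cfg$level_frequencies[[src]][[v]]
      if (any(p < 0)) stop("negative frequency in ", src, "$", v)
      if (abs(sum(p) - 1) > 1e-9) {
        stop("frequencies for ", src, "$", v, " sum to ", sum(p), ", not 1")
      }
    }
  }
  invisible(TRUE)
}

# deterministic substream seed for a named generation stage
stage_seed <- function(seed, stage) {
  offsets <- c(covariates = 1L, outcome = 2L, survival = 3L, age = 4L,
               missingness = 5L)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

#' Generate a synthetic cohort
#'
#' Covariates are drawn independently per variable from the configured
#' per-source level frequencies; the binary outcome comes from the
#' configured link applied to the summed true effects; event records
#' receive exponential survival times with the group mean for their
#' malignancy and treatment status, and alive records a censoring time.
#' Identical seeds give identical cohorts.
#'
#' @param config a [syntheticConfig()] object.
#' @return A `lizard_cohort`.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validateSyntheticConfig(config)
  n <- config$n_records
  if (n == 0) {
    empty <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(schemaFields())), schemaFields()),
      stringsAsFactors = FALSE)
    return(asCohort(empty))
  }

  set.seed(stage_seed(config$seed, "covariates"))
  source <- ifelse(stats::runif(n) < config$source_split,
                   "literature", "escra")
  vars <- c("species_scientific", "sex", "life_stage", "diagnosis",
            "malignancy", "metastasis", "tumor_location", "treatment")
  rec <- data.frame(record_id = sprintf("SYN%05d", seq_len(n)),
                    source = source, stringsAsFactors = FALSE)
  for (v in vars) {
    col <- character(n)
    for (src in unique(source)) {
      p <- config$level_frequencies[[src]][[v]]
      idx <- source == src
      col[idx] <- sample(names(p), sum(idx), replace = TRUE, prob = p)
    }
    rec[[v]] <- col
  }
  rec$species_common <- ifelse(
    rec$species_scientific %in% names(species_common_names),
    species_common_names[rec$species_scientific], rec$species_scientific)

  set.seed(stage_seed(config$seed, "age"))
  age_known <- stats::runif(n) < 0.35
  age <- rep(NA_real_, n)
  adult_like <- rec$life_stage != "juvenile"
  age[age_known & adult_like] <-
    round(stats::rlnorm(sum(age_known & adult_like),
                        meanlog = log(60), sdlog = 0.7), 1)
  age[age_known & !adult_like] <-
    round(stats::runif(sum(age_known & !adult_like), 0, 3), 1)
  rec$age_months <- age

  # outcome: linear predictor over configured true effects
  set.seed(stage_seed(config$seed, "outcome"))
  eta <- numeric(n)
  for (v in names(config$true_effects)) {
    eff <- config$true_effects[[v]]
    hit <- rec[[v]] %in% names(eff)
    eta[hit] <- eta[hit] + eff[rec[[v]][hit]]
  }
  p <- switch(config$outcome_link,
              logistic = stats::plogis(stats::qlogis(config$baseline_p) + eta),
              linear_probability = pmin(pmax(config$baseline_p + eta, 0), 1))
  non_neoplastic <- stats::runif(n) < p
  alive <- non_neoplastic & (stats::runif(n) < config$censor_prob)
  rec$outcome <- ifelse(!non_neoplastic, "died_neoplasia",
                        ifelse(alive, "alive", "died_other"))

  set.seed(stage_seed(config$seed, "survival"))
  treated <- !(rec$treatment %in% c("no_treatment", "unknown_treatment"))
  grp <- ifelse(rec$outcome == "died_other", "nonneoplastic",
                ifelse(treated, "treated", "untreated"))
  mu <- mapply(function(m, g) config$survival_means_months[[m]][[g]],
               rec$malignancy, grp)
  surv <- round(stats::rexp(n, rate = 1 / mu), 2)
  surv[alive] <- round(stats::rexp(sum(alive),
                                   rate = 1 / config$censor_mean_months), 2)
  rec$survival_months <- surv

  asCohort(rec[, schemaFields()])
}

#' Replace field values with unknown at given rates
#'
#' Missingness is injected independently per field at the configured rate.
#' Categorical fields are set to the unknown level, numeric fields to NA;
#' for the outcome field, death records are degraded to
#' `died_unknown_cause` (the cause, not the death, becomes unknown).
#'
#' @param cohort a `lizard_cohort`.
#' @param rates named numeric vector of rates in `[0, 1]`, names are
#'   schema fields.
#' @param seed integer seed.
#' @return A new `lizard_cohort`.
#' @export
injectMissingness <- function(cohort, rates, seed = 1L) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  bad <- setdiff(names(rates), schemaFields())
  if (length(bad) > 0) stop("unknown fields: ", paste(bad, collapse = ", "))
  r <- cohort$records
  set.seed(stage_seed(seed, "missingness"))
  for (f in names(rates)) {
    hit <- stats::runif(nrow(r)) < rates[[f]]
    if (f %in% c("age_months", "survival_months")) {
      r[[f]][hit] <- NA_real_
    } else if (f == "outcome") {
      deg <- hit & r$outcome %in% c("died_neoplasia", "died_other")
      r$outcome[deg] <- "died_unknown_cause"
      r$outcome[hit & r$outcome == "alive"] <- "unknown"
    } else if (f == "treatment") {
      r$treatment[hit] <- "unknown_treatment"
    } else {
      r[[f]][hit] <- "unknown"
    }
  }
  asCohort(r)
}
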