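#' sauronc: boosting and survival analysis of neoplasia outcomes in lizards
#'
#' Harmonized case records for retrospective lizard oncology cohorts,
#' a synthetic-cohort generator, componentwise L2 boosting over categorical
#' predictors with ridge-penalized base-learners, permutation-calibrated
#' per-level significance, Kaplan-Meier survival contrasts, and descriptive
#' summaries.
#'
#' @keywords internal
"_PACKAGE"

## ---- schema constants -----------------------------------------------------

#' Case-record schema field names
#'
#' The column names of a harmonized case-record table, in canonical order.
#' One row per lizard; empty cells mean unknown.
#'
#' @return Character vector of field names.
#' @export
schemaFields <- function() {
  c("record_id", "source", "species_common", "species_scientific",
    "age_months", "life_stage", "sex", "diagnosis", "malignancy",
    "metastasis", "tumor_location", "treatment", "outcome",
    "survival_months")
}

#' Controlled vocabularies for the closed categorical fields
#'
#' @return Named list of character vectors, one per closed field.
#' @export
schemaVocabularies <- function() {
  list(
    source = c("literature", "escra"),
    life_stage = c("adult", "juvenile", "unknown"),
    sex = c("male", "female", "unknown"),
    malignancy = c("benign", "malignant", "undetermined"),
    metastasis = c("present", "absent", "unknown"),
    treatment = treatmentCategories(),
    outcome = c("died_neoplasia", "died_other", "died_unknown_cause",
                "alive", "unknown")
  )
}

#' Treatment categories
#'
#' Union of the literature-review categories and the clinical-registry
#' (ESCRA) submission-form categories.
#'
#' @return Character vector of treatment category labels.
#' @export
treatmentCategories <- function() {
  c("surgery_only", "chemotherapy_only", "radiation_only",
    "surgery_and_chemotherapy", "surgery_and_radiation",
    "surgery_radiation_and_chemotherapy", "supportive_care",
    "unknown_treatment", "no_treatment")
}

#' The eight modeled predictor variables
#'
#' Species, sex, life stage, primary histologic diagnosis, malignancy,
#' metastasis status, tumor location, and treatment category. Age is
#' summarized descriptively, never boosted.
#'
#' @return Character vector of schema field names.
#' @export
modelVariables <- function() {
  c("species_scientific", "sex", "life_stage", "diagnosis",
    "malignancy", "metastasis", "tumor_location", "treatment")
}

# Tokens normalized to the unknown level (case-insensitive).
unknown_tokens <- c("", "na", "n/a", "unknown", "unk", "?")

#' Normalize unknown tokens in a character vector
#'
#' Empty cells, "NA", "unknown" (case-insensitive) and similar placeholders
#' collapse to the literal level `"unknown"`; unknown is a first-class
#' modeled category throughout the package.
#'
#' @param x character vector.
#' @return character vector with placeholders replaced by `"unknown"`.
#' @export
normalizeUnknown <- function(x) {
  x <- as.character(x)
  x[is.na(x) | tolower(trimws(x)) %in% unknown_tokens] <- "unknown"
  trimws(x)
}

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## ---- malignancy classification --------------------------------------------

#' Classify a neoplasm as benign, malignant or undetermined
#'
#' Hematopoietic diagnoses (lymphoma, leukemia and their synonyms) are
#' categorically malignant regardless of the reported behavior. A clearly
#' reported behavior passes through. When the reported behavior is
#' ambiguous, observed metastatic disease or local invasion with tissue
#' destruction makes the case malignant; otherwise it is undetermined.
#'
#' @param diagnosis non-empty diagnosis string.
#' @param reported_behavior one of `"benign"`, `"malignant"`, `"ambiguous"`.
#' @param metastasis_observed logical; distal (metastatic) disease observed.
#' @param local_invasion logical; local invasion with tissue destruction.
#' @param hematopoietic_synonyms character vector of case-insensitive
#'   substrings that force the malignant class.
#' @return `"benign"`, `"malignant"` or `"undetermined"`.
#' @examples
#' classifyMalignancy("leukemia", "ambiguous", FALSE, FALSE)
#' classifyMalignancy("carcinoma NOS", "ambiguous", TRUE, FALSE)
#' @export
classifyMalignancy <- function(diagnosis, reported_behavior,
                               metastasis_observed = FALSE,
                               local_invasion = FALSE,
                               hematopoietic_synonyms = c(
                                 "lymphoma", "leukemia", "leukaemia",
                                 "lymphosarcoma")) {
  stopifnot(is.character(diagnosis), nzchar(diagnosis))
  reported_behavior <- match.arg(reported_behavior,
                                 c("benign", "malignant", "ambiguous"))
  if (any(vapply(tolower(hematopoietic_synonyms),
                 function(s) grepl(s, tolower(diagnosis), fixed = TRUE),
                 logical(1)))) {
    return("malignant")
  }
  if (reported_behavior != "ambiguous") return(reported_behavior)
  if (isTRUE(metastasis_observed) || isTRUE(local_invasion)) "malignant"
  else "undetermined"
}

## ---- treatment categorization ----------------------------------------------

# modality token -> component {surgery, chemotherapy, radiation, supportive,
# none, unknown}; the synonym table is the module's configuration surface.
default_modality_table <- function() {
  c(
    "surgery" = "surgery", "surgical excision" = "surgery",
    "complete excision" = "surgery", "marginal excision" = "surgery",
    "excision" = "surgery", "cryosurgery" = "surgery",
    "cryotherapy" = "surgery", "amputation" = "surgery",
    "chemotherapy" = "chemotherapy",
    "electrochemotherapy" = "chemotherapy",
    "steroid" = "chemotherapy", "steroids" = "chemotherapy",
    "steroid therapy" = "chemotherapy", "nsaid" = "chemotherapy",
    "nsaids" = "chemotherapy",
    "radiation" = "radiation", "radiation therapy" = "radiation",
    "external beam" = "radiation", "strontium" = "radiation",
    "photoradiation" = "radiation", "phototherapy" = "radiation",
    "supportive care" = "supportive", "antibiotics" = "supportive",
    "topical antibiotics" = "supportive", "systemic antibiotics" = "supportive",
    "fine needle aspirate" = "none", "fine needle aspirates" = "none",
    "incision biopsy" = "none", "incisional biopsy" = "none",
    "biopsy" = "none", "none" = "none", "no treatment" = "none",
    "unknown" = "unknown"
  )
}

#' Map raw treatment modalities to a treatment category
#'
#' Diagnostic sampling alone (fine needle aspirates, incision biopsies) is
#' not a treatment and maps to `no_treatment`. Electrochemotherapy, steroids
#' and NSAIDs count as chemotherapy; photoradiation and phototherapy as
#' radiation; cryosurgery and cryotherapy as surgery. Combinations map to
#' the corresponding combined category.
#'
#' @param raw_modalities character vector (treated as a set) of modality
#'   descriptions as recorded at the source.
#' @param source `"literature"` or `"escra"`; kept for provenance (the
#'   synonym table covers both dialects).
#' @param modality_table named character vector mapping lowercase modality
#'   tokens to components.
#' @return A [treatmentCategories()] label.
#' @examples
#' categorizeTreatment("cryotherapy", "escra")
#' categorizeTreatment(c("surgery", "radiation therapy"), "literature")
#' @export
categorizeTreatment <- function(raw_modalities, source = "literature",
                                modality_table = default_modality_table()) {
  source <- match.arg(source, c("literature", "escra"))
  if (length(raw_modalities) == 0) return("no_treatment")
  tokens <- tolower(trimws(as.character(raw_modalities)))
  miss <- setdiff(tokens, names(modality_table))
  if (length(miss) > 0) {
    stop("unmapped modality: ", paste(miss, collapse = ", "))
  }
  comp <- unique(unname(modality_table[tokens]))
  if (identical(comp, "unknown")) return("unknown_treatment")
  comp <- setdiff(comp, c("none", "unknown"))
  if (length(comp) == 0) return("no_treatment")
  surg <- "surgery" %in% comp
  chem <- "chemotherapy" %in% comp
  rad <- "radiation" %in% comp
  if (surg && chem && rad) return("surgery_radiation_and_chemotherapy")
  if (surg && chem) return("surgery_and_chemotherapy")
  if (surg && rad) return("surgery_and_radiation")
  if (surg) return("surgery_only")
  if (chem && rad) return("surgery_radiation_and_chemotherapy") # not attested; closest combined class
  if (chem) return("chemotherapy_only")
  if (rad) return("radiation_only")
  "supportive_care"
}

## ---- outcome coding ---------------------------------------------------------

#' Encode a case outcome for boosting
#'
#' Binary coding follows the effect-table convention: y = 1 is the
#' non-neoplastic outcome (alive, or death from a cause other than the
#' identified neoplasm) and y = 0 is death or euthanasia due to the
#' neoplasm, so positive effects read as association with the
#' non-neoplastic outcome. Deaths of unknown cause are grouped with the
#' non-neoplastic class by default (they are not deaths due to the
#' identified neoplasm) and can instead be excluded. Records with a fully
#' unknown outcome are never modeled.
#'
#' @param outcome character vector of schema outcome values.
#' @param unknown_death `"nonneoplastic"` (default) codes
#'   `died_unknown_cause` as y = 1; `"exclude"` drops those records from
#'   modeling.
#' @param positive_class `"non_neoplastic"` (default, effect-table
#'   convention) or `"neoplasia_death"` to flip the coding.
#' @return data.frame with columns `y` (0/1, NA when excluded) and
#'   `included` (logical).
#' @examples
#' encodeOutcome(c("died_neoplasia", "alive", "unknown"))
#' @export
encodeOutcome <- function(outcome,
                          unknown_death = c("nonneoplastic", "exclude"),
                          positive_class = c("non_neoplastic",
                                             "neoplasia_death")) {
  unknown_death <- match.arg(unknown_death)
  positive_class <- match.arg(positive_class)
  outcome <- as.character(outcome)
  bad <- setdiff(outcome, schemaVocabularies()$outcome)
  if (length(bad) > 0) stop("unknown outcome value: ",
                            paste(unique(bad), collapse = ", "))
  y <- rep(NA_real_, length(outcome))
  y[outcome == "died_neoplasia"] <- 0
  y[outcome %in% c("alive", "died_other")] <- 1
  y[outcome == "died_unknown_cause"] <-
    if (unknown_death == "nonneoplastic") 1 else NA_real_
  if (positive_class == "neoplasia_death") y <- 1 - y
  data.frame(y = y, included = !is.na(y))
}
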