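# Builds inst/extdata/printed_cohort_synthetic.csv: a synthetic 274-record
# case table whose marginal counts reproduce the published frequency tables
# and running-text aggregates (species, sex, life stage, diagnosis,
# malignancy, metastasis, tumor location, treatment, outcome, survival and
# age summaries). Rows are synthetic: the real per-animal records are
# restricted, so only the printed aggregates are reconstructed. Where the
# published tables disagree internally, the running text wins; every such
# case is recorded in inst/extdata/discrepancy_log.json.
#
# Run from the package root: Rscript data-raw/make_fixture.R

rep_levels <- function(counts) rep(names(counts), times = counts)

stopifnot_file <- function(p) stopifnot(dir.exists(dirname(p)))

## ---- literature arm (n = 219) ----------------------------------------------

n_lit <- 219
lit_species_listed <- c(
  "Iguana iguana" = 55, "Pogona vitticeps" = 32,
  "Varanus exanthematicus" = 10, "Uromastyx acanthinura" = 10,
  "Chamaeleo calyptratus" = 8, "Heloderma suspectum" = 5,
  "Eublepharis macularius" = 5, "Lacerta viridis" = 4,
  "Varanus komodoensis" = 3, "Varanus acanthurus" = 3,
  "Heloderma exasperatum" = 2, "Eumeces laticeps" = 2,
  "Shinisaurus crocodilurus" = 2, "Cnemidophorus uniparens" = 2,
  "Hydrosaurus amboinensis" = 2, "Anolis carolinensis" = 2,
  "Heloderma horridum" = 2, "Furcifer pardalis" = 2,
  "Leiolopisma telfairii" = 2)
# 40 unlisted literature species fill the remaining 66 records
# (26 doublets + 14 singletons), for 59 distinct species in this arm
lit_other <- sprintf("Synthetic lacertilia sp. L%02d", 1:40)
lit_other_counts <- setNames(c(rep(2L, 26), rep(1L, 14)), lit_other)
lit_species <- c(rep_levels(lit_species_listed), rep_levels(lit_other_counts))
stopifnot(length(lit_species) == n_lit,
          length(unique(lit_species)) == 59)

lit_sex <- rep_levels(c(male = 40, female = 41, unknown = 138))
lit_stage <- rep_levels(c(adult = 52, juvenile = 6, unknown = 161))
lit_diag <- rep_levels(c(
  "lymphoma" = 18, "squamous cell carcinoma" = 13, "leukemia" = 5,
  "osteosarcoma" = 5, "leiomyosarcoma" = 5, "biliary adenocarcinoma" = 6,
  "cholangiocarcinoma" = 4, "carcinoma" = 3, "gastric carcinoid" = 3,
  "granulosa cell tumor" = 3, "hepatocellular carcinoma" = 3,
  "islet cell carcinoma" = 3, "thyroid carcinoma" = 3,
  "chondrosarcoma" = 2, "colon adenocarcinoma" = 2,
  "hemangiosarcoma" = 2, "pancreatic adenocarcinoma" = 2,
  "undifferentiated sarcoma" = 2, "chromatophoroma" = 10,
  "melanophoroma" = 5, "teratoma" = 10, "fibroma" = 6, "myxoma" = 3,
  "papilloma" = 3, "fibropapilloma" = 2, "hepatoma" = 2,
  "interstitial cell adenoma" = 2, "parathyroid adenoma" = 4,
  "renal adenoma" = 2, "other neoplasm" = 86))
lit_malig <- rep_levels(c(malignant = 133, benign = 58, undetermined = 28))
lit_meta <- rep_levels(c(present = 13, absent = 50, unknown = 156))
lit_loc <- rep_levels(c(
  "liver" = 15, "skin" = 20, "gastrointestinal" = 12,
  "hematopoietic/lymphatic" = 10, "jaw" = 6, "abdominal organ" = 6,
  "skin/scales (head region)" = 6, "bone marrow" = 4, "kidney" = 4,
  "pancreas" = 4, "arm/leg" = 4, "other location" = 100, "unknown" = 28))
lit_treat <- rep_levels(c(
  surgery_only = 25, chemotherapy_only = 3, radiation_only = 2,
  surgery_and_chemotherapy = 1, no_treatment = 161,
  unknown_treatment = 27))
lit_outcome <- rep_levels(c(
  died_neoplasia = 25, alive = 25, died_unknown_cause = 11,
  died_other = 1, unknown = 157))
# 108 known survival times: min 0, max 56, mean 20.0, median 0
lit_surv <- c(rep(0, 55), rep(1, 14), 18, rep(56, 38), rep(NA, 111))
stopifnot(sum(!is.na(lit_surv)) == 108,
          isTRUE(all.equal(mean(lit_surv, na.rm = TRUE), 20.0)),
          median(lit_surv, na.rm = TRUE) == 0,
          max(lit_surv, na.rm = TRUE) == 56)
# 50 known ages on adult rows: min 5, max 300, mean 77.7, median 60
lit_age_known <- c(5, rep(30, 23), 60, 60, 130, rep(120, 22), 300)
stopifnot(length(lit_age_known) == 50,
          isTRUE(all.equal(mean(lit_age_known), 77.7)),
          median(lit_age_known) == 60)
lit_age <- c(lit_age_known, rep(NA, n_lit - 50))  # rows 1..52 are adults

lit <- data.frame(
  record_id = sprintf("LIT%03d", 1:n_lit), source = "literature",
  species_scientific = lit_species, age_months = lit_age,
  life_stage = lit_stage, sex = lit_sex, diagnosis = lit_diag,
  malignancy = lit_malig, metastasis = lit_meta, tumor_location = lit_loc,
  treatment = lit_treat, outcome = lit_outcome,
  survival_months = lit_surv, stringsAsFactors = FALSE)

## ---- ESCRA arm (n = 55) -----------------------------------------------------

n_esc <- 55
# bearded dragon count follows the running text (n = 25), not the table
# cell "21/55(45.5%)"
esc_species_listed <- c(
  "Pogona vitticeps" = 25, "Furcifer pardalis" = 4,
  "Eublepharis macularius" = 4, "Iguana iguana" = 3,
  "Chamaeleo calyptratus" = 3, "Tiliqua nigrolutea" = 2)
# 14 singletons; 9 reuse unlisted literature species so that exactly 14
# species are shared between the arms (5 listed + 9 singleton)
esc_other <- c(sprintf("Synthetic lacertilia sp. L%02d", 1:9),
               sprintf("Synthetic lacertilia sp. E%02d", 1:5))
esc_species <- c(rep_levels(esc_species_listed),
                 rep_levels(setNames(rep(1L, 14), esc_other)))
stopifnot(length(esc_species) == n_esc,
          length(unique(esc_species)) == 20)

esc_sex <- rep_levels(c(male = 26, female = 20, unknown = 9))
esc_stage <- rep_levels(c(adult = 42, unknown = 13))
esc_diag <- rep_levels(c(
  "squamous cell carcinoma" = 8, "spindle cell sarcoma" = 4,
  "leukemia" = 2, "lymphosarcoma" = 2, "myxosarcoma" = 2, "sarcoma" = 2,
  "chromatophoroma" = 2, "papilloma" = 2, "other neoplasm" = 31))
# malignancy: 40 malignant + 7 benign + remainder undetermined (the text's
# 40+7+9 = 56 overruns n = 55)
esc_malig <- rep_levels(c(malignant = 40, benign = 7, undetermined = 8))
esc_meta <- rep_levels(c(present = 5, absent = 7, unknown = 43))
esc_loc <- rep_levels(c(
  "skin" = 6, "skin/scales (head region)" = 6, "gastrointestinal" = 5,
  "other location" = 28, "unknown" = 10))
esc_treat <- rep_levels(c(
  surgery_only = 17, chemotherapy_only = 1, surgery_and_radiation = 1,
  no_treatment = 30, unknown_treatment = 6))
esc_outcome <- rep_levels(c(
  died_neoplasia = 17, died_other = 14, alive = 9,
  died_unknown_cause = 1, unknown = 14))
# 13 known survival times: min 0, max 30, mean 10.3, median 2
esc_surv <- c(0, 0, 1, 1, 2, 2, 2, 2.9, 8, 25, 30, 30, 30,
              rep(NA, n_esc - 13))
stopifnot(isTRUE(all.equal(mean(esc_surv, na.rm = TRUE), 10.3)),
          median(esc_surv, na.rm = TRUE) == 2)
# 34 known ages on adult rows: min 24, max 173, mean 81.5, median 72
esc_age_known <- c(24, rep(50, 15), 72, 72, rep(112, 15), 173)
stopifnot(length(esc_age_known) == 34,
          isTRUE(all.equal(mean(esc_age_known), 81.5)),
          median(esc_age_known) == 72)
esc_age <- c(esc_age_known, rep(NA, n_esc - 34))  # rows 1..42 are adults

esc <- data.frame(
  record_id = sprintf("ESC%03d", 1:n_esc), source = "escra",
  species_scientific = esc_species, age_months = esc_age,
  life_stage = esc_stage, sex = esc_sex, diagnosis = esc_diag,
  malignancy = esc_malig, metastasis = esc_meta, tumor_location = esc_loc,
  treatment = esc_treat, outcome = esc_outcome,
  survival_months = esc_surv, stringsAsFactors = FALSE)

## ---- assemble, normalize through the package, write -------------------------

fix <- rbind(lit, esc)
common <- c(
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
  "Anolis carolinensis" = "Green anole")
fix$species_common <- ifelse(fix$species_scientific %in% names(common),
                             common[fix$species_scientific],
                             fix$species_scientific)

pkgload::load_all(".", quiet = TRUE)
cohort <- asCohort(fix)
stopifnot(cohortSize(cohort) == 274,
          nrow(validateCohort(cohort)[
            validateCohort(cohort)$severity == "error", ]) == 0)
writeCohort(cohort, "inst/extdata/printed_cohort_synthetic.csv")

disc <- list(
  list(quantity = "ESCRA bearded dragon count",
       table_value = "21/55 (45.5%)", text_value = 25,
       resolution = "running text (n = 25) used"),
  list(quantity = "literature green iguana percent",
       table_value = "55/219 (28%)", text_value = "55/219 = 25.1%",
       resolution = "count 55 kept; percent recomputed"),
  list(quantity = "literature life-stage counts",
       table_value = "141 unknown + 52 adult + 6 juvenile = 199 of 219",
       text_value = "arm size 219",
       resolution = "printed adult/juvenile kept; remainder (161) unknown"),
  list(quantity = "ESCRA malignancy counts",
       table_value = "40 malignant + 7 benign + 9 unknown = 56 of 55",
       text_value = "arm size 55",
       resolution = "malignant 40, benign 7, undetermined 8"),
  list(quantity = "literature outcome counts",
       table_value = "available for 89; categories sum to 62",
       text_value = "25 + 25 + 11 + 1 known",
       resolution = "printed category counts kept; remainder unknown"),
  list(quantity = "distinct neoplasm count",
       table_value = "85 + 38 - 16 = 107", text_value = "108 neoplasms",
       resolution = "not a fixture quantity; noted only"))
jsonlite::write_json(disc, "inst/extdata/discrepancy_log.json",
                     pretty = TRUE, auto_unbox = TRUE)
cat("fixture written:",
    nrow(cohort$records), "records\n")
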