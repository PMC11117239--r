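test_that("malignancy classification follows the diagnostic rules", {
  # hematopoietic diagnoses are categorically malignant
  expect_equal(classifyMalignancy("leukemia", "ambiguous"), "malignant")
  expect_equal(classifyMalignancy("Cutaneous Lymphoma", "benign"),
               "malignant")
  # reported behavior passes through
  expect_equal(classifyMalignancy("fibroma", "benign"), "benign")
  expect_equal(classifyMalignancy("fibrosarcoma", "malignant"), "malignant")
  # ambiguous behavior resolved by metastasis or invasion, else undetermined
  expect_equal(classifyMalignancy("carcinoma NOS", "ambiguous",
                                  metastasis_observed = TRUE), "malignant")
  expect_equal(classifyMalignancy("mass", "ambiguous",
                                  local_invasion = TRUE), "malignant")
  expect_equal(classifyMalignancy("spindle cell proliferation",
                                  "ambiguous"), "undetermined")
  # total and deterministic under synonym-list reordering
  syn <- c("lymphoma", "leukemia", "leukaemia", "lymphosarcoma")
  for (perm in list(syn, rev(syn), syn[c(3, 1, 4, 2)])) {
    expect_equal(classifyMalignancy("leukaemia, chronic", "ambiguous",
                                    hematopoietic_synonyms = perm),
                 "malignant")
  }
})

test_that("treatment categorization maps modality sets to categories", {
  expect_equal(categorizeTreatment("cryotherapy", "escra"), "surgery_only")
  expect_equal(categorizeTreatment("electrochemotherapy", "escra"),
               "chemotherapy_only")
  expect_equal(categorizeTreatment("phototherapy", "escra"),
               "radiation_only")
  expect_equal(categorizeTreatment("fine needle aspirate", "literature"),
               "no_treatment")
  expect_equal(categorizeTreatment(c("surgery", "radiation therapy"),
                                   "literature"), "surgery_and_radiation")
  expect_equal(
    categorizeTreatment(c("surgery", "chemotherapy", "external beam"),
                        "literature"),
    "surgery_radiation_and_chemotherapy")
  expect_equal(categorizeTreatment(c("biopsy", "surgical excision"),
                                   "escra"), "surgery_only")
  expect_equal(categorizeTreatment("supportive care", "escra"),
               "supportive_care")
  expect_error(categorizeTreatment("leeches", "literature"),
               "unmapped modality.*leeches")
})

test_that("outcome coding matches the effect-table convention", {
  enc <- encodeOutcome(c("died_neoplasia", "alive", "died_other",
                         "died_unknown_cause", "unknown"))
  expect_equal(enc$y, c(0, 1, 1, 1, NA))
  expect_equal(enc$included, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # flipped convention
  flip <- encodeOutcome("died_neoplasia", positive_class = "neoplasia_death")
  expect_equal(flip$y, 1)
  # unknown-cause deaths can be excluded instead
  excl <- encodeOutcome("died_unknown_cause", unknown_death = "exclude")
  expect_false(excl$included)
  # included + excluded counts partition any cohort
  out <- sample(schemaVocabularies()$outcome, 50, replace = TRUE)
  enc <- encodeOutcome(out)
  expect_equal(sum(enc$included) + sum(!enc$included), 50)
})

test_that("cohort CSV round-trip preserves values and order", {
  co <- make_cohort(7, sex = c("male", "female", "unknown"),
                    age_months = c(10.5, NA), survival_months = c(0, 3.25),
                    outcome = c("alive", "died_neoplasia"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co, path)
  co2 <- readCohort(path)
  expect_equal(co2$records, co$records)
  # write . read . write is byte-stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("cohort reader enforces the schema contract", {
  # 0-row file with a valid header gives an empty cohort
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(schemaFields(), collapse = ","), path)
  expect_equal(cohortSize(readCohort(path)), 0)
  # missing mandatory column is a schema error naming the absentee
  df <- make_records(3)
  df$diagnosis <- NULL
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path3, row.names = FALSE)
  expect_error(readCohort(path3), "missing mandatory columns.*diagnosis")
  # duplicate record ids are an error
  expect_error(asCohort(make_records(2, record_id = "X")),
               "duplicate record_id.*X")
})

test_that("unknown placeholders normalize to one first-class level", {
  co <- make_cohort(5, sex = c("", "NA", "Unknown", "male", "unk"))
  expect_equal(co$records$sex,
               c("unknown", "unknown", "unknown", "male", "unknown"))
  # unknown is part of the observed vocabulary, not dropped
  expect_true("unknown" %in% co$vocab$sex)
})

test_that("validation reports invariant violations without mutating", {
  co <- make_cohort(4, life_stage = c("juvenile", "adult"),
                    age_months = c(48, 10), sex = c("intersex", "male"))
  before <- co$records
  rep <- validateCohort(co)
  expect_identical(co$records, before)
  # juvenile aged 48 months is a warning, not an error
  juv <- rep[rep$field == "life_stage", ]
  expect_true(all(juv$severity == "warning"))
  expect_match(juv$message[1], "48")
  # out-of-vocabulary sex value is an error
  expect_true(any(rep$field == "sex" & rep$severity == "error"))
  # a clean cohort yields an empty report
  expect_equal(nrow(validateCohort(make_cohort(3))), 0)
})
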