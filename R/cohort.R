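## Cohort container: a validated collection of harmonized case records.

#' Construct a cohort from a case-record data frame
#'
#' Normalizes unknown placeholders in the categorical fields, coerces the
#' numeric fields, checks mandatory columns and record-id uniqueness, and
#' attaches the per-field vocabularies of observed levels.
#'
#' @param records data.frame with (at least) the [schemaFields()] columns.
#' @return An object of class `lizard_cohort`: a list with elements
#'   `records` (normalized data.frame) and `vocab` (named list of observed
#'   levels per categorical field).
#' @export
asCohort <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(schemaFields(), names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, schemaFields(), drop = FALSE]
  cat_fields <- setdiff(schemaFields(),
                        c("record_id", "age_months", "survival_months"))
  for (f in cat_fields) records[[f]] <- normalizeUnknown(records[[f]])
  # the treatment vocabulary spells its unknown level explicitly
  records$treatment[records$treatment == "unknown"] <- "unknown_treatment"
  for (f in c("age_months", "survival_months")) {
    records[[f]] <- suppressWarnings(as.numeric(records[[f]]))
  }
  records$record_id <- as.character(records$record_id)
  if (anyDuplicated(records$record_id)) {
    dup <- unique(records$record_id[duplicated(records$record_id)])
    stop("duplicate record_id: ", paste(dup, collapse = ", "))
  }
  vocab <- lapply(records[cat_fields], function(x) sort(unique(x)))
  structure(list(records = records, vocab = vocab),
            class = "lizard_cohort")
}

#' Number of records in a cohort
#' @param x a `lizard_cohort`.
#' @return integer record count.
#' @export
cohortSize <- function(x) {
  stopifnot(inherits(x, "lizard_cohort"))
  nrow(x$records)
}

#' @export
print.lizard_cohort <- function(x, ...) {
  n <- nrow(x$records)
  src <- table(factor(x$records$source, c("literature", "escra")))
  cat("Lizard neoplasia cohort: ", n, " records (",
      src[["literature"]], " literature, ", src[["escra"]], " ESCRA)\n",
      sep = "")
  if (n > 0) {
    cat("  species: ", length(unique(x$records$species_scientific)),
        " | diagnoses: ", length(unique(x$records$diagnosis)), "\n", sep = "")
  }
  invisible(x)
}

#' Read a cohort from a delimited case-record file
#'
#' Comma-separated, UTF-8, quoted fields allowed; a header row naming the
#' schema fields is required and empty cells mean unknown. Reading then
#' writing a cohort reproduces the normalized form exactly.
#'
#' @param path file path.
#' @return A `lizard_cohort` with a validation report attached as
#'   attribute `"validation"` (see [validateCohort()]).
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  cohort <- asCohort(df)
  attr(cohort, "validation") <- validateCohort(cohort)
  cohort
}

#' Write a cohort to a delimited case-record file
#'
#' @param cohort a `lizard_cohort`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  out <- cohort$records
  for (f in c("age_months", "survival_months")) {
    v <- out[[f]]
    out[[f]] <- ifelse(is.na(v), "", format(v, trim = TRUE,
                                            scientific = FALSE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Validate a cohort against the record invariants
#'
#' Pure check: flags duplicate ids (when constructed by other means),
#' out-of-vocabulary values in the closed fields, negative ages or survival
#' times, juveniles with a known age of three months or more (a warning,
#' not an error), and tallies unknown-cause deaths (their outcome coding is
#' a configuration choice). Never mutates the cohort.
#'
#' @param cohort a `lizard_cohort`.
#' @return data.frame with columns `record_id`, `field`, `severity`
#'   (`"error"`/`"warning"`), `message`; zero rows when clean. Per-field
#'   vocabulary summaries are attached as attribute `"vocabulary"`.
#' @export
validateCohort <- function(cohort) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  r <- cohort$records
  issues <- list()
  add <- function(id, field, severity, message) {
    issues[[length(issues) + 1L]] <<-
      data.frame(record_id = id, field = field, severity = severity,
                 message = message, stringsAsFactors = FALSE)
  }
  dup <- r$record_id[duplicated(r$record_id)]
  for (id in unique(dup)) add(id, "record_id", "error", "duplicate record_id")
  closed <- schemaVocabularies()
  for (f in names(closed)) {
    bad <- !(r[[f]] %in% closed[[f]])
    for (i in which(bad)) {
      add(r$record_id[i], f, "error",
          paste0("value '", r[[f]][i], "' not in vocabulary"))
    }
  }
  for (f in c("age_months", "survival_months")) {
    neg <- which(!is.na(r[[f]]) & r[[f]] < 0)
    for (i in neg) add(r$record_id[i], f, "error", "negative value")
  }
  juv <- which(r$life_stage == "juvenile" & !is.na(r$age_months) &
                 r$age_months >= 3)
  for (i in juv) {
    add(r$record_id[i], "life_stage", "warning",
        paste0("juvenile with age ", r$age_months[i],
               " months (juvenile is defined as < 3 months)"))
  }
  unk_death <- which(r$outcome == "died_unknown_cause")
  for (i in unk_death) {
    add(r$record_id[i], "outcome", "warning",
        "death of unknown cause: coded non-neoplastic by default")
  }
  out <- if (length(issues) > 0) do.call(rbind, issues) else
    data.frame(record_id = character(), field = character(),
               severity = character(), message = character(),
               stringsAsFactors = FALSE)
  attr(out, "vocabulary") <- cohort$vocab
  out
}

#' Export the observed vocabularies as JSON
#'
#' @param cohort a `lizard_cohort`.
#' @param path file path for the JSON document.
#' @return `path`, invisibly.
#' @export
writeVocabularies <- function(cohort, path) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  jsonlite::write_json(cohort$vocab, path, pretty = TRUE)
  invisible(path)
}
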