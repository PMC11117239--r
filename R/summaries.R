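## Descriptive cohort summaries: frequency tables, species-union
## accounting, metastasis prevalence, survival-time statistics, and the
## pursued/not-pursued treatment split.

# percents are reported half-up to one decimal, as printed summary tables
# conventionally round
percent1 <- function(count, denom) round_half_up(100 * count / denom, 1)

#' Level frequency table for a cohort field
#'
#' Counts per observed level with the per-(source-)cohort size as
#' denominator and percents rounded half-up to one decimal.
#'
#' @param cohort a `lizard_cohort`.
#' @param field a schema field name.
#' @param by_source split into one table per source?
#' @return data.frame with columns `level`, `count`, `denominator`,
#'   `percent` (and `source` when split).
#' @export
frequencyTable <- function(cohort, field, by_source = FALSE) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  if (!field %in% schemaFields()) stop("unknown field: ", field)
  one <- function(records, src = NULL) {
    denom <- nrow(records)
    if (denom == 0) {
      out <- data.frame(level = character(0), count = integer(0),
                        denominator = integer(0), percent = numeric(0),
                        stringsAsFactors = FALSE)
      if (!is.null(src)) out <- cbind(source = character(0), out)
      return(out)
    }
    tab <- table(records[[field]])
    out <- data.frame(level = names(tab), count = as.integer(tab),
                      denominator = denom,
                      percent = percent1(as.integer(tab), denom),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$level), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(src)) out <- cbind(source = src, out,
                                    stringsAsFactors = FALSE)
    out
  }
  if (!by_source) return(one(cohort$records))
  parts <- lapply(c("literature", "escra"), function(src) {
    one(cohort$records[cohort$records$source == src, , drop = FALSE], src)
  })
  do.call(rbind, parts)
}

#' Species accounting across the two sources
#'
#' Distinct scientific names per source and their overlap; the union obeys
#' inclusion-exclusion (asserted).
#'
#' @param cohort a `lizard_cohort`.
#' @return Named list: `n_total_unique`, `n_literature`, `n_escra`,
#'   `n_shared`.
#' @export
combinedSpeciesCount <- function(cohort) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  r <- cohort$records
  lit <- unique(r$species_scientific[r$source == "literature"])
  esc <- unique(r$species_scientific[r$source == "escra"])
  out <- list(n_total_unique = length(union(lit, esc)),
              n_literature = length(lit), n_escra = length(esc),
              n_shared = length(intersect(lit, esc)))
  stopifnot(out$n_total_unique ==
              out$n_literature + out$n_escra - out$n_shared)
  out
}

#' Metastasis prevalence over the full cohort
#'
#' @param cohort a `lizard_cohort`.
#' @return Named list: `percent_present` and `percent_absent` to one
#'   decimal, `percent_unknown` rounded to a whole percent (the headline
#'   figure convention), plus raw counts.
#' @export
metastasisSummary <- function(cohort) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  m <- cohort$records$metastasis
  n <- length(m)
  list(percent_present = percent1(sum(m == "present"), n),
       percent_absent = percent1(sum(m == "absent"), n),
       percent_unknown = round_half_up(100 * sum(m == "unknown") / n),
       n_present = sum(m == "present"), n_absent = sum(m == "absent"),
       n_unknown = sum(m == "unknown"), n = n)
}

#' Survival-time summary over records with a known time
#'
#' @param cohort a `lizard_cohort`.
#' @param by_source split by source?
#' @return data.frame with columns `source` (`"combined"` when not
#'   split), `n_known`, `min`, `max`, `mean`, `median`; statistics are NA
#'   when no time is known.
#' @export
survivalTimeSummary <- function(cohort, by_source = FALSE) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  one <- function(records, src) {
    t <- records$survival_months
    t <- t[!is.na(t)]
    if (length(t) == 0) {
      return(data.frame(source = src, n_known = 0L, min = NA_real_,
                        max = NA_real_, mean = NA_real_,
                        median = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(source = src, n_known = length(t), min = min(t),
               max = max(t), mean = round_half_up(mean(t), 1),
               median = stats::median(t), stringsAsFactors = FALSE)
  }
  if (!by_source) return(one(cohort$records, "combined"))
  do.call(rbind, lapply(c("literature", "escra"), function(src) {
    one(cohort$records[cohort$records$source == src, , drop = FALSE], src)
  }))
}

#' Treatment frequency table with the pursued / not-pursued split
#'
#' Treatment counts as pursued for any category except `no_treatment` and
#' `unknown_treatment`.
#'
#' @param cohort a `lizard_cohort`.
#' @param by_source split by source?
#' @return The treatment [frequencyTable()] with attribute `"pursuit"`: a
#'   data.frame of `source`, `pursued`, `not_pursued`, `unknown`.
#' @export
treatmentSummary <- function(cohort, by_source = FALSE) {
  tab <- frequencyTable(cohort, "treatment", by_source = by_source)
  split_one <- function(records, src) {
    tr <- records$treatment
    data.frame(source = src,
               pursued = sum(!tr %in% c("no_treatment", "unknown_treatment")),
               not_pursued = sum(tr == "no_treatment"),
               unknown = sum(tr == "unknown_treatment"),
               stringsAsFactors = FALSE)
  }
  pursuit <- if (by_source) {
    do.call(rbind, lapply(c("literature", "escra"), function(src) {
      split_one(cohort$records[cohort$records$source == src, ,
                               drop = FALSE], src)
    }))
  } else split_one(cohort$records, "combined")
  attr(tab, "pursuit") <- pursuit
  tab
}
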