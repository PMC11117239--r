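## Simulation studies for the inference machinery: type-I-error
## calibration under a global null, power and direction recovery for an
## injected effect, and the qualitative ordering of survival curves under
## the default generator.

# derived replicate seed, kept inside the 32-bit integer range
substream <- function(seed, stream, r) {
  as.integer((as.numeric(seed) * 97 + stream * 1e6 + r) %% 2147483647)
}

#' False-positive rate of the permutation test under a global null
#'
#' Generates cohorts in which no predictor moves the outcome, runs the
#' boosting + permutation pipeline on each, and reports the fraction of
#' significance-eligible levels (sample size >= `min_n`) flagged at
#' `alpha`. With a well-calibrated test the mean rate approaches `alpha`.
#'
#' @param n_replicates number of simulated cohorts.
#' @param n_records cohort size per replicate.
#' @param B permutations per replicate.
#' @param alpha significance threshold.
#' @param hyperparams boosting settings.
#' @param seed root seed; each replicate derives two fixed substream
#'   seeds from it (cohort generation and permutations).
#' @return List: `rates` (per-replicate false-positive rates), `mean_rate`.
#' @export
calibrationStudy <- function(n_replicates = 100, n_records = 274,
                             B = 500L, alpha = 0.05,
                             hyperparams = boostHyperparams(),
                             seed = 1L) {
  rates <- vapply(seq_len(n_replicates), function(r) {
    cfg <- syntheticConfig(n_records = n_records, true_effects = list(),
                           baseline_p = 0.5, seed = substream(seed, 1, r))
    cohort <- generateCohort(cfg)
    y <- encodeOutcome(cohort$records$outcome)$y
    blocks <- buildDesign(cohort)
    fit <- fitBoost(blocks, y, hyperparams)
    effects <- extractEffects(fit, blocks)
    nulls <- nullDistributions(blocks, y, B = B,
                               hyperparams = hyperparams,
                               seed = substream(seed, 2, r))
    sig <- significanceTable(effects, nulls, alpha = alpha, min_n = 2)
    eligible <- sig$n >= 2
    sum(sig$significant) / sum(eligible)
  }, numeric(1))
  list(rates = rates, mean_rate = mean(rates))
}

#' Power and direction recovery for one injected effect
#'
#' Injects a probability-scale effect on one predictor level (default:
#' +0.3 on benign malignancy, pushing its non-neoplastic outcome
#' probability from 0.5 to 0.8) and measures how often the permutation
#' test flags that level with the correct direction.
#'
#' @param n_replicates number of simulated cohorts.
#' @param n_records cohort size per replicate.
#' @param B permutations per replicate.
#' @param variable,level where the effect is injected.
#' @param effect probability-scale effect size.
#' @param alpha significance threshold.
#' @param hyperparams boosting settings.
#' @param seed root seed (same substream scheme as [calibrationStudy()]).
#' @return List: `detected` (logical per replicate: significant with the
#'   injected direction), `detection_rate`, `level_sizes`.
#' @export
powerStudy <- function(n_replicates = 50, n_records = 300, B = 500L,
                       variable = "malignancy", level = "benign",
                       effect = 0.3, alpha = 0.05,
                       hyperparams = boostHyperparams(), seed = 1L) {
  eff_list <- list(stats::setNames(effect, level))
  names(eff_list) <- variable
  hits <- logical(n_replicates)
  sizes <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- syntheticConfig(n_records = n_records, baseline_p = 0.5,
                           true_effects = eff_list,
                           outcome_link = "linear_probability",
                           seed = substream(seed, 1, r))
    cohort <- generateCohort(cfg)
    y <- encodeOutcome(cohort$records$outcome)$y
    blocks <- buildDesign(cohort)
    fit <- fitBoost(blocks, y, hyperparams)
    effects <- extractEffects(fit, blocks)
    nulls <- nullDistributions(blocks, y, B = B,
                               hyperparams = hyperparams,
                               seed = substream(seed, 2, r))
    sig <- significanceTable(effects, nulls, alpha = alpha, min_n = 2)
    row <- sig[sig$variable == variable & sig$level == level, ]
    sizes[r] <- row$n
    hits[r] <- row$significant &&
      row$direction == (if (effect > 0) "non_neoplastic" else
        "neoplasia_death")
  }
  list(detected = hits, detection_rate = mean(hits), level_sizes = sizes)
}

#' Ordering of untreated versus treated malignant survival curves
#'
#' Under the default generator, untreated malignant cases have shorter
#' event times than treated ones; this study measures, over replicates,
#' how often the untreated curve lies below the treated curve at the
#' pooled median survival time of the two groups.
#'
#' @param n_replicates number of simulated cohorts.
#' @param n_records cohort size per replicate.
#' @param seed root seed.
#' @return List: `below` (logical per replicate), `fraction_below`.
#' @export
kmOrderingStudy <- function(n_replicates = 50, n_records = 274,
                            seed = 1L) {
  below <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cohort <- generateCohort(syntheticConfig(n_records = n_records,
                                             seed = substream(seed, 1, r)))
    rec <- cohort$records
    grp <- groupSurvival(cohort)
    untr <- grp[["malignant.neoplasia_no_treatment"]]
    trt <- grp[["malignant.neoplasia_with_treatment"]]
    if (is.null(untr) || is.null(trt)) {
      below[r] <- NA
      next
    }
    pool <- rec$malignancy == "malignant" &
      rec$outcome %in% c("died_neoplasia", "alive") &
      !is.na(rec$survival_months)
    pooled <- kmEstimate(rec$survival_months[pool],
                         rec$outcome[pool] != "alive")
    t_star <- medianSurvival(pooled)
    if (is.na(t_star)) {
      below[r] <- NA
      next
    }
    below[r] <- survivalAt(untr, t_star) < survivalAt(trt, t_star)
  }
  list(below = below, fraction_below = mean(below, na.rm = TRUE))
}
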