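## Permutation-calibrated significance of boosted per-level effects.
##
## The null distribution of each level's effect is built by refitting the
## boosting model on uniformly permuted outcomes (the design stays fixed),
## and the observed effect is placed in the two-sided tail of its own null.

#' Uniformly permute an outcome vector
#'
#' @param y numeric vector (nonempty).
#' @return `y` in uniformly random order (the multiset is preserved).
#' @export
permuteOutcomes <- function(y) {
  if (length(y) == 0) stop("y must be nonempty")
  y[sample.int(length(y))]
}

#' Per-level null effect distributions from permuted outcomes
#'
#' Fits the boosting model `B` times, each on an independent uniform
#' permutation of `y` with identical hyperparameters, and collects every
#' level's effect from every refit. Reproducible given `seed`. All
#' permutations are fitted as columns of one residual matrix, which is
#' algebraically identical to refitting one by one.
#'
#' @param blocks design blocks from [buildDesign()].
#' @param y numeric 0/1 outcomes.
#' @param B number of permutations (>= 0; the study default is 2000).
#' @param hyperparams a [boostHyperparams()] object.
#' @param seed integer seed.
#' @return A `null_distributions` object: list with `null_effects` (a
#'   data.frame of `variable`, `level`, `n` plus a B-column matrix in
#'   attribute rows) — concretely, elements `levels` (data.frame
#'   variable/level/n) and `effects` (matrix, one row per level, one
#'   column per permutation), plus `B` and `hyperparams`.
#' @export
nullDistributions <- function(blocks, y, B = 2000L,
                              hyperparams = boostHyperparams(),
                              seed = 1L) {
  if (B < 0) stop("B must be >= 0")
  n <- length(blocks[[1]]$index)
  stopifnot(length(y) == n)
  set.seed(as.integer(seed))
  lev <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(variable = b$variable, level = b$levels,
               n = block_counts(b), stringsAsFactors = FALSE)
  }))
  if (B == 0) {
    eff <- matrix(numeric(0), nrow = nrow(lev), ncol = 0)
  } else {
    Y <- vapply(seq_len(B), function(b) permuteOutcomes(as.numeric(y)),
                numeric(n))
    fit <- boost_core(blocks, Y, hyperparams)
    eff <- do.call(rbind, fit$coefficients)
  }
  structure(list(levels = lev, effects = eff, B = as.integer(B),
                 hyperparams = hyperparams),
            class = "null_distributions")
}

#' Two-sided permutation significance of per-level effects
#'
#' For each level the p-value is the finite-sample-corrected two-sided
#' tail position `(1 + #\{b : |null_b| >= |observed|\}) / (B + 1)`; with
#' `tail_rule = "percentile"` a level is instead called significant when
#' its observed effect falls outside the central `1 - alpha` percentile
#' interval of its null (the p-value reported is then the smaller
#' one-sided percentile position doubled, capped at 1). Significance is
#' only awarded to levels with at least `min_n` individuals; smaller
#' levels are reported with significance suppressed.
#'
#' @param effects effect table from [extractEffects()].
#' @param nulls a [nullDistributions()] object over the same levels.
#' @param alpha significance threshold (default 0.05).
#' @param min_n minimum level sample size for a significance call
#'   (default 2).
#' @param tail_rule `"absolute"` (default; |effect| tail comparison) or
#'   `"percentile"`.
#' @return data.frame with columns `variable`, `level`, `n`, `effect`,
#'   `p_value`, `significant`, `direction` (`"neoplasia_death"` for
#'   negative effects, `"non_neoplastic"` otherwise).
#' @export
significanceTable <- function(effects, nulls, alpha = 0.05, min_n = 2L,
                              tail_rule = c("absolute", "percentile")) {
  tail_rule <- match.arg(tail_rule)
  stopifnot(inherits(nulls, "null_distributions"))
  if (nulls$B == 0) stop("B = 0: no null distribution to compare against")
  key_e <- paste(effects$variable, effects$level, sep = "\r")
  key_n <- paste(nulls$levels$variable, nulls$levels$level, sep = "\r")
  if (!setequal(key_e, key_n)) {
    stop("effects and null distributions cover different levels")
  }
  idx <- match(key_e, key_n)
  B <- nulls$B
  p <- numeric(nrow(effects))
  sig <- logical(nrow(effects))
  for (i in seq_len(nrow(effects))) {
    null_i <- nulls$effects[idx[i], ]
    obs <- effects$effect[i]
    if (tail_rule == "absolute") {
      p[i] <- (1 + sum(abs(null_i) >= abs(obs))) / (B + 1)
      sig[i] <- p[i] < alpha
    } else {
      lo <- stats::quantile(null_i, alpha / 2, type = 1)
      hi <- stats::quantile(null_i, 1 - alpha / 2, type = 1)
      p_lo <- (1 + sum(null_i <= obs)) / (B + 1)
      p_hi <- (1 + sum(null_i >= obs)) / (B + 1)
      p[i] <- min(1, 2 * min(p_lo, p_hi))
      sig[i] <- obs < lo || obs > hi
    }
  }
  eligible <- effects$n >= min_n
  data.frame(variable = effects$variable, level = effects$level,
             n = effects$n, effect = effects$effect,
             p_value = p, significant = sig & eligible,
             direction = ifelse(effects$effect < 0, "neoplasia_death",
                                "non_neoplastic"),
             stringsAsFactors = FALSE)
}
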