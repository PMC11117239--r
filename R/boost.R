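## Componentwise L2 gradient boosting over categorical predictors.
##
## Each predictor is one base-learner: a ridge-penalized least-squares fit
## on its one-hot indicator block ("random-effects" style), with the ridge
## penalty chosen per block so that every base-learner has the same
## effective degrees of freedom. At each iteration the block that best fits
## the current residuals is selected and a shrunken update is added.
##
## Because the levels of one variable are mutually exclusive, Z'Z is
## diagonal (the level sample sizes), which gives closed-form base-learner
## fits and lets the permutation engine fit all permuted outcomes at once
## as matrix columns.

#' Boosting hyperparameters
#'
#' @param mstop number of boosting iterations (>= 0).
#' @param nu step length in (0, 1].
#' @param df target effective degrees of freedom per base-learner; blocks
#'   with fewer levels than `df` are fitted unpenalized.
#' @return A `boost_hyperparams` list.
#' @export
boostHyperparams <- function(mstop = 100L, nu = 0.1, df = 4) {
  if (mstop < 0) stop("mstop must be >= 0")
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]")
  if (df <= 0) stop("df must be positive")
  structure(list(mstop = as.integer(mstop), nu = nu, df = df),
            class = "boost_hyperparams")
}

#' Build one-hot design blocks for categorical variables
#'
#' One block per variable; levels are the lexicographically sorted observed
#' values (unknown included as an ordinary level). Every record carries
#' exactly one level per variable, so each indicator row sums to 1 and the
#' column sums are the level sample sizes.
#'
#' @param cohort a `lizard_cohort`.
#' @param variables ordered character vector of schema field names
#'   (default: the eight modeled predictors, [modelVariables()]).
#' @return List of `design_block` objects with elements `variable`,
#'   `levels`, `index` (level index per record) and `n_levels`; the
#'   indicator matrix is materialized on demand by [blockMatrix()].
#' @export
buildDesign <- function(cohort, variables = modelVariables()) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  bad <- setdiff(variables, schemaFields())
  if (length(bad) > 0) stop("unknown variable: ", paste(bad, collapse = ", "))
  lapply(variables, function(v) {
    x <- cohort$records[[v]]
    levs <- sort(unique(x))
    structure(list(variable = v, levels = levs,
                   index = match(x, levs), n_levels = length(levs)),
              class = "design_block")
  })
}

#' Dense indicator matrix of a design block
#' @param block a `design_block`.
#' @return n x n_levels 0/1 matrix with level labels as column names.
#' @export
blockMatrix <- function(block) {
  stopifnot(inherits(block, "design_block"))
  Z <- matrix(0, length(block$index), block$n_levels,
              dimnames = list(NULL, block$levels))
  Z[cbind(seq_along(block$index), block$index)] <- 1
  Z
}

# level sample sizes (column sums of the indicator matrix)
block_counts <- function(block) {
  tabulate(block$index, nbins = block$n_levels)
}

#' Ridge penalty giving a target effective degrees of freedom
#'
#' Solves trace(Z (Z'Z + lambda I)^-1 Z') = df for lambda >= 0 by
#' bisection on the spectrum of Z'Z; for a one-hot block the spectrum is
#' the vector of level sample sizes. `df` equal to the block rank gives
#' lambda = 0.
#'
#' @param block a `design_block`.
#' @param df target degrees of freedom, 0 < df <= rank(Z).
#' @param tol bisection tolerance on the achieved trace.
#' @return lambda >= 0.
#' @export
ridgeLambdaForDf <- function(block, df, tol = 1e-11) {
  counts <- block_counts(block)
  d2 <- counts[counts > 0]  # eigenvalues of Z'Z
  rank <- length(d2)
  if (df > rank + 1e-12) stop("df (", df, ") exceeds block rank (", rank, ")")
  if (abs(df - rank) <= 1e-12) return(0)
  tr <- function(lambda) sum(d2 / (d2 + lambda))
  lo <- 0
  hi <- max(d2)
  while (tr(hi) > df) hi <- hi * 2
  while (hi - lo > tol * max(1, hi) || abs(tr((lo + hi) / 2) - df) > tol) {
    mid <- (lo + hi) / 2
    if (tr(mid) > df) lo <- mid else hi <- mid
    if (hi - lo < 1e-15 * max(1, hi)) break
  }
  (lo + hi) / 2
}

#' Fit one ridge-penalized base-learner
#'
#' Closed form for a one-hot block: coefficients are the per-level residual
#' sums shrunk by the level size plus the penalty,
#' c_l = sum(r at level l) / (n_l + lambda); lambda = 0 gives per-level
#' residual means.
#'
#' @param block a `design_block`.
#' @param residuals numeric vector (length = number of records).
#' @param lambda ridge penalty >= 0.
#' @return List with `coefficients` (named by level) and `rss` (residual
#'   sum of squares of the fit on `residuals`).
#' @export
fitBaseLearner <- function(block, residuals, lambda) {
  stopifnot(length(residuals) == length(block$index))
  counts <- block_counts(block)
  if (lambda == 0 && any(counts == 0)) {
    stop("singular unpenalized system: empty level in block '",
         block$variable, "'")
  }
  s <- rowsum_vec(residuals, block$index, block$n_levels)
  coef <- s / (counts + lambda)
  fitted <- coef[block$index]
  list(coefficients = stats::setNames(coef, block$levels),
       rss = sum((residuals - fitted)^2))
}

# rowsum over a level index for a vector (no names, fixed bin count)
rowsum_vec <- function(x, index, nbins) {
  out <- numeric(nbins)
  acc <- rowsum(x, index)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Componentwise L2 boosting fit
#'
#' Intercept (offset) is the outcome mean. Each iteration fits every
#' block's base-learner at its precomputed ridge penalty to the current
#' residuals, selects the block with the smallest residual sum of squares
#' (ties go to the lowest block index), and adds `nu` times its
#' coefficients to that block's running coefficients.
#'
#' @param blocks list of `design_block`s from [buildDesign()].
#' @param y numeric 0/1 outcomes (non-neoplastic = 1 under the default
#'   coding), length = number of records.
#' @param hyperparams a [boostHyperparams()] object.
#' @return A `boost_fit` with `intercept`, `coefficients` (named list of
#'   named numeric vectors per variable; exactly 0 for never-selected
#'   variables), `selection_path`, `loss_trace` and `hyperparams`.
#' @export
fitBoost <- function(blocks, y, hyperparams = boostHyperparams()) {
  if (length(blocks) == 0) stop("at least one design block is required")
  n <- length(blocks[[1]]$index)
  if (n == 0) stop("empty cohort: no records to fit")
  stopifnot(length(y) == n)
  fit <- boost_core(blocks, matrix(as.numeric(y), ncol = 1), hyperparams)
  structure(list(
    intercept = fit$intercept[1],
    coefficients = lapply(seq_along(blocks), function(k) {
      stats::setNames(fit$coefficients[[k]][, 1], blocks[[k]]$levels)
    }) |> stats::setNames(vapply(blocks, `[[`, "", "variable")),
    selection_path = if (hyperparams$mstop > 0)
      vapply(blocks, `[[`, "", "variable")[fit$selection[, 1]]
      else character(0),
    loss_trace = fit$loss_trace[, 1],
    lambdas = fit$lambdas,
    hyperparams = hyperparams,
    variables = vapply(blocks, `[[`, "", "variable")
  ), class = "boost_fit")
}

# Matrix boosting engine: fits every column of Y (n x B) independently but
# in lock-step, sharing the per-block rowsum. Returns per-block coefficient
# matrices (n_levels x B), per-column selection path and loss trace.
boost_core <- function(blocks, Y, hp) {
  n <- nrow(Y); B <- ncol(Y); K <- length(blocks)
  counts <- lapply(blocks, block_counts)
  lambdas <- vapply(seq_len(K), function(k) {
    ridgeLambdaForDf(blocks[[k]], min(hp$df, sum(counts[[k]] > 0)))
  }, numeric(1))
  shrink <- lapply(seq_len(K), function(k) counts[[k]] + lambdas[k])
  # rss reduction weight: fitting c = s/(n+l) reduces RSS by
  # sum_l s_l^2 * (n_l + 2 lambda) / (n_l + lambda)^2
  redw <- lapply(seq_len(K), function(k) {
    (counts[[k]] + 2 * lambdas[k]) / shrink[[k]]^2
  })
  intercept <- colMeans(Y)
  R <- sweep(Y, 2, intercept)
  coefs <- lapply(seq_len(K), function(k) {
    matrix(0, blocks[[k]]$n_levels, B)
  })
  selection <- matrix(0L, hp$mstop, B)
  loss_trace <- matrix(0, hp$mstop, B)
  if (hp$mstop > 0) {
    for (m in seq_len(hp$mstop)) {
      base_rss <- colSums(R^2)
      S <- vector("list", K)
      red <- matrix(0, K, B)
      for (k in seq_len(K)) {
        S[[k]] <- rowsum_mat(R, blocks[[k]]$index, blocks[[k]]$n_levels)
        red[k, ] <- colSums(S[[k]]^2 * redw[[k]])
      }
      # smallest RSS = largest reduction; ties -> lowest block index
      sel <- apply(red, 2, which.max)
      selection[m, ] <- sel
      for (k in unique(sel)) {
        j <- which(sel == k)
        Ck <- S[[k]][, j, drop = FALSE] / shrink[[k]]
        coefs[[k]][, j] <- coefs[[k]][, j] + hp$nu * Ck
        R[, j] <- R[, j] - hp$nu * Ck[blocks[[k]]$index, , drop = FALSE]
      }
      loss_trace[m, ] <- colSums(R^2)
    }
  }
  list(intercept = intercept, coefficients = coefs, selection = selection,
       loss_trace = loss_trace, lambdas = lambdas, base_rss = colSums(R^2))
}

# rowsum over a level index for matrix columns (L x B result)
rowsum_mat <- function(X, index, nbins) {
  out <- matrix(0, nbins, ncol(X))
  acc <- rowsum(X, index)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' @export
print.boost_fit <- function(x, ...) {
  cat("Componentwise L2 boosting fit\n")
  cat("  intercept (offset): ", format(x$intercept), "\n", sep = "")
  cat("  iterations: ", x$hyperparams$mstop, " (nu = ", x$hyperparams$nu,
      ", df = ", x$hyperparams$df, ")\n", sep = "")
  sel <- table(factor(x$selection_path, levels = x$variables))
  cat("  selections per variable:\n")
  for (v in names(sel)) cat("    ", v, ": ", sel[[v]], "\n", sep = "")
  invisible(x)
}

#' Extract per-level effects in the results-table layout
#'
#' One row per observed level with its accumulated coefficient (exactly 0
#' for variables never selected) and level sample size. Under the default
#' outcome coding a positive effect means association with the
#' non-neoplastic outcome and a negative effect with death due to
#' neoplasia.
#'
#' @param fit a `boost_fit` produced from `blocks`.
#' @param blocks the design blocks used for the fit.
#' @return data.frame with columns `variable`, `level`, `n`, `effect`.
#' @export
extractEffects <- function(fit, blocks) {
  stopifnot(inherits(fit, "boost_fit"))
  vars <- vapply(blocks, `[[`, "", "variable")
  if (!identical(unname(vars), unname(fit$variables))) {
    stop("blocks do not match the fitted design")
  }
  do.call(rbind, lapply(seq_along(blocks), function(k) {
    data.frame(variable = blocks[[k]]$variable,
               level = blocks[[k]]$levels,
               n = block_counts(blocks[[k]]),
               effect = unname(fit$coefficients[[k]]),
               stringsAsFactors = FALSE)
  }))
}

#' Fitted values of a boosting model
#'
#' @param object a `boost_fit`.
#' @param blocks design blocks conformable with the fit (same variables;
#'   levels must have been observed at fit time).
#' @param ... unused.
#' @return numeric vector: intercept plus the summed block contributions.
#' @export
predict.boost_fit <- function(object, blocks, ...) {
  vars <- vapply(blocks, `[[`, "", "variable")
  if (!identical(unname(vars), unname(object$variables))) {
    stop("blocks do not match the fitted design")
  }
  n <- length(blocks[[1]]$index)
  eta <- rep(object$intercept, n)
  for (k in seq_along(blocks)) {
    coef <- object$coefficients[[k]]
    unseen <- setdiff(blocks[[k]]$levels, names(coef))
    if (length(unseen) > 0) {
      stop("level(s) unseen at fit time in '", blocks[[k]]$variable,
           "': ", paste(unseen, collapse = ", "))
    }
    eta <- eta + unname(coef[blocks[[k]]$levels])[blocks[[k]]$index]
  }
  eta
}
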