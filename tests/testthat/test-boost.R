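test_that("design blocks are exclusive one-hot encodings", {
  co <- make_cohort(5, sex = c("male", "female", "unknown", "male",
                               "female"))
  blocks <- buildDesign(co, c("sex", "malignancy"))
  Z <- blockMatrix(blocks[[1]])
  expect_equal(dim(Z), c(5, 3))
  expect_equal(unname(rowSums(Z)), rep(1, 5))
  # column sums are the level sample sizes, and agree with the frequency
  # table for the same cohort
  ft <- frequencyTable(co, "sex")
  expect_equal(unname(colSums(Z)[ft$level]), as.numeric(ft$count))
  # a constant variable is a single column of ones
  Z2 <- blockMatrix(blocks[[2]])
  expect_equal(unname(Z2), matrix(1, 5, 1))
  expect_error(buildDesign(co, "sexx"), "unknown variable")
})

test_that("ridge penalty reaches the target degrees of freedom", {
  # full-rank df means no penalty
  co <- make_cohort(9, sex = c("male", "female", "unknown"))
  block <- buildDesign(co, "sex")[[1]]
  expect_equal(ridgeLambdaForDf(block, 3), 0)
  expect_error(ridgeLambdaForDf(block, 4), "exceeds block rank")
  # balanced 4-level block, 10 per level, df = 2: trace is 4*10/(10+l),
  # so l = 10 exactly; also checked against the eigen-decomposition oracle
  co4 <- make_cohort(40, diagnosis = c("a", "b", "c", "d"))
  b4 <- buildDesign(co4, "diagnosis")[[1]]
  l <- ridgeLambdaForDf(b4, 2)
  expect_equal(l, 10, tolerance = 1e-6)
  expect_equal(l, oracle_lambda(blockMatrix(b4), 2), tolerance = 1e-6)
  # trace is monotone decreasing in lambda on a random unbalanced block
  set.seed(1)
  co_r <- make_cohort(30, diagnosis = sample(letters[1:4], 30,
                                             replace = TRUE))
  b_r <- buildDesign(co_r, "diagnosis")[[1]]
  counts <- tabulate(b_r$index)
  tr <- function(l) sum(counts / (counts + l))
  expect_true(all(diff(sapply(c(0, 1, 10, 100, 1e4), tr)) < 0))
  expect_lt(tr(1e8), 0.01)
})

test_that("base-learner fits match the closed form and a dense solve", {
  set.seed(2)
  co <- make_cohort(12, sex = rep(c("male", "female"), 6))
  block <- buildDesign(co, "sex")[[1]]
  r <- stats::rnorm(12)
  # lambda = 0 on a balanced block: per-level residual means
  fit0 <- fitBaseLearner(block, r, 0)
  means <- tapply(r, co$records$sex, mean)
  expect_equal(unname(fit0$coefficients[names(means)]),
               as.vector(means), tolerance = 1e-12)
  # zero residuals give zero coefficients and zero RSS
  fitz <- fitBaseLearner(block, rep(0, 12), 3)
  expect_equal(unname(fitz$coefficients), c(0, 0))
  expect_equal(fitz$rss, 0)
  # random instance against the dense linear-algebra oracle
  Z <- blockMatrix(block)
  lambda <- 2.7
  dense <- solve(crossprod(Z) + lambda * diag(2), crossprod(Z, r))
  fit <- fitBaseLearner(block, r, lambda)
  expect_equal(unname(fit$coefficients), unname(drop(dense)),
               tolerance = 1e-10)
})

test_that("boosting fit honors the trivial contracts", {
  co <- make_cohort(10, sex = rep(c("male", "female"), 5),
                    malignancy = rep(c("benign", "malignant"), each = 5))
  blocks <- buildDesign(co, c("sex", "malignancy"))
  y <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  # mstop = 0: intercept only
  fit0 <- fitBoost(blocks, y, boostHyperparams(mstop = 0))
  expect_equal(fit0$intercept, mean(y))
  expect_true(all(unlist(fit0$coefficients) == 0))
  expect_equal(predict(fit0, blocks), rep(mean(y), 10))
  # constant y: zero residuals, zero coefficients at any mstop
  fitc <- fitBoost(blocks, rep(1, 10), boostHyperparams(mstop = 50))
  expect_true(all(unlist(fitc$coefficients) == 0))
  # empty design or cohort is an error
  expect_error(fitBoost(list(), y), "at least one")
})

test_that("boosting matches the naive reference loop on random instances", {
  set.seed(2024)
  for (rep_i in 1:8) {
    n <- sample(10:50, 1)
    K <- sample(2:4, 1)
    inst <- random_boost_instance(n, K, binary_y = rep_i %% 2 == 0)
    mstop <- sample(c(5, 25), 1)
    fit <- pkg_boost_fit(inst, mstop, 0.1, 4)
    ref <- oracle_boost(inst$xs, inst$y, mstop, 0.1, 4)
    expect_equal(fit$intercept, ref$intercept, tolerance = 1e-12)
    for (k in seq_len(K)) {
      expect_lt(max(abs(unname(fit$coefficients[[k]]) -
                          unname(ref$coefficients[[k]]))), 1e-10)
    }
    # fitted values and the recorded loss trace agree with the oracle
    blocks <- buildDesign(
      do.call(make_cohort,
              c(list(n = n),
                stats::setNames(inst$xs, names(fit$coefficients)))),
      names(fit$coefficients))
    pred <- predict(fit, blocks)
    expect_equal(sum((inst$y - pred)^2),
                 utils::tail(fit$loss_trace, 1), tolerance = 1e-10)
    expect_equal(utils::tail(fit$loss_trace, 1), ref$final_rss,
                 tolerance = 1e-10)
  }
})

test_that("loss trace never increases and effects are continuous in nu", {
  set.seed(99)
  inst <- random_boost_instance(40, 3)
  fit <- pkg_boost_fit(inst, 100, 0.1, 3)
  expect_true(all(diff(fit$loss_trace) <= 1e-12))
  # small step-length perturbation moves effects only slightly
  f1 <- pkg_boost_fit(inst, 50, 0.100, 3)
  f2 <- pkg_boost_fit(inst, 50, 0.101, 3)
  d <- max(abs(unlist(f1$coefficients) - unlist(f2$coefficients)))
  expect_lt(d, 0.05)
})

test_that("a single unpenalized block converges to centered level means", {
  set.seed(7)
  x <- sample(c("a", "b", "c"), 60, replace = TRUE)
  y <- stats::rbinom(60, 1, ifelse(x == "a", 0.8, 0.3))
  co <- make_cohort(60, diagnosis = x)
  blocks <- buildDesign(co, "diagnosis")
  fit <- fitBoost(blocks, y, boostHyperparams(mstop = 5000, nu = 0.1,
                                              df = 3))
  target <- tapply(y - mean(y), x, mean)
  expect_equal(unname(fit$coefficients$diagnosis[names(target)]),
               as.vector(target), tolerance = 1e-3)
})

test_that("effect extraction reports every level with its sample size", {
  x <- rep(c("good", "bad"), each = 6)
  y <- as.numeric(x == "good")
  co <- make_cohort(12, treatment = ifelse(x == "good", "surgery_only",
                                           "no_treatment"))
  blocks <- buildDesign(co, "treatment")
  fit <- fitBoost(blocks, y, boostHyperparams(mstop = 300))
  eff <- extractEffects(fit, blocks)
  expect_equal(eff$n, c(6, 6))
  # sign forced by construction: all-good level positive, all-bad negative
  expect_gt(eff$effect[eff$level == "surgery_only"], 0)
  expect_lt(eff$effect[eff$level == "no_treatment"], 0)
  # sample-size weighted effects of an unpenalized single block sum to ~0
  fit3 <- fitBoost(blocks, y, boostHyperparams(mstop = 200, df = 2))
  eff3 <- extractEffects(fit3, blocks)
  expect_equal(sum(eff3$n * eff3$effect), 0, tolerance = 1e-8)
  # prediction refuses unseen levels
  co_new <- make_cohort(3, treatment = "radiation_only")
  expect_error(predict(fit, buildDesign(co_new, "treatment")),
               "unseen.*radiation_only")
})
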