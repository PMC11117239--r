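test_that("product-limit estimates match hand-computed examples", {
  expect_error(kmEstimate(numeric(0), logical(0)), "empty input")
  # all censored: survival stays at 1
  allc <- kmEstimate(c(2, 5, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(allc$surv == 1))
  expect_equal(allc$censor_marks, c(2, 5, 9))
  # no censoring: the classic 2/3, 1/3, 0 staircase
  km <- kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # middle observation censored: S(1) = 2/3, S(3) = 0
  kmc <- kmEstimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(survivalAt(kmc, c(1, 2, 3)), c(2 / 3, 2 / 3, 0))
  # a larger example against the naive reference implementation
  set.seed(31)
  times <- round(stats::rexp(40, 0.2), 1)
  events <- stats::runif(40) < 0.7
  ref <- oracle_km(times, events)
  cv <- kmEstimate(times, events)
  expect_equal(survivalAt(cv, ref$time), ref$s, tolerance = 1e-12)
})

test_that("survival equals one minus the empirical CDF without censoring", {
  set.seed(8)
  times <- sample(0:20, 50, replace = TRUE)
  cv <- kmEstimate(times, rep(TRUE, 50))
  expect_equal(survivalAt(cv, cv$time),
               1 - stats::ecdf(times)(cv$time), tolerance = 1e-12)
  # moving a censoring time that is already beyond every event even
  # further out never changes the curve (the risk sets at event times are
  # unchanged)
  cva <- kmEstimate(c(times, 21), c(rep(TRUE, 50), FALSE))
  cvb <- kmEstimate(c(times, 100), c(rep(TRUE, 50), FALSE))
  expect_equal(survivalAt(cvb, cva$time), survivalAt(cva, cva$time),
               tolerance = 1e-12)
})

test_that("Greenwood log-log bands match the direct formula and survfit", {
  times <- c(1, 1, 2, 3, 4, 4, 5, 6, 8, 9)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
              FALSE)
  cv <- kmEstimate(times, events)
  # direct formula: exp(-exp(log(-log S) +/- z * se(loglog)))
  d <- cv$n_event
  nr <- cv$n_risk
  V <- cumsum(ifelse(nr > d, d / (nr * (nr - d)), 0))
  z <- stats::qnorm(0.975)
  mid <- cv$surv > 0 & cv$surv < 1
  se <- sqrt(V[mid]) / abs(log(cv$surv[mid]))
  expect_equal(cv$lower[mid],
               exp(-exp(log(-log(cv$surv[mid])) + z * se)),
               tolerance = 1e-12)
  expect_equal(cv$upper[mid],
               exp(-exp(log(-log(cv$surv[mid])) - z * se)),
               tolerance = 1e-12)
  # independent cross-check: the survival package's own log-log bands
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log-log")
  expect_equal(cv$lower, ifelse(is.na(sf$lower), cv$surv, sf$lower),
               tolerance = 1e-9)
  expect_equal(cv$upper, ifelse(is.na(sf$upper), cv$surv, sf$upper),
               tolerance = 1e-9)
  # bands always bracket the estimate inside [0, 1]
  expect_true(all(cv$lower <= cv$surv + 1e-12 &
                    cv$surv <= cv$upper + 1e-12))
  expect_true(all(cv$lower >= 0 & cv$upper <= 1))
  # while survival is still 1 the band is degenerate at [1, 1]
  early <- kmEstimate(c(5, 6, 7), c(FALSE, FALSE, TRUE))
  expect_equal(early$lower[early$surv == 1], c(1, 1))
  # Greenwood variance is zero before any event has occurred
  expect_equal(early$greenwood_var[early$time < 7], c(0, 0))
})

test_that("bands widen as the sample shrinks along the same path", {
  big <- kmEstimate(rep(c(1, 2, 3, 10), each = 10),
                    rep(c(TRUE, TRUE, TRUE, FALSE), each = 10))
  small <- kmEstimate(c(1, 2, 3, 10), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(survivalAt(small, c(1, 2, 3)), survivalAt(big, c(1, 2, 3)))
  mid <- which(big$surv > 0 & big$surv < 1)
  expect_true(all((big$upper - big$lower)[mid] <
                    (small$upper - small$lower)[mid]))
})

test_that("median survival scans the step function correctly", {
  # never reaching 0.5: undefined
  cv <- kmEstimate(c(1, 2, 3, 4), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(medianSurvival(cv)))
  # a single immediate death: median 0
  expect_equal(medianSurvival(kmEstimate(0, TRUE)), 0)
  # 8-record curve against a brute-force scan
  set.seed(12)
  times <- c(0, 1, 1, 3, 5, 7, 8, 11)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  cv8 <- kmEstimate(times, events)
  scan <- NA_real_
  for (t in sort(unique(times))) {
    if (survivalAt(cv8, t) <= 0.5) { scan <- t; break }
  }
  expect_equal(medianSurvival(cv8), scan)
})

test_that("group survival partitions by malignancy and treatment status", {
  co <- make_cohort(
    12,
    malignancy = c(rep("malignant", 8), rep("benign", 4)),
    treatment = c(rep("no_treatment", 4), rep("surgery_only", 4),
                  rep("surgery_only", 4)),
    outcome = c(rep("died_neoplasia", 3), "alive",
                rep("died_neoplasia", 2), "died_other", "alive",
                rep("died_neoplasia", 2), "alive", "unknown"),
    survival_months = c(1:11, 12))
  curves <- groupSurvival(co)
  # the unknown-outcome record is excluded and counted
  expect_equal(attr(curves, "n_excluded"), 1)
  sizes <- vapply(curves, function(cv) cv$n, numeric(1))
  expect_equal(sum(sizes), 11)
  expect_setequal(
    names(curves),
    c("malignant.neoplasia_no_treatment",
      "malignant.neoplasia_with_treatment",
      "malignant.died_non_neoplastic", "benign.neoplasia_with_treatment"))
  # non-neoplastic deaths form their own group regardless of treatment
  expect_equal(curves[["malignant.died_non_neoplastic"]]$n, 1)
  # a cohort with only benign treated cases yields exactly one curve
  solo <- groupSurvival(make_cohort(4, malignancy = "benign",
                                    treatment = "surgery_only",
                                    outcome = "died_neoplasia",
                                    survival_months = 1:4))
  expect_equal(length(solo), 1)
})
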