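## Kaplan-Meier survival estimation with right censoring.
##
## The product-limit estimate itself comes from survival::survfit; the
## Greenwood-based log-log 95% bands are recomputed here from the stored
## event counts so the band construction is explicit and testable.

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' Standard tied-time convention: censorings at a death time occur after
#' the deaths. Time 0 events are legal (survival is measured from
#' diagnosis and same-day deaths occur).
#'
#' @param times nonnegative observation times in months.
#' @param events logical (or 0/1): TRUE = death observed, FALSE =
#'   right-censored (e.g. still alive).
#' @param conf_level confidence level for the Greenwood log-log bands.
#' @return A `km_curve`: data.frame-backed list with `time` (distinct
#'   observed times), `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `greenwood_var` (cumulative Greenwood sum d/(n(n-d))), `lower`,
#'   `upper`, and `censor_marks` (times with at least one censoring).
#' @export
kmEstimate <- function(times, events, conf_level = 0.95) {
  if (length(times) == 0) stop("empty input: no observations")
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  curve <- list(time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, n_censor = fit$n.censor,
                surv = fit$surv,
                greenwood_var = cumsum(
                  ifelse(fit$n.risk > fit$n.event,
                         fit$n.event / (fit$n.risk *
                                          (fit$n.risk - fit$n.event)),
                         0)),
                censor_marks = fit$time[fit$n.censor > 0],
                n = length(times))
  class(curve) <- "km_curve"
  greenwoodCi(curve, conf_level)
}

#' Greenwood log-log confidence bands for a survival curve
#'
#' Complementary log-log transformed intervals,
#' `exp(-exp(log(-log S) +/- z * se))` with
#' `se = sqrt(V) / |log S|` and `V` the cumulative Greenwood sum, clipped
#' to `[0, 1]` and degenerate where `S` is 0 or 1. The log-log transform
#' keeps the bands inside `[0, 1]` by construction.
#'
#' @param curve a `km_curve`.
#' @param conf_level confidence level (default 0.95).
#' @return The curve with `lower`/`upper` recomputed at `conf_level`.
#' @export
greenwoodCi <- function(curve, conf_level = 0.95) {
  stopifnot(inherits(curve, "km_curve"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  s <- curve$surv
  v <- curve$greenwood_var
  lower <- upper <- s
  mid <- s > 0 & s < 1
  se_loglog <- sqrt(v[mid]) / abs(log(s[mid]))
  cloglog <- log(-log(s[mid]))
  lower[mid] <- exp(-exp(cloglog + z * se_loglog))
  upper[mid] <- exp(-exp(cloglog - z * se_loglog))
  curve$lower <- pmin(pmax(lower, 0), 1)
  curve$upper <- pmin(pmax(upper, 0), 1)
  curve$conf_level <- conf_level
  curve
}

#' Median survival time of a curve
#'
#' @param curve a `km_curve`.
#' @return Smallest time with survival <= 0.5, or NA if the curve never
#'   reaches 0.5.
#' @export
medianSurvival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$surv <= 0.5)
  if (length(hit) == 0) NA_real_ else curve$time[hit[1]]
}

#' Evaluate a survival step function at arbitrary times
#' @param curve a `km_curve`.
#' @param t numeric times.
#' @return survival probabilities (1 before the first observed time).
#' @export
survivalAt <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    j <- which(curve$time <= ti)
    if (length(j) == 0) 1 else curve$surv[max(j)]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", x$n, " observations, ",
      sum(x$n_event), " events, ", sum(x$n_censor), " censored\n", sep = "")
  med <- medianSurvival(x)
  cat("  median survival: ",
      if (is.na(med)) "not reached" else paste(med, "months"), "\n", sep = "")
  invisible(x)
}

#' Group-wise survival curves by malignancy and treatment status
#'
#' Partitions the cohort the way the survival contrast figure reads:
#' within each malignancy class (malignant, benign), cases dying of a
#' non-neoplastic cause form one group, and the remaining cases split by
#' whether treatment was pursued (any category except no or unknown
#' treatment). Alive records are right-censored at their last known
#' survival time; records with unknown survival time, unknown outcome or
#' unknown cause of death are excluded and counted.
#'
#' @param cohort a `lizard_cohort`.
#' @param malignancies malignancy classes to panel over.
#' @param conf_level confidence level for the bands.
#' @return Named list of `km_curve`s (names like
#'   `"malignant.neoplasia_no_treatment"`); the number of excluded records
#'   is attached as attribute `"n_excluded"`.
#' @export
groupSurvival <- function(cohort, malignancies = c("malignant", "benign"),
                          conf_level = 0.95) {
  stopifnot(inherits(cohort, "lizard_cohort"))
  r <- cohort$records
  usable <- !is.na(r$survival_months) &
    r$outcome %in% c("died_neoplasia", "died_other", "alive")
  n_excluded <- sum(!usable)
  r <- r[usable, , drop = FALSE]
  treated <- !(r$treatment %in% c("no_treatment", "unknown_treatment"))
  status <- ifelse(r$outcome == "died_other", "died_non_neoplastic",
                   ifelse(treated, "neoplasia_with_treatment",
                          "neoplasia_no_treatment"))
  curves <- list()
  for (m in malignancies) {
    for (st in c("neoplasia_no_treatment", "neoplasia_with_treatment",
                 "died_non_neoplastic")) {
      idx <- r$malignancy == m & status == st
      if (any(idx)) {
        curves[[paste(m, st, sep = ".")]] <-
          kmEstimate(r$survival_months[idx], r$outcome[idx] != "alive",
                     conf_level)
      }
    }
  }
  attr(curves, "n_excluded") <- n_excluded
  curves
}

#' Export a survival curve as a data frame
#' @param curve a `km_curve`.
#' @return data.frame with columns time, n_risk, n_event, n_censor, S,
#'   lo, hi.
#' @export
kmAsDataFrame <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  data.frame(time = curve$time, n_risk = curve$n_risk,
             n_event = curve$n_event, n_censor = curve$n_censor,
             S = curve$surv, lo = curve$lower, hi = curve$upper)
}

#' Plot survival curves with confidence bands and censor marks
#'
#' Step curves with shaded Greenwood log-log bands; `+` marks at censored
#' times, as survival-percentage plots are conventionally drawn.
#'
#' @param x a `km_curve` or a named list of them (e.g. from
#'   [groupSurvival()]).
#' @param col colors, recycled over curves.
#' @param xlab,ylab,main usual plot labels.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plotKm <- function(x, col = c("#C0392B", "#2471A3", "#1E8449", "#9A7D0A"),
                   xlab = "Months since diagnosis",
                   ylab = "Survival probability", main = "", ...) {
  curves <- if (inherits(x, "km_curve")) list(curve = x) else x
  xmax <- max(vapply(curves, function(cv) max(cv$time), numeric(1)), 1)
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, main = main, ...)
  col <- rep_len(col, length(curves))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    tt <- c(0, cv$time)
    ss <- c(1, cv$surv)
    lo <- c(1, cv$lower)
    hi <- c(1, cv$upper)
    shade <- grDevices::adjustcolor(col[i], alpha.f = 0.2)
    graphics::polygon(c(rep(tt, each = 2)[-1], rev(rep(tt, each = 2)[-1])),
                      c(rep(lo, each = 2)[-(2 * length(tt))],
                        rev(rep(hi, each = 2)[-(2 * length(tt))])),
                      col = shade, border = NA)
    graphics::lines(tt, ss, type = "s", col = col[i], lwd = 2)
    if (length(cv$censor_marks) > 0) {
      graphics::points(cv$censor_marks, survivalAt(cv, cv$censor_marks),
                       pch = 3, col = col[i])
    }
  }
  if (length(curves) > 1) {
    graphics::legend("topright", legend = names(curves),
                     col = col, lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(x)
}
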