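# Independent reference implementations used as oracles. Everything here
# is deliberately naive: dense matrices, explicit loops, stats::uniroot --
# no code shared with the package internals.

# indicator matrix of a factor-like vector
oracle_indicator <- function(x) {
  levs <- sort(unique(x))
  Z <- matrix(0, length(x), length(levs), dimnames = list(NULL, levs))
  for (i in seq_along(x)) Z[i, match(x[i], levs)] <- 1
  Z
}

# ridge penalty for a target trace of the hat matrix, via uniroot on the
# eigenvalues of Z'Z
oracle_lambda <- function(Z, df) {
  d <- eigen(crossprod(Z), symmetric = TRUE, only.values = TRUE)$values
  d <- d[d > 1e-12]
  if (abs(df - length(d)) < 1e-12) return(0)
  f <- function(l) sum(d / (d + l)) - df
  upper <- max(d)
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

# literal componentwise L2 boosting loop on dense blocks
oracle_boost <- function(xs, y, mstop, nu, df) {
  Zs <- lapply(xs, oracle_indicator)
  lambdas <- vapply(Zs, function(Z) oracle_lambda(Z, min(df, ncol(Z))),
                    numeric(1))
  intercept <- mean(y)
  r <- y - intercept
  coefs <- lapply(Zs, function(Z) {
    stats::setNames(rep(0, ncol(Z)), colnames(Z))
  })
  path <- integer(0)
  for (m in seq_len(mstop)) {
    rss <- numeric(length(Zs))
    cands <- vector("list", length(Zs))
    for (k in seq_along(Zs)) {
      Z <- Zs[[k]]
      c_k <- solve(crossprod(Z) + lambdas[k] * diag(ncol(Z)),
                   crossprod(Z, r))
      cands[[k]] <- drop(c_k)
      rss[k] <- sum((r - Z %*% c_k)^2)
    }
    k_best <- which.min(rss)
    path <- c(path, k_best)
    coefs[[k_best]] <- coefs[[k_best]] + nu * cands[[k_best]]
    r <- r - nu * (Zs[[k_best]] %*% cands[[k_best]])
  }
  list(intercept = intercept, coefficients = coefs, path = path,
       final_rss = sum(r^2))
}

# random boosting instance: n records, K categorical variables
random_boost_instance <- function(n, K, max_levels = 5, binary_y = TRUE) {
  xs <- lapply(seq_len(K), function(k) {
    nl <- sample(2:max_levels, 1)
    sample(letters[seq_len(nl)], n, replace = TRUE)
  })
  # ensure every drawn level actually appears at least twice
  xs <- lapply(xs, function(x) {
    tab <- table(x)
    x[x %in% names(tab)[tab < 2]] <- names(tab)[which.max(tab)]
    x
  })
  y <- if (binary_y) stats::rbinom(n, 1, 0.5) else stats::rnorm(n)
  list(xs = xs, y = as.numeric(y))
}

# package-side fit of the same instance
pkg_boost_fit <- function(inst, mstop, nu, df) {
  n <- length(inst$y)
  over <- stats::setNames(inst$xs,
                          c("sex", "life_stage", "malignancy",
                            "metastasis")[seq_along(inst$xs)])
  cohort <- do.call(make_cohort, c(list(n = n), over))
  blocks <- buildDesign(cohort, names(over))
  fitBoost(blocks, inst$y, boostHyperparams(mstop, nu, df))
}

# hand-rolled product-limit curve: returns S at each distinct time with
# deaths (censorings at tied times count after the deaths)
oracle_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out <- data.frame(time = numeric(0), n_risk = numeric(0),
                    d = numeric(0), s = numeric(0))
  for (t in ut) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events)
    if (d > 0) s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, n_risk = n_risk, d = d, s = s))
  }
  out
}
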