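# Binomial model of spurious-pseudogene generation. Each observation is a
# count k of spurious pseudogenes among n coding features of an assembly,
# produced from reads with a given fold coverage and mean base quality.
# The per-CDS probability is modeled on the logit scale as linear in
# log10(coverage) and quality, and fit by maximum likelihood through
# iteratively reweighted least squares (IRLS).

model_matrix_obs <- function(coverage, quality, use_quality) {
  X <- cbind(`(Intercept)` = 1, log10_coverage = log10(coverage))
  if (use_quality) X <- cbind(X, quality = quality)
  X
}

binom_loglik <- function(k, n, mu) {
  sum(stats::dbinom(k, n, pmin(pmax(mu, 1e-15), 1 - 1e-15), log = TRUE))
}

#' Fit the binomial spurious-pseudogene model
#'
#' Maximum-likelihood fit of `k ~ Binomial(n, p)` with
#' `logit(p) = beta0 + beta_cov * log10(coverage) + beta_q * quality`,
#' by IRLS iterated to `|delta log-likelihood| < 1e-8` (at most 100
#' iterations). When quality is constant across observations the quality
#' term is dropped (`beta_q = NA`, flagged). Complete or quasi-complete
#' separation is detected from diverging coefficients or degenerate
#' fitted probabilities and handled with a small ridge (1e-6) on the
#' normal equations, never silently: the fit is flagged. When every k is
#' zero the likelihood has no interior maximum and the fit is returned
#' with a `boundary` flag and no coefficient estimates.
#'
#' @param observations data.frame with columns `k`, `n`, `coverage`,
#'   `quality` (one row per assembly/condition). At least 3 distinct
#'   coverage values are required.
#' @return An object of class `binomial_fit`: `coefficients` (named
#'   beta0, beta_cov, beta_q), `se`, `deviance`, `loglik`, `n_obs`,
#'   `flags` (character vector, possibly empty), `link`
#'   ("logit(p) ~ log10(coverage) + quality").
#' @export
fit_binomial <- function(observations) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("k", "n", "coverage", "quality") %in% names(obs)))
  k <- obs$k; n <- obs$n; cov <- obs$coverage; q <- obs$quality
  if (any(n <= 0)) stop("all n must be positive")
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
  if (any(cov <= 0)) stop("coverage must be positive")
  if (length(unique(cov)) < 3L) {
    stop("need at least 3 distinct coverage values")
  }
  flags <- character()
  use_quality <- length(unique(q)) > 1L
  if (!use_quality) flags <- c(flags, "quality_dropped")
  if (all(k == 0L)) {
    return(structure(list(
      coefficients = c(beta0 = NA_real_, beta_cov = NA_real_,
                       beta_q = NA_real_),
      se = c(beta0 = NA_real_, beta_cov = NA_real_, beta_q = NA_real_),
      deviance = 0, loglik = 0, n_obs = nrow(obs),
      flags = c(flags, "boundary"),
      link = "logit(p) ~ log10(coverage) + quality"
    ), class = "binomial_fit"))
  }
  X <- model_matrix_obs(cov, q, use_quality)
  p0 <- pmin(pmax((k + 0.5) / (n + 1), 1e-10), 1 - 1e-10)
  beta <- stats::lm.fit(X, stats::qlogis(p0))$coefficients
  beta[is.na(beta)] <- 0
  ll_old <- -Inf
  ridge <- 0
  separated <- FALSE
  XtWX <- diag(ncol(X))
  for (iter in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- n * mu * (1 - mu)
    if (any(w < 1e-12) || any(abs(beta) > 50)) {
      if (!separated) {
        separated <- TRUE
        ridge <- 1e-6
        flags <- c(flags, "separation_ridge")
      }
      w <- pmax(w, 1e-12)
    }
    z <- eta + (k - n * mu) / w
    XtWX <- crossprod(X, w * X) + ridge * diag(ncol(X))
    beta_new <- drop(solve(XtWX, crossprod(X, w * z)))
    beta <- beta_new
    ll <- binom_loglik(k, n, stats::plogis(drop(X %*% beta)))
    if (is.finite(ll) && abs(ll - ll_old) < 1e-8) break
    ll_old <- ll
  }
  se <- sqrt(diag(solve(XtWX)))
  mu <- stats::plogis(drop(X %*% beta))
  ll_sat <- binom_loglik(k, n, ifelse(n > 0, k / n, 0))
  deviance <- 2 * (ll_sat - binom_loglik(k, n, mu))
  full <- function(v) {
    out <- c(beta0 = NA_real_, beta_cov = NA_real_, beta_q = NA_real_)
    out[c("beta0", "beta_cov")] <- v[1:2]
    if (use_quality) out[["beta_q"]] <- v[[3]]
    out
  }
  structure(list(
    coefficients = full(beta), se = full(se),
    deviance = deviance, loglik = binom_loglik(k, n, mu),
    n_obs = nrow(obs), flags = flags,
    link = "logit(p) ~ log10(coverage) + quality"
  ), class = "binomial_fit")
}

#' @export
print.binomial_fit <- function(x, ...) {
  cat("<binomial_fit>", x$link, "\n")
  if ("boundary" %in% x$flags) {
    cat("  boundary fit (all counts zero); no finite MLE\n")
  } else {
    for (nm in names(x$coefficients)) {
      if (is.na(x$coefficients[[nm]])) next
      cat(sprintf("  %-9s % .4f (SE %.4f)\n", nm, x$coefficients[[nm]],
                  x$se[[nm]]))
    }
    cat(sprintf("  deviance %.3f on %d observations\n", x$deviance, x$n_obs))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

fit_eta <- function(fit, coverage, quality) {
  b <- fit$coefficients
  if (any(is.na(b[c("beta0", "beta_cov")]))) {
    stop("fit has no coefficient estimates (boundary fit?)")
  }
  bq <- if (is.na(b[["beta_q"]])) 0 else b[["beta_q"]]
  b[["beta0"]] + b[["beta_cov"]] * log10(coverage) + bq * quality
}

#' Predicted spurious-pseudogene density
#'
#' Converts the fitted per-CDS probability into a per-Mbp density:
#' `density = plogis(eta) * n_cds * 1e6 / genome_len`.
#'
#' @param fit a [fit_binomial()] result.
#' @param coverage fold coverage (> 0), possibly vectorized.
#' @param quality mean base quality.
#' @param n_cds number of coding sequences in the assembly.
#' @param genome_len assembly length in bp.
#' @return Per-Mbp density (numeric, same length as `coverage`).
#' @export
predict_density <- function(fit, coverage, quality, n_cds, genome_len) {
  if (any(coverage <= 0)) stop("coverage must be positive")
  stats::plogis(fit_eta(fit, coverage, quality)) * n_cds * 1e6 / genome_len
}

#' Coverage required to reach a target spurious-pseudogene density
#'
#' Solves `predict_density(coverage) = target_density` for coverage by
#' bisection on log10(coverage) over `[0.1, 1e6]` to a relative tolerance
#' of 1e-6. Requires a model that is decreasing in coverage
#' (`beta_cov < 0`).
#'
#' @inheritParams predict_density
#' @param target_density target per-Mbp density (default 1.0).
#' @return A list with `coverage` (fold; `Inf` when even 1e6-fold leaves
#'   the density above target) and `flag` (`"ok"`, `"above_target"` —
#'   never reaches target — or `"below_bracket"` — density is already
#'   below target at the 0.1-fold lower bracket, whose value is
#'   returned).
#' @export
coverage_for_density <- function(fit, target_density = 1.0, quality, n_cds,
                                 genome_len) {
  b_cov <- fit$coefficients[["beta_cov"]]
  if (is.na(b_cov) || b_cov >= 0) {
    stop("model is not decreasing in coverage (beta_cov >= 0)")
  }
  f <- function(l) {
    predict_density(fit, 10^l, quality, n_cds, genome_len) - target_density
  }
  lo <- -1; hi <- 6
  if (f(hi) > 0) return(list(coverage = Inf, flag = "above_target"))
  if (f(lo) < 0) return(list(coverage = 10^lo, flag = "below_bracket"))
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (10^hi - 10^lo <= 1e-6 * 10^lo) break
  }
  list(coverage = 10^((lo + hi) / 2), flag = "ok")
}

#' 99th-percentile binomial anomaly filter against the nearest neighbor
#'
#' Tests whether an assembly's internal-stop pseudogene count exceeds the
#' 99th percentile of a binomial with its own number of coding sequences
#' but its nearest neighbor's per-CDS pseudogene rate. Only evaluated
#' when the neighbor's ANI is at least 99.9%; the threshold is the exact
#' discrete binomial quantile `min{t : CDF(t; n_cds, rate) >= 0.99}` and
#' rejection requires a strictly greater count.
#'
#' @param n_stops internal-stop pseudogene count of the assembly.
#' @param n_cds coding-sequence count of the assembly (> 0).
#' @param neighbor_stops,neighbor_n_cds the nearest neighbor's counts.
#' @param neighbor_ani ANI (percent) to the nearest neighbor.
#' @param ani_gate minimum neighbor ANI for evaluation (default 99.9).
#' @param quantile percentile defining the threshold (default 0.99).
#' @return An object of class `filter_verdict`: `evaluated`, `n_stops`,
#'   `n_cds`, `neighbor_rate`, `threshold`, `reject`, `neighbor_ani`.
#' @export
binomial_filter <- function(n_stops, n_cds, neighbor_stops, neighbor_n_cds,
                            neighbor_ani, ani_gate = 99.9, quantile = 0.99) {
  if (n_cds <= 0) stop("n_cds must be positive")
  if (neighbor_n_cds <= 0) stop("neighbor_n_cds must be positive")
  if (is.na(neighbor_ani) || neighbor_ani < ani_gate) {
    return(structure(list(
      evaluated = FALSE, n_stops = n_stops, n_cds = n_cds,
      neighbor_rate = NA_real_, threshold = NA_integer_, reject = NA,
      neighbor_ani = neighbor_ani
    ), class = "filter_verdict"))
  }
  rate <- neighbor_stops / neighbor_n_cds
  threshold <- stats::qbinom(quantile, n_cds, rate)
  structure(list(
    evaluated = TRUE, n_stops = n_stops, n_cds = n_cds,
    neighbor_rate = rate, threshold = as.integer(threshold),
    reject = n_stops > threshold, neighbor_ani = neighbor_ani
  ), class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  if (!x$evaluated) {
    cat("<filter_verdict> not evaluated (neighbor ANI below gate)\n")
  } else {
    cat(sprintf(
      "<filter_verdict> %d stops in %d CDS vs neighbor rate %.4g: threshold %d -> %s\n",
      x$n_stops, x$n_cds, x$neighbor_rate, x$threshold,
      if (x$reject) "REJECT" else "keep"
    ))
  }
  invisible(x)
}

#' R-squared of pseudogene deviation on ANI
#'
#' Ordinary least-squares R-squared of the absolute internal-stop
#' deviation (per Mbp) regressed on ANI.
#'
#' @param deviation numeric vector of |delta internal stops per Mbp|.
#' @param ani numeric vector of ANI percents (same length, >= 3 points).
#' @return R-squared in `[0, 1]`, or `NA` when either coordinate has zero
#'   variance.
#' @export
deviation_ani_rsq <- function(deviation, ani) {
  stopifnot(length(deviation) == length(ani))
  if (length(deviation) < 3L) stop("need at least 3 points")
  if (stats::var(deviation) == 0 || stats::var(ani) == 0) return(NA_real_)
  f <- stats::lm(deviation ~ ani)
  1 - sum(stats::residuals(f)^2) / sum((deviation - mean(deviation))^2)
}
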