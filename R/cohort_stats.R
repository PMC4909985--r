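# Cohort-level statistics: Wilson intervals, exact binomial tests, odds
# ratios, IRLS logistic regression, length-adjusted rates and event
# summaries.

#' Wilson score interval for a binomial proportion
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (n >= 1).
#' @param conf confidence level, default 0.95.
#' @return numeric `c(lower, upper)`, both in \[0, 1\].
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  z <- stats::qnorm((1 + conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Two-sided exact binomial test by tail doubling
#'
#' `2 * min(P(X <= k), P(X >= k))` under `Binomial(n, p0)`, capped at 1;
#' computed by exact summation of the probability mass function.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability, in (0, 1); default 0.5.
#' @return two-sided p-value.
#' @export
#' @examples
#' two_sided_binomial(21, 26)  # 0.00249..., reported as 0.002
two_sided_binomial <- function(k, n, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  lower <- sum(stats::dbinom(0:k, n, p0))
  upper <- sum(stats::dbinom(k:n, n, p0))
  min(1, 2 * min(lower, upper))
}

#' Odds ratio with Woolf confidence interval from a 2x2 table
#'
#' Cells follow the conventional layout `a` = exposed cases, `b` = exposed
#' non-cases, `c` = unexposed cases, `d` = unexposed non-cases;
#' `OR = ad / bc` with log-scale CI
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param conf confidence level, default 0.95.
#' @param continuity add 0.5 to every cell (Haldane-Anscombe) when any cell
#'   is zero; opt-in, default `FALSE` (a zero cell without it is an error).
#' @return list with `or`, `lower`, `upper`.
#' @export
odds_ratio <- function(a, b, c, d, conf = 0.95, continuity = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells == 0)) {
    if (!continuity)
      stop("zero cell; enable continuity = TRUE for the Haldane-Anscombe correction")
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- a * d / (b * c)
  z <- stats::qnorm((1 + conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression fitted with IRLS; convergence
#' when the maximum absolute score falls below `tol` (default 1e-8) or
#' after `max_iter` iterations.  Detects complete separation (a diverging
#' coefficient beyond `sep_limit`) and rank deficiency explicitly.
#'
#' @param x design matrix (including an intercept column if wanted).
#' @param y 0/1 outcome vector.
#' @param max_iter iteration cap, default 50.
#' @param tol score-convergence tolerance, default 1e-8.
#' @param sep_limit coefficient magnitude treated as separation, default 15.
#' @return list with `coefficients`, `se`, `z`, `p_value` (Wald, two-sided),
#'   `or` (`exp(coefficients)`), `iterations`, `loglik`, `converged`.
#' @export
logistic_fit <- function(x, y, max_iter = 50, tol = 1e-8, sep_limit = 15) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y dimensions disagree")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (n <= p) stop("need more observations than parameters")
  qrx <- qr(x)
  if (qrx$rank < p)
    stop("rank-deficient design; drop column(s): ",
         paste(colnames(x)[qrx$pivot[(qrx$rank + 1):p]], collapse = ", "))
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    score <- drop(crossprod(x, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    z_work <- eta + (y - mu) / w
    fit <- stats::lm.wfit(x, z_work, w)
    beta <- fit$coefficients
    if (any(abs(beta) > sep_limit))
      stop("complete separation detected (diverging coefficient); model not identifiable")
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(x * sqrt(w))
  se <- sqrt(diag(solve(info)))
  zval <- beta / se
  list(coefficients = stats::setNames(beta, colnames(x)),
       se = stats::setNames(se, colnames(x)), z = zval,
       p_value = 2 * stats::pnorm(-abs(zval)),
       or = exp(beta), iterations = it,
       loglik = sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300))),
       converged = converged)
}

#' Length-adjusted mosaic event rate
#'
#' Events per 10,000 Mb of scanned genome:
#' `rate = n_events / (n_individuals * territory_mb / 1e4)`.  This is the
#' package's own definition of the adjustment; it is documented as *not*
#' reproducing previously published per-10,000-Mb rates, whose derivation
#' is not reconstructible from printed quantities (see the methods
#' vignette).
#'
#' @param n_events number of detected events.
#' @param n_individuals individuals scanned.
#' @param territory_mb scanned territory per individual, in Mb.
#' @return events per 10,000 Mb.
#' @export
length_adjusted_rate <- function(n_events, n_individuals, territory_mb) {
  if (n_individuals <= 0 || territory_mb <= 0)
    stop("n_individuals and territory_mb must be positive")
  if (n_events < 0) stop("n_events must be non-negative")
  n_events / (n_individuals * territory_mb / 1e4)
}

#' Welch two-sample t-test
#'
#' Plain unequal-variance comparison of two means (used to compare mean
#' mosaic fractions between groups); standard statistics, included for
#' completeness.
#'
#' @param x,y numeric vectors.
#' @return list with `estimate` (mean difference), `t`, `df`, `p_value`.
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(estimate = mean(x) - mean(y), t = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

#' Default age bins for prevalence-by-age summaries
#' @return numeric vector of cut points (left-closed bins; below the first
#'   cut is the youngest bin, at or above the last is the oldest).
#' @export
default_age_bins <- function() c(50, 55, 60, 65, 70, 75)

#' Summarize detected events against a cohort table
#'
#' Produces deterministic cohort-level tables: counts and proportions by
#' copy state and by location, carrier prevalence overall and per age bin
#' with Wilson intervals, the share of carriers with more than one event,
#' and the mean mosaic fraction among carriers.  Constitutional rows
#' (non-empty `flag`) are excluded from all mosaic tallies.
#'
#' @param calls `data.frame` of [call_events()] rows (whole cohort).
#' @param cohort `data.frame` with at least `sample_id`, `age`; every call's
#'   sample must appear in it.
#' @param age_bins cut points, see [default_age_bins()].
#' @param conf confidence level for Wilson intervals.
#' @return list of `data.frame`s: `by_state`, `by_location`, `prevalence`
#'   (overall), `by_age` (per bin), `multi_event`, `fraction_summary`.
#' @export
summarize_events <- function(calls, cohort, age_bins = default_age_bins(),
                             conf = 0.95) {
  if (is.null(calls$flag)) calls$flag <- rep("", nrow(calls))
  bad <- setdiff(unique(calls$sample_id), cohort$sample_id)
  if (length(bad))
    stop("call sample id(s) absent from the cohort: ",
         paste(bad, collapse = ", "))
  mos <- calls[calls$flag == "", , drop = FALSE]
  states <- c("loss", "copy-neutral", "gain")
  locations <- c("interstitial", "spans centromere", "telomeric p",
                 "telomeric q", "whole")
  n_ev <- nrow(mos)
  by_state <- data.frame(
    state = states,
    n = vapply(states, function(s) sum(mos$state == s), 0L),
    row.names = NULL)
  by_state$proportion <- if (n_ev) by_state$n / n_ev else 0
  by_location <- data.frame(
    location = locations,
    n = vapply(locations, function(l) sum(mos$location == l), 0L),
    row.names = NULL)
  by_location$proportion <- if (n_ev) by_location$n / n_ev else 0
  carriers <- unique(mos$sample_id)
  n_carriers <- length(carriers)
  n_women <- nrow(cohort)
  ci <- wilson_ci(n_carriers, n_women, conf)
  prevalence <- data.frame(n_carriers = n_carriers, n_women = n_women,
                           prevalence = n_carriers / n_women,
                           lower = ci[1], upper = ci[2], row.names = NULL)
  bin <- cut(cohort$age, c(-Inf, age_bins, Inf), right = FALSE)
  is_carrier <- cohort$sample_id %in% carriers
  by_age <- do.call(rbind, lapply(levels(bin), function(b) {
    in_b <- bin == b
    k <- sum(is_carrier & in_b); n <- sum(in_b)
    ci <- if (n) wilson_ci(k, n, conf) else c(NA_real_, NA_real_)
    data.frame(age_bin = b, n = n, carriers = k,
               prevalence = if (n) k / n else NA_real_,
               lower = ci[1], upper = ci[2], row.names = NULL)
  }))
  ev_per <- table(mos$sample_id)
  multi_event <- data.frame(
    n_carriers = n_carriers,
    n_multi = sum(ev_per > 1),
    share = if (n_carriers) sum(ev_per > 1) / n_carriers else 0,
    row.names = NULL)
  fraction_summary <- data.frame(
    n_events = n_ev,
    mean_fraction = if (n_ev) mean(mos$fraction) else NA_real_,
    sd_fraction = if (n_ev > 1) stats::sd(mos$fraction) else NA_real_,
    row.names = NULL)
  list(by_state = by_state, by_location = by_location,
       prevalence = prevalence, by_age = by_age,
       multi_event = multi_event, fraction_summary = fraction_summary)
}
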