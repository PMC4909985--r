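test_that("wilson_ci matches its closed form and contains k/n", {
  expect_equal(unname(wilson_ci(0, 10)[1]), 0)
  ci <- wilson_ci(5, 10)
  expect_equal(unname(sum(ci) / 2 > 0.45 && sum(ci) / 2 < 0.55), TRUE)
  expect_true(ci[1] < 0.5 && ci[2] > 0.5)
  ci97 <- wilson_ci(97, 38303)
  expect_equal(unname(signif(ci97, 3)), c(0.00208, 0.00309))
  for (r in 1:20) {
    set.seed(r)
    n <- sample(1:500, 1); k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_true(ci[1] <= k / n && k / n <= ci[2])
  }
  # width shrinks toward 0 at fixed k/n
  w <- vapply(c(10, 100, 1000, 1e5), function(n) diff(wilson_ci(n / 5, n)), 0)
  expect_true(all(diff(w) < 0))
  expect_error(wilson_ci(5, 0), "at least 1")
})

test_that("two_sided_binomial equals pmf enumeration for all n <= 30", {
  for (n in 1:30) for (k in 0:n)
    expect_lt(abs(two_sided_binomial(k, n) - oracle_two_sided_binomial(k, n)),
              1e-13, label = sprintf("k=%d n=%d", k, n))
  expect_equal(two_sided_binomial(21, 26), 0.00249391794204712,
               tolerance = 1e-8)
  expect_equal(two_sided_binomial(13, 26), 1.0)
  expect_equal(two_sided_binomial(0, 1), 1.0)
  expect_error(two_sided_binomial(2, 10, p0 = 1.5), "p0")
})

test_that("odds ratio and Woolf interval match closed form and bootstrap", {
  expect_equal(odds_ratio(10, 10, 10, 10)$or, 1.0)
  o <- odds_ratio(20, 80, 10, 90)
  expect_equal(o$or, 2.25)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(o$lower, exp(log(2.25) - qnorm(0.975) * se))
  expect_equal(o$upper, exp(log(2.25) + qnorm(0.975) * se))
  expect_error(odds_ratio(0, 80, 10, 90), "continuity")
  oc <- odds_ratio(0, 80, 10, 90, continuity = TRUE)
  expect_equal(oc$or, 0.5 * 90.5 / (80.5 * 10.5))
  # bootstrap oracle: resample the two exposure groups, compare log-OR SD
  set.seed(404)
  B <- 1e5
  a <- rbinom(B, 100, 0.2); c_ <- rbinom(B, 100, 0.1)
  keep <- a > 0 & a < 100 & c_ > 0 & c_ < 100
  lor <- log(a[keep] * (100 - c_[keep]) / ((100 - a[keep]) * c_[keep]))
  expect_equal(sd(lor), se, tolerance = 0.1)
  expect_true(o$lower < 2.25 && 2.25 < o$upper)
})

test_that("IRLS logistic regression matches the 2x2 closed form and glm", {
  # single binary covariate: fitted OR equals the table OR
  x <- cbind(1, c(rep(1, 100), rep(0, 100)))
  y <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  fit <- logistic_fit(x, y)
  expect_equal(unname(fit$or[2]), 2.25, tolerance = 1e-6)
  # agreement with stats::glm on a random design (extra guard)
  set.seed(12)
  xg <- cbind(1, rnorm(500), rbinom(500, 1, 0.4))
  eta <- xg %*% c(-1, 0.8, -0.5)
  yg <- rbinom(500, 1, plogis(eta))
  fg <- logistic_fit(xg, yg)
  gl <- glm(yg ~ xg[, 2] + xg[, 3], family = binomial())
  expect_equal(unname(fg$coefficients), unname(coef(gl)), tolerance = 1e-6)
  expect_equal(unname(fg$se), unname(summary(gl)$coefficients[, 2]),
               tolerance = 1e-4)
  # null covariate stays within 3 SE of zero
  set.seed(13)
  xn <- cbind(1, rnorm(1e4))
  yn <- rbinom(1e4, 1, 0.3)
  fn <- logistic_fit(xn, yn)
  expect_lt(abs(fn$coefficients[2]), 3 * fn$se[2])
  # separation and rank deficiency are explicit errors
  xs <- cbind(1, c(rep(0, 20), rep(1, 20)))
  ys <- c(rep(0, 20), rep(1, 20))
  expect_error(logistic_fit(xs, ys), "separation")
  xr <- cbind(1, 1:30, 2 * (1:30))
  expect_error(logistic_fit(xr, rep(0:1, 15)), "rank-deficient")
})

test_that("length-adjusted rate follows its documented definition", {
  expect_equal(length_adjusted_rate(0, 100, 155), 0)
  expect_equal(length_adjusted_rate(1, 1, 10000), 1.0)
  expect_equal(length_adjusted_rate(124, 38303, 154.9), 0.2089958,
               tolerance = 1e-6)
  expect_error(length_adjusted_rate(1, 0, 155), "positive")
})

test_that("welch_test agrees with t.test", {
  set.seed(3)
  x <- rnorm(40, 0.3, 0.1); y <- rnorm(60, 0.36, 0.12)
  w <- welch_test(x, y)
  tt <- t.test(x, y)
  expect_equal(w$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-8)
})

table1_calls <- function() {
  # the X-column location mix over 124 events, one carrier per event except
  # 15 carriers holding the surplus events so that carriers = 97
  loc <- c(rep("interstitial", 46), rep("spans centromere", 2),
           rep("telomeric p", 4), rep("telomeric q", 12), rep("whole", 60))
  state <- c(rep("loss", 59), rep("copy-neutral", 43), rep("gain", 22))
  owner <- c(paste0("W", sprintf("%03d", 1:97)),
             paste0("W", sprintf("%03d", c(1:15, 1:12))))
  data.frame(sample_id = owner, chrom = "X",
             start_bp = 25e6, end_bp = 60e6, n_probes = 100L,
             state = state, location = loc,
             delta_b = 0.1, delta_lrr = 0, fraction = 0.3, flag = "",
             stringsAsFactors = FALSE)
}

test_that("summarize_events reproduces the printed cohort shares", {
  calls <- table1_calls()
  cohort <- data.frame(sample_id = paste0("W", sprintf("%03d", 1:38303)),
                       age = rep(40:79, length.out = 38303))
  s <- summarize_events(calls, cohort)
  expect_equal(sum(s$by_location$n), 124L)
  whole <- s$by_location$proportion[s$by_location$location == "whole"]
  inter <- s$by_location$proportion[s$by_location$location == "interstitial"]
  expect_equal(round(100 * whole, 1), 48.4)
  expect_equal(round(100 * inter, 1), 37.1)
  expect_equal(s$prevalence$n_carriers, 97L)
  expect_equal(round(100 * s$prevalence$prevalence, 2), 0.25)
  expect_equal(s$multi_event$n_multi, 15L)
  expect_equal(round(100 * s$multi_event$share), 15)
  # proportions sum to 1 within rounding for each breakdown
  expect_equal(sum(s$by_state$proportion), 1)
  expect_equal(sum(s$by_location$proportion), 1)
  # empty input: all-zero tables, no exception
  s0 <- summarize_events(calls[0, ], cohort)
  expect_equal(s0$prevalence$n_carriers, 0L)
  expect_equal(sum(s0$by_state$n), 0L)
  # unjoinable ids error
  bad <- calls; bad$sample_id[1] <- "NOPE"
  expect_error(summarize_events(bad, cohort), "NOPE")
})
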