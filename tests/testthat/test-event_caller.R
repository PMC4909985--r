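test_that("mixture typing recovers band structure by BIC", {
  set.seed(11)
  # split het band: hom tails 0.01/0.99, het at 0.35/0.65, SD 0.03
  x4 <- c(rnorm(175, 0.01, 0.03), rnorm(125, 0.35, 0.03),
          rnorm(125, 0.65, 0.03), rnorm(75, 0.99, 0.03))
  x4 <- pmin(pmax(x4, 0), 1)
  fit <- fit_baf_mixture(x4, delta = 0.15)
  expect_equal(fit$k, 4L)
  expect_lt(abs(fit$delta_b_hat - 0.15), 0.01)
  # normal segment: het band centered at 0.5
  set.seed(12)
  x3 <- pmin(pmax(c(rnorm(175, 0.01, 0.03), rnorm(150, 0.5, 0.03),
                    rnorm(175, 0.99, 0.03)), 0), 1)
  expect_equal(fit_baf_mixture(x3)$k, 3L)
  # complete LOH: homozygous bands only
  set.seed(13)
  x2 <- pmin(pmax(c(rnorm(250, 0.01, 0.03), rnorm(250, 0.99, 0.03)), 0), 1)
  f2 <- fit_baf_mixture(x2)
  expect_equal(f2$k, 2L)
  expect_equal(f2$delta_b_hat, 0)
  expect_error(fit_baf_mixture(rnorm(30, 0.5, 0.02)), "at least 50")
})

test_that("GmmFit invariants hold: sorted means, weights sum to 1", {
  set.seed(14)
  x <- pmin(pmax(c(rnorm(200, 0.01, 0.02), rnorm(100, 0.4, 0.03),
                   rnorm(100, 0.6, 0.03), rnorm(200, 0.99, 0.02)), 0), 1)
  fit <- fit_baf_mixture(x, delta = 0.1)
  expect_equal(fit$means, sort(fit$means))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  expect_gte(fit$delta_b_hat, 0)
})

test_that("copy-state thresholds are +/-0.01 whole, +/-0.05 partial, strict", {
  expect_equal(classify_copy_state(-0.20, TRUE), "loss")
  expect_equal(classify_copy_state(0.02, FALSE), "copy-neutral")
  expect_equal(classify_copy_state(0.02, TRUE), "gain")
  expect_equal(classify_copy_state(0.01, TRUE), "copy-neutral")   # boundary
  expect_equal(classify_copy_state(-0.05, FALSE), "copy-neutral") # boundary
  expect_error(classify_copy_state(NaN, TRUE), "finite")
})

test_that("fraction closed forms match their examples and validate input", {
  expect_equal(estimate_mosaic_fraction(0.15, "copy-neutral"), 0.30)
  expect_equal(estimate_mosaic_fraction(0.125, "loss"), 0.40)
  expect_equal(estimate_mosaic_fraction(1 / 6, "gain"), 1.00)
  for (st in c("loss", "gain", "copy-neutral"))
    expect_equal(estimate_mosaic_fraction(0, st), 0)
  expect_error(estimate_mosaic_fraction(-0.01, "loss"), "non-negative")
  expect_warning(estimate_mosaic_fraction(0.2, "gain"), "capped")
})

test_that("fraction estimation is strictly increasing and inverts the allele-count oracle", {
  db <- seq(0.01, 0.16, by = 0.01)
  for (st in c("loss", "gain", "copy-neutral")) {
    f <- vapply(db, estimate_mosaic_fraction, 0, state = st)
    expect_true(all(diff(f) > 0))
  }
  # oracle: mix f carriers with normals, count alleles, measure the band
  for (st in c("loss", "gain", "copy-neutral")) {
    for (f in c(0.1, 0.25, 0.4, 0.6)) {
      band <- oracle_het_baf(st, f)
      db_obs <- band - 0.5
      expect_equal(estimate_mosaic_fraction(db_obs, st), f, tolerance = 1e-3,
                   label = sprintf("%s f=%.2f", st, f))
      expect_equal(delta_b_for_fraction(st, f), db_obs, tolerance = 1e-3)
    }
  }
})

test_that("location classification matches the fixed vocabulary", {
  map <- tiny_map(400)
  first <- map$position[1]; last <- map$position[400]
  expect_equal(classify_location(first, last, map), "whole")
  expect_equal(classify_location(first, 30e6, map), "telomeric p")
  expect_equal(classify_location(100e6, last, map), "telomeric q")
  expect_equal(classify_location(40e6, 80e6, map), "spans centromere")
  expect_equal(classify_location(70e6, 90e6, map), "interstitial")
  expect_error(classify_location(0, 10e6, map), "outside")
  expect_error(classify_location(10e6, 200e6, map), "outside")
})

test_that("every valid interval gets exactly one location category", {
  map <- tiny_map(400)
  vocab <- c("whole", "telomeric p", "telomeric q", "spans centromere",
             "interstitial")
  set.seed(21)
  s <- runif(1e4, 1, map$chrom_length - 2)
  e <- s + runif(1e4, 1, map$chrom_length - s)
  loc <- mapply(function(a, b) classify_location(a, b, map), s, e)
  expect_true(all(loc %in% vocab))
  expect_equal(length(loc), 1e4L)
})

test_that("constitutional screening removes near-complete whole-X dosage events", {
  calls <- data.frame(
    sample_id = "s", chrom = "X",
    start_bp = c(1, 1, 25e6), end_bp = c(154e6, 154e6, 30e6),
    n_probes = 100L,
    state = c("loss", "loss", "copy-neutral"),
    location = c("whole", "whole", "interstitial"),
    delta_b = 0.2, delta_lrr = -0.2,
    fraction = c(0.98, 0.40, 0.97), flag = "",
    stringsAsFactors = FALSE)
  scr <- screen_constitutional(calls)
  expect_equal(scr$flagged$flag, "XO")
  expect_equal(scr$flagged$fraction, 0.98)
  expect_equal(nrow(scr$retained), 2L)   # mosaic loss and CNLOH retained
  gain <- calls[1, ]; gain$state <- "gain"
  expect_equal(screen_constitutional(gain)$flagged$flag, "trisomy X")
})

test_that("call_events finds planted events and stays quiet on nulls", {
  map <- make_probe_map(2000, seed = 7)
  cfg <- test_config(seed = 42)
  batch <- cluster_batch("B1", 0.5, -0.05)
  params <- call_params(seed = 5)
  no_ev <- data.frame(state = character(), start_bp = numeric(),
                      end_bp = numeric(), fraction = numeric())
  # planted whole-chromosome loss at f = 0.4
  ev <- data.frame(state = "loss", start_bp = map$position[1],
                   end_bp = map$position[2000], fraction = 0.4)
  s <- simulate_sample(ev, map, batch, cfg, seed = 11, sample_id = "T1")
  calls <- call_events(s, map, batch, params)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$state, "loss")
  expect_equal(calls$location, "whole")
  expect_lt(abs(calls$fraction - 0.4), 0.05)
  # event-free sample
  s0 <- simulate_sample(no_ev, map, batch, cfg, seed = 12, sample_id = "N1")
  expect_equal(nrow(call_events(s0, map, batch, params)), 0L)
  # two interstitial CNLOH events (the observed interstitial clusters)
  ev2 <- data.frame(state = rep("copy-neutral", 2),
                    start_bp = c(25e6, 47e6), end_bp = c(30e6, 52e6),
                    fraction = 0.3)
  s2 <- simulate_sample(ev2, map, batch, cfg, seed = 13, sample_id = "T2")
  calls2 <- call_events(s2, map, batch, params)
  expect_equal(nrow(calls2), 2L)
  expect_true(all(calls2$state == "copy-neutral"))
  expect_lt(abs(calls2$start_bp[1] - 25e6), 5e5)
  expect_lt(abs(calls2$end_bp[1] - 30e6), 5e5)
  expect_lt(abs(calls2$start_bp[2] - 47e6), 5e5)
  expect_lt(abs(calls2$end_bp[2] - 52e6), 5e5)
  # no call ever spans < 2 Mb
  expect_true(all(calls2$end_bp - calls2$start_bp >= 2e6))
})
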