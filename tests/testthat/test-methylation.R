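make_ref_matrices <- function(spec) {
  # spec: data.frame(probe_id, mean_w, sd_w, mean_m, sd_m)
  nw <- 30; nm <- 30
  w <- t(mapply(function(m, s, i) exact_stats(nw, m, s, seed = i),
                spec$mean_w, spec$sd_w, seq_len(nrow(spec))))
  m <- t(mapply(function(mu, s, i) exact_stats(nm, mu, s, seed = 100 + i),
                spec$mean_m, spec$sd_m, seq_len(nrow(spec))))
  rownames(w) <- rownames(m) <- spec$probe_id
  list(w = w, m = m)
}

test_that("reference-probe filter applies the box with the stated boundary convention", {
  spec <- data.frame(
    probe_id = paste0("cg", 1:5),
    mean_w = c(0.42, 0.30, 0.42, 0.35, 0.50),  # means inclusive at 0.35/0.50
    sd_w = c(0.05, 0.05, 0.05, 0.05, 0.05),
    mean_m = c(0.08, 0.08, 0.08, 0.08, 0.08),
    sd_m = c(0.03, 0.03, 0.06, 0.03, 0.03))
  mats <- make_ref_matrices(spec)
  ann <- data.frame(probe_id = spec$probe_id, chrom = "X",
                    pos = seq(1e6, 5e6, length.out = 5),
                    promoter_region_id = paste0("PR", 1:5))
  ref <- select_reference_probes(mats$w, mats$m, ann, min_controls = 20)
  expect_equal(ref$passed_filter, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(attr(ref, "n_control_women"), 30)
  expect_error(select_reference_probes(mats$w, mats$m, ann[, -4],
                                       min_controls = 20), "promoter_region_id")
  expect_error(select_reference_probes(mats$w[, 1:5], mats$m, ann), "at least")
})

test_that("expected_beta matches copy bookkeeping and is monotone in f", {
  expect_equal(expected_beta("loss", "Xi", 1, 0.5), 0)
  expect_equal(expected_beta("gain", "Xi", 0.4, 0.5), (1 + 0.4) / (2 + 0.4))
  expect_equal(expected_beta("loss", "Xa", 0.5, 0.5), 1 / 1.5)
  pairs <- expand.grid(state = c("loss", "gain", "copy-neutral"),
                       homolog = c("Xi", "Xa"), stringsAsFactors = FALSE)
  f <- seq(0, 1, by = 0.05)
  for (i in seq_len(nrow(pairs))) {
    b <- vapply(f, function(ff)
      expected_beta(pairs$state[i], pairs$homolog[i], ff, 0.42), 0)
    expect_equal(b[1], 0.42)                       # f = 0 returns beta0
    expect_true(all(diff(b) > 0) || all(diff(b) < 0))  # strictly monotone
    # direction: methylated homolog gained/retained => beta rises
    rising <- (pairs$state[i] == "gain" && pairs$homolog[i] == "Xi") ||
      (pairs$state[i] == "loss" && pairs$homolog[i] == "Xa") ||
      (pairs$state[i] == "copy-neutral" && pairs$homolog[i] == "Xi")
    expect_equal(all(diff(b) > 0), rising)
  }
  expect_error(expected_beta("loss", "Xi", 1.2, 0.5), "fraction")
  expect_error(expected_beta("loss", "Xi", 0.5, 1.2), "beta0")
})

test_that("phase_event maps z-score sign and state to the homolog call", {
  n_probes <- 16
  ref <- data.frame(
    probe_id = paste0("cg", 1:n_probes), pos = seq(20e6, 35e6, length.out = n_probes),
    promoter_region_id = paste0("PR", rep(1:8, each = 2)),
    mean_beta_women = 0.42, sd_beta_women = 0.05,
    mean_beta_men = 0.08, sd_beta_men = 0.03,
    passed_filter = TRUE, stringsAsFactors = FALSE)
  class(ref) <- c("MethylationReference", "data.frame")
  call <- data.frame(sample_id = "W1", state = "loss",
                     start_bp = 19e6, end_bp = 36e6)
  low <- setNames(rep(0.42 - 0.125, n_probes), ref$probe_id)  # z = -2.5
  res <- phase_event(low, ref, call)
  expect_equal(res$homolog_call, "Xi")
  expect_equal(res$interpretation, "loss of Xi")
  expect_equal(res$mean_z, -2.5, tolerance = 1e-9)
  call$state <- "gain"
  high <- setNames(rep(0.42 + 0.15, n_probes), ref$probe_id)  # z = +3
  res2 <- phase_event(high, ref, call)
  expect_equal(res2$interpretation, "gain of Xi")
  call$state <- "copy-neutral"
  expect_equal(phase_event(high, ref, call)$interpretation, "Xi replaced Xa")
  expect_equal(phase_event(low, ref, call)$interpretation, "Xa replaced Xi")
  # fewer than 5 promoter regions => indeterminate regardless of signal
  call3 <- data.frame(sample_id = "W1", state = "loss",
                      start_bp = 19e6, end_bp = ref$pos[6] + 1)
  expect_equal(phase_event(low, ref, call3)$homolog_call, "indeterminate")
  # |mean z| below threshold => indeterminate
  flat <- setNames(rep(0.42 - 0.01, n_probes), ref$probe_id)
  res4 <- phase_event(flat, ref, call)
  expect_equal(res4$homolog_call, "indeterminate")
  # no passing probes inside the event: diagnostic, not an exception
  call4 <- data.frame(sample_id = "W1", state = "loss",
                      start_bp = 100e6, end_bp = 120e6)
  res5 <- phase_event(low, ref, call4)
  expect_equal(res5$homolog_call, "indeterminate")
  expect_match(attr(res5, "diagnostic"), "no passed-filter")
})

test_that("xi_preference_test reproduces the pooled phasing counts", {
  mk <- function(k, n) data.frame(
    state = "loss", homolog_call = c(rep("Xi", k), rep("Xa", n - k)),
    stringsAsFactors = FALSE)
  r <- xi_preference_test(mk(21, 26))
  expect_equal(r$k, 21); expect_equal(r$n, 26)
  expect_equal(r$p_value, 0.00249391794204712, tolerance = 1e-8)
  expect_equal(round(r$p_value, 3), 0.002)
  expect_equal(xi_preference_test(mk(13, 26))$p_value, 1.0)
  expect_equal(xi_preference_test(mk(26, 26))$p_value, 2 * 2^-26)
  empty <- data.frame(state = character(), homolog_call = character())
  expect_error(xi_preference_test(empty), "no phased")
  bad <- mk(3, 5); bad$homolog_call[1] <- "indeterminate"
  expect_error(xi_preference_test(bad), "determinate")
  cn <- mk(3, 5); cn$state <- "copy-neutral"
  expect_error(xi_preference_test(cn), "losses and gains")
})

test_that("synthetic control generator and filter agree exactly", {
  cfg <- test_config(seed = 99)
  truth0 <- data.frame(sample_id = character(), state = character(),
                       homolog = character(), start_bp = numeric(),
                       end_bp = numeric(), fraction = numeric())
  meth <- simulate_methylation(cfg, truth0)
  ref <- select_reference_probes(meth$control_women, meth$control_men,
                                 meth$annotation)
  expect_equal(ref$passed_filter, meth$in_box)
})

test_that("an f = 0 carrier is indistinguishable from controls", {
  cfg <- test_config(seed = 7)
  truth <- data.frame(sample_id = "W1", state = "loss", homolog = "Xi",
                      start_bp = 3e6, end_bp = 150e6, fraction = 0)
  meth <- simulate_methylation(cfg, truth)
  carrier <- meth$carrier_betas[meth$in_box, "W1"]
  ctl <- as.vector(meth$control_women[meth$in_box, 1:5])
  expect_gt(stats::ks.test(carrier, ctl)$p.value, 0.01)
})
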