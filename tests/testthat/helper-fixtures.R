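# Shared fixtures, built in code at test time.

# Small X-like map: 400 probes on a 155 Mb chromosome, hg18-style geometry.
tiny_map <- function(n = 400, seed = 101) {
  make_probe_map(n, hg18_x_geometry(), seed = seed)
}

# Default simulation config for tests (cohort size overridden per test).
test_config <- function(seed = 2024, ...) {
  sim_config(n_women = 10, seed = seed, ...)
}

# A batch with a known baseline.
test_batch <- function(baseline = 0) cluster_batch("B1", 0.5, baseline)

# Vector with exact sample mean and sd (for filter-boundary tests).
exact_stats <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  v <- rnorm(n)
  as.numeric(scale(v)) * sd + mean
}

# Independent R oracle: exhaustive max arc t-statistic over all (i, j).
oracle_max_arc <- function(x) {
  n <- length(x)
  best <- list(stat = -Inf, i = NA, j = NA)
  for (i in 0:(n - 2)) for (j in (i + 1):n) {
    m <- j - i
    if (m == n) next
    arc <- x[(i + 1):j]
    comp <- x[-((i + 1):j)]
    sp2 <- (sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)) / (n - 2)
    t <- if (sp2 <= 1e-24) {
      if (abs(mean(arc) - mean(comp)) > 1e-12) 1e12 else 0
    } else abs(mean(arc) - mean(comp)) / sqrt(sp2 * (1 / m + 1 / (n - m)))
    if (t > best$stat) best <- list(stat = t, i = i, j = j)
  }
  best
}

# Independent binomial pmf by multiplicative recurrence (no pbinom/dbinom).
oracle_binom_pmf <- function(n, p) {
  v <- numeric(n + 1)
  v[1] <- (1 - p)^n
  if (n > 0) for (i in 1:n) v[i + 1] <- v[i] * (n - i + 1) / i * p / (1 - p)
  v
}

oracle_two_sided_binomial <- function(k, n, p = 0.5) {
  v <- oracle_binom_pmf(n, p)
  min(1, 2 * min(sum(v[1:(k + 1)]), sum(v[(k + 1):(n + 1)])))
}

# Brute-force allele-count oracle: expected het-band BAF in a cell mixture
# with N cells of which round(f*N) carry the event (B allele on the
# affected homolog).
oracle_het_baf <- function(state, f, N = 10000) {
  nc <- round(f * N)          # carrier cells
  nn <- N - nc                # normal diploid cells (1 B of 2 alleles)
  b_normal <- nn * 1; a_normal <- nn * 2
  switch(state,
    "loss" = (b_normal + nc * 1) / (a_normal + nc * 1),          # B retained
    "gain" = (b_normal + nc * 2) / (a_normal + nc * 3),          # B duplicated
    "copy-neutral" = (b_normal + nc * 2) / (a_normal + nc * 2))  # B homolog doubled
}
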