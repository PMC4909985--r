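# Synthetic cohorts: SNP-array intensities, methylation matrices and qPCR
# plates with known ground truth, emulating the statistical structure the
# detection pipeline assumes.

#' hg18 (NCBI36) X-chromosome geometry
#'
#' Length 154,913,754 bp; centromere 58.5-61.7 Mb; PAR1 1-2,709,520 and
#' PAR2 154,584,238-end.
#' @return list with `chromosome`, `chrom_length`, `centromere`,
#'   `par_regions`.
#' @export
hg18_x_geometry <- function() {
  list(chromosome = "X", chrom_length = 154913754,
       centromere = c(58.5e6, 61.7e6),
       par_regions = list(c(1, 2709520), c(154584238, 154913754)))
}

#' Simulation configuration
#'
#' Defaults encode the world the detector is built for: a large adult
#' female cohort genotyped on SNP arrays, with age-dependent mosaic-event
#' prevalence, the observed loss:copy-neutral:gain and location mixes,
#' mosaic fractions in the detectable 6-88% range, and noise levels
#' typical of the array family (het BAF SD 0.03, LRR SD 0.15).
#'
#' @param n_women cohort size.
#' @param n_probes X-chromosome probes on the simulated array.
#' @param geometry chromosome geometry, see [hg18_x_geometry()].
#' @param het_rate heterozygous call rate per probe.
#' @param nc_rate no-call rate per probe.
#' @param baf_sd,lrr_sd per-probe noise SDs.
#' @param hom_baf homozygous-band BAF means `c(low, high)`.
#' @param lrr_compression multiplier on the ideal dosage log-ratio (1 =
#'   uncompressed response).
#' @param batches `data.frame` with `batch_id`, `male_fraction`,
#'   `lrr_baseline`; default four batches whose baselines follow an
#'   attenuated mixed-sex clustering offset.
#' @param age_mean,age_sd,age_range age distribution (Normal, truncated).
#' @param prev_intercept,prev_log_or carrier logit
#'   `intercept + log_or * age`; defaults give ~0.11% prevalence at age 45
#'   and ~0.45% at 78 with an odds ratio of 1.04 per year.
#' @param state_probs event-state mix (loss / copy-neutral / gain).
#' @param location_probs event-location mix.
#' @param fraction_beta,fraction_range mosaic fractions drawn from a
#'   `Beta(shape1, shape2)` rescaled to `fraction_range` (defaults give a
#'   right-skewed distribution with mean ~0.30 inside 6-88%).
#' @param multi_event_probs probabilities of 1, 2, 3 events per carrier.
#' @param xi_prob probability an event involves the inactive X.
#' @param n_promoters,probes_per_promoter,decoy_fraction methylation
#'   annotation structure and fraction of probes drawn outside the
#'   differential-methylation filter box.
#' @param n_control_women,n_control_men methylation control counts.
#' @param n_assays,efficiency,ct_noise_sd,n_dilutions qPCR structure.
#' @param seed master seed (mandatory); all child seeds derive from it
#'   deterministically.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(n_women = 500,
                       n_probes = 2000,
                       geometry = hg18_x_geometry(),
                       het_rate = 0.30, nc_rate = 0.002,
                       baf_sd = 0.03, lrr_sd = 0.15,
                       hom_baf = c(0.01, 0.99),
                       lrr_compression = 1,
                       batches = NULL,
                       age_mean = 62, age_sd = 10, age_range = c(30, 95),
                       prev_intercept = -8.58, prev_log_or = log(1.04),
                       state_probs = c("loss" = 59, "copy-neutral" = 43,
                                       "gain" = 22) / 124,
                       location_probs = c("interstitial" = 46,
                                          "spans centromere" = 2,
                                          "telomeric p" = 4,
                                          "telomeric q" = 12,
                                          "whole" = 60) / 124,
                       fraction_beta = c(1.6, 3.5),
                       fraction_range = c(0.06, 0.88),
                       multi_event_probs = c(0.85, 0.12, 0.03),
                       xi_prob = 0.8,
                       n_promoters = 212, probes_per_promoter = 9,
                       decoy_fraction = 0.3,
                       n_control_women = 136, n_control_men = 1665,
                       n_assays = 12, efficiency = 1.0, ct_noise_sd = 0.1,
                       n_dilutions = 6,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a master seed is mandatory")
  if (baf_sd <= 0 || lrr_sd <= 0 || ct_noise_sd <= 0)
    stop("noise SDs must be positive")
  state_probs <- state_probs / sum(state_probs)
  location_probs <- location_probs / sum(location_probs)
  multi_event_probs <- multi_event_probs / sum(multi_event_probs)
  if (is.null(batches)) {
    mf <- c(0, 0.25, 0.5, 0.75)
    batches <- data.frame(batch_id = paste0("B", seq_along(mf)),
                          male_fraction = mf,
                          # attenuated mixed-sex clustering offset
                          lrr_baseline = 0.3 * log2(2 / (2 - mf)),
                          stringsAsFactors = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a probe map
#'
#' Positions are drawn uniformly over non-PAR territory, sorted and unique;
#' deterministic under the seed.
#'
#' @param n_probes number of probes (at least 100).
#' @param geometry see [hg18_x_geometry()].
#' @param seed integer seed.
#' @return A [probe_map()].
#' @export
make_probe_map <- function(n_probes, geometry = hg18_x_geometry(), seed = NULL) {
  if (n_probes < 100) stop("n_probes must be at least 100")
  with_seed_(seed, {
    lo <- 1; hi <- geometry$chrom_length
    ok <- function(p) {
      keep <- rep(TRUE, length(p))
      for (pr in geometry$par_regions)
        keep <- keep & !(p >= pr[1] & p <= pr[2])
      keep
    }
    pos <- numeric(0)
    while (length(pos) < n_probes) {
      cand <- round(stats::runif(2 * n_probes, lo, hi))
      cand <- cand[ok(cand)]
      pos <- unique(c(pos, cand))
    }
    pos <- sort(pos[seq_len(n_probes)])
    probe_map(sprintf("rsX%06d", seq_len(n_probes)), pos,
              chromosome = geometry$chromosome,
              chrom_length = geometry$chrom_length,
              centromere = geometry$centromere,
              par_regions = geometry$par_regions)
  })
}

#' Ideal LRR shift for an event
#' @param state event state.
#' @param f mosaic fraction.
#' @return log2 dosage ratio (0 for copy-neutral).
#' @export
lrr_shift_for_fraction <- function(state, f) {
  state <- match.arg(state, c("loss", "gain", "copy-neutral"))
  switch(state,
         "loss" = log2((2 - f) / 2),
         "gain" = log2((2 + f) / 2),
         "copy-neutral" = 0)
}

#' Simulate one sample's intensity vector
#'
#' Per probe, a genotype is drawn at the configured het rate; heterozygous
#' BAF means inside an event are displaced to `0.5 +/- delta_b(state, f)`
#' (random band per probe), homozygous bands stay at their tails, and LRR
#' means add the batch baseline plus the dosage log-ratio of the event.
#' Gaussian noise is added throughout; BAF is clipped to \[0, 1\].
#'
#' @param events `data.frame` with columns `state`, `start_bp`, `end_bp`,
#'   `fraction` (non-overlapping; may have zero rows).
#' @param map a [probe_map()].
#' @param batch a [cluster_batch()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param sample_id identifier.
#' @return A [sample_intensities()].
#' @export
simulate_sample <- function(events, map, batch, config, seed = NULL,
                            sample_id = "S1") {
  if (nrow(events) > 1) {
    ev <- events[order(events$start_bp), ]
    if (any(ev$start_bp[-1] <= ev$end_bp[-nrow(ev)]))
      stop("events must be non-overlapping")
  }
  with_seed_(seed, {
    n <- length(map$position)
    u <- stats::runif(n)
    geno <- ifelse(u < config$nc_rate, "NC",
            ifelse(u < config$nc_rate + config$het_rate, "AB",
            ifelse(u < config$nc_rate + config$het_rate +
                     (1 - config$nc_rate - config$het_rate) / 2, "AA", "BB")))
    baf_mean <- ifelse(geno == "AA", config$hom_baf[1],
                ifelse(geno == "BB", config$hom_baf[2], 0.5))
    nc <- geno == "NC"
    if (any(nc))  # no-calls sit in one of the three bands anyway
      baf_mean[nc] <- sample(c(config$hom_baf[1], 0.5, config$hom_baf[2]),
                             sum(nc), replace = TRUE,
                             prob = c((1 - config$het_rate) / 2,
                                      config$het_rate,
                                      (1 - config$het_rate) / 2))
    lrr_mean <- rep(batch$lrr_baseline, n)
    for (r in seq_len(nrow(events))) {
      in_ev <- map$position >= events$start_bp[r] &
        map$position <= events$end_bp[r]
      db <- delta_b_for_fraction(events$state[r], events$fraction[r])
      het <- in_ev & baf_mean == 0.5
      side <- sample(c(-1, 1), sum(het), replace = TRUE)
      baf_mean[het] <- 0.5 + side * db
      lrr_mean[in_ev] <- lrr_mean[in_ev] + config$lrr_compression *
        lrr_shift_for_fraction(events$state[r], events$fraction[r])
    }
    baf <- pmin(pmax(baf_mean + stats::rnorm(n, 0, config$baf_sd), 0), 1)
    lrr <- lrr_mean + stats::rnorm(n, 0, config$lrr_sd)
    sample_intensities(sample_id, baf, lrr, geno, batch$batch_id, map)
  })
}

# Draw event bounds for a location class; returns c(start_bp, end_bp).
draw_event_bounds_ <- function(location, map, config) {
  first <- map$position[1]; last <- map$position[length(map$position)]
  cen <- c(map$centromere_start, map$centromere_end)
  log_size <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  switch(location,
    "whole" = c(first, last),
    "telomeric p" = {
      size <- log_size(5e6, min(50e6, last - first - 3e6))
      c(first, first + size)
    },
    "telomeric q" = {
      size <- log_size(5e6, min(50e6, last - first - 3e6))
      c(last - size, last)
    },
    "spans centromere" = {
      s <- stats::runif(1, max(first + 2e6, cen[1] - 30e6), cen[1] - 2e6)
      e <- stats::runif(1, cen[2] + 2e6, min(last - 2e6, cen[2] + 30e6))
      c(s, e)
    },
    "interstitial" = {
      for (i in 1:50) {
        size <- log_size(4e6, 40e6)
        s <- stats::runif(1, first + 2e6, last - 2e6 - size)
        e <- s + size
        if (!(s < cen[1] && e > cen[2])) break  # avoid spanning the centromere
      }
      c(s, e)
    })
}

#' Simulate a cohort with known ground truth
#'
#' Ages are drawn from the configured truncated normal; carrier status is
#' Bernoulli on the logit `intercept + log(1.04) * age`; carriers receive
#' one event (a configurable minority more), with states, locations,
#' fractions and homologs drawn from the configured mixes.  Every planted
#' event is recorded in the truth table.
#'
#' @param config a [sim_config()].
#' @param intensities which samples get full intensity vectors:
#'   `"carriers"` (default), `"all"`, or `"none"` (cohort and truth only,
#'   cheap at large n).
#' @return list with `cohort` (one row per woman), `truth` (one row per
#'   planted event), `samples` (named list of [sample_intensities()]),
#'   `map`, `batches` (list of [cluster_batch()]).
#' @export
simulate_cohort <- function(config,
                            intensities = c("carriers", "all", "none")) {
  stopifnot(inherits(config, "SimulationConfig"))
  intensities <- match.arg(intensities)
  master <- config$seed
  map <- make_probe_map(config$n_probes, config$geometry,
                        seed = child_seed_(master, 1L))
  batches <- lapply(seq_len(nrow(config$batches)), function(i)
    cluster_batch(config$batches$batch_id[i],
                  config$batches$male_fraction[i],
                  config$batches$lrr_baseline[i]))
  names(batches) <- config$batches$batch_id
  n <- config$n_women
  cohort <- truth <- NULL
  with_seed_(child_seed_(master, 2L), {
    age <- round(stats::rnorm(n, config$age_mean, config$age_sd))
    age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
    p_carrier <- stats::plogis(config$prev_intercept + config$prev_log_or * age)
    carrier <- stats::runif(n) < p_carrier
    batch_id <- sample(config$batches$batch_id, n, replace = TRUE)
    anc <- matrix(stats::rgamma(3 * n, shape = rep(c(8, 1, 1), each = n)), n, 3)
    anc <- anc / rowSums(anc)
    cohort <- data.frame(
      sample_id = sprintf("W%05d", seq_len(n)),
      age = age,
      case_status = ifelse(stats::runif(n) < 0.545, "case", "control"),
      dna_source = ifelse(stats::runif(n) < 0.9, "blood", "buccal"),
      anc_european = anc[, 1], anc_african = anc[, 2], anc_asian = anc[, 3],
      study_id = sample(paste0("ST", 1:4), n, replace = TRUE),
      batch_id = batch_id,
      has_x_event = carrier,
      stringsAsFactors = FALSE)
    ev_rows <- list()
    for (i in which(carrier)) {
      n_ev <- sample(seq_along(config$multi_event_probs), 1,
                     prob = config$multi_event_probs)
      placed <- NULL
      for (e in seq_len(n_ev)) {
        state <- sample(names(config$state_probs), 1,
                        prob = config$state_probs)
        clash <- TRUE
        for (try in 1:50) {
          loc <- sample(names(config$location_probs), 1,
                        prob = config$location_probs)
          if (loc == "whole" && n_ev > 1) next  # whole excludes others
          b <- draw_event_bounds_(loc, map, config)
          clash <- !is.null(placed) &&
            any(b[1] <= placed$end_bp & b[2] >= placed$start_bp)
          if (!clash) break
        }
        if (clash) next
        fr <- config$fraction_range[1] +
          diff(config$fraction_range) *
          stats::rbeta(1, config$fraction_beta[1], config$fraction_beta[2])
        row <- data.frame(
          sample_id = sprintf("W%05d", i), state = state,
          homolog = if (stats::runif(1) < config$xi_prob) "Xi" else "Xa",
          start_bp = b[1], end_bp = b[2], fraction = fr,
          location = loc, stringsAsFactors = FALSE)
        placed <- rbind(placed, row)
      }
      ev_rows[[length(ev_rows) + 1L]] <- placed
    }
    truth <- if (length(ev_rows)) do.call(rbind, ev_rows) else
      data.frame(sample_id = character(), state = character(),
                 homolog = character(), start_bp = numeric(),
                 end_bp = numeric(), fraction = numeric(),
                 location = character(), stringsAsFactors = FALSE)
  })
  cohort$x_event_count <- as.integer(table(factor(truth$sample_id,
                                                  cohort$sample_id)))
  cohort$has_x_event <- cohort$x_event_count > 0
  mf <- tapply(truth$fraction, factor(truth$sample_id, cohort$sample_id), mean)
  cohort$mean_fraction <- as.numeric(mf)
  samples <- list()
  if (intensities != "none") {
    who <- if (intensities == "all") seq_len(nrow(cohort)) else
      which(cohort$has_x_event)
    samples <- lapply(who, function(i) {
      sid <- cohort$sample_id[i]
      simulate_sample(truth[truth$sample_id == sid, , drop = FALSE],
                      map, batches[[cohort$batch_id[i]]], config,
                      seed = child_seed_(master, 100L + i),
                      sample_id = sid)
    })
    names(samples) <- cohort$sample_id[who]
  }
  rownames(truth) <- NULL
  list(cohort = cohort, truth = truth, samples = samples,
       map = map, batches = batches)
}

#' Simulate methylation matrices with ground truth
#'
#' Generates an X promoter-probe annotation (promoter regions with a few
#' probes each), control beta matrices for women and men whose probe means
#' sit inside the differential-methylation filter box (with a configurable
#' fraction of out-of-box decoys), and carrier beta vectors in which
#' probes inside a planted event follow [expected_beta()] for the event's
#' state, homolog and fraction.  In-box parameters are drawn with margins
#' wide enough that the sample-statistic filter recovers the in-box set
#' exactly.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_cohort()] (may have zero rows).
#' @param seed integer seed (defaults to a child of the config's master).
#' @return list with `annotation`, `control_women`, `control_men`
#'   (probes x samples matrices), `carrier_betas` (probes x carriers),
#'   `in_box` (logical ground truth of the filter).
#' @export
simulate_methylation <- function(config, truth, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(seed)) seed <- child_seed_(config$seed, 3L)
  with_seed_(seed, {
    npr <- config$n_promoters
    geom <- config$geometry
    prom_pos <- sort(round(stats::runif(npr, 3e6, geom$chrom_length - 1e6)))
    nprobe <- pmax(stats::rpois(npr, config$probes_per_promoter - 3) + 3, 3)
    probe_prom <- rep(seq_len(npr), nprobe)
    pos <- prom_pos[probe_prom] + round(stats::runif(sum(nprobe), 0, 2000))
    total <- length(pos)
    annotation <- data.frame(
      probe_id = sprintf("cg%07d", seq_len(total)),
      chrom = geom$chromosome, pos = pos,
      promoter_region_id = sprintf("PR%03d", probe_prom),
      stringsAsFactors = FALSE)
    in_box <- stats::runif(total) >= config$decoy_fraction
    mean_w <- stats::runif(total, 0.38, 0.47)
    sd_w <- stats::runif(total, 0.04, 0.07)
    mean_m <- stats::runif(total, 0.02, 0.12)
    sd_m <- stats::runif(total, 0.02, 0.04)
    decoy <- which(!in_box)
    kind <- sample(1:4, length(decoy), replace = TRUE)
    mean_w[decoy[kind == 1]] <- stats::runif(sum(kind == 1), 0.58, 0.90)
    sd_w[decoy[kind == 2]] <- stats::runif(sum(kind == 2), 0.12, 0.16)
    mean_m[decoy[kind == 3]] <- stats::runif(sum(kind == 3), 0.25, 0.50)
    # noisy male band: mean raised with the SD so [0,1] clipping cannot
    # shrink the sample SD back inside the filter box
    sd_m[decoy[kind == 4]] <- stats::runif(sum(kind == 4), 0.07, 0.09)
    mean_m[decoy[kind == 4]] <- stats::runif(sum(kind == 4), 0.25, 0.40)
    clip01 <- function(x) pmin(pmax(x, 0), 1)
    nw <- config$n_control_women; nm <- config$n_control_men
    control_women <- clip01(matrix(stats::rnorm(total * nw, mean_w, sd_w),
                                   total, nw))
    control_men <- clip01(matrix(stats::rnorm(total * nm, mean_m, sd_m),
                                 total, nm))
    rownames(control_women) <- rownames(control_men) <- annotation$probe_id
    colnames(control_women) <- sprintf("CW%04d", seq_len(nw))
    colnames(control_men) <- sprintf("CM%04d", seq_len(nm))
    carriers <- unique(truth$sample_id)
    carrier_betas <- matrix(NA_real_, total, length(carriers),
                            dimnames = list(annotation$probe_id, carriers))
    for (s in carriers) {
      mu <- mean_w
      evs <- truth[truth$sample_id == s, , drop = FALSE]
      for (r in seq_len(nrow(evs))) {
        hit <- in_box & pos >= evs$start_bp[r] & pos <= evs$end_bp[r]
        if (any(hit))
          mu[hit] <- expected_beta(evs$state[r], evs$homolog[r],
                                   evs$fraction[r], 0.5) * mean_w[hit] / 0.5
      }
      carrier_betas[, s] <- clip01(stats::rnorm(total, mu, sd_w))
    }
    list(annotation = annotation, control_women = control_women,
         control_men = control_men, carrier_betas = carrier_betas,
         in_box = in_box)
  })
}

#' Simulate qPCR plate tables
#'
#' Builds per-plate standard dilution series (6 concentrations, slope set
#' by the configured amplification efficiency) and triplicate sample wells
#' for the 12 target assays plus the RNase P reference; the target template
#' amount is `ratio / 2` times the reference template, so a diploid-X
#' sample has ratio 2.  Per-sample DNA input varies, exercising the
#' scale-free property of standard-curve quantification.
#'
#' @param ratios named numeric vector of true X copy ratios per sample.
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to a child of the config's master).
#' @param plate_size samples per plate, default 24.
#' @return `data.frame` with columns `plate_id`, `assay_id`, `sample_id`,
#'   `role` (`sample`/`standard`), `dilution_log10` (standards only),
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(ratios, config, seed = NULL, plate_size = 24) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (is.null(seed)) seed <- child_seed_(config$seed, 4L)
  with_seed_(seed, {
    assays <- c(sprintf("XQ%02d", seq_len(config$n_assays)), "RNaseP")
    slope <- -1 / log10(1 + config$efficiency)
    intercept <- stats::setNames(stats::runif(length(assays), 20, 24), assays)
    dil <- seq(1, by = -1, length.out = config$n_dilutions)  # log10 conc
    plates <- if (length(ratios))
      split(names(ratios), ceiling(seq_along(ratios) / plate_size))
    else list(character(0))  # standards-only plate when no samples
    # DNA input varies per sample but is shared by all its assays
    c0 <- stats::setNames(stats::runif(length(ratios), 0.5, 2), names(ratios))
    rows <- list()
    for (p in seq_along(plates)) {
      pid <- sprintf("P%02d", p)
      for (a in assays) {
        # two internal standard curves (pooled male / female gDNA) are run
        # in every plate; both series feed one fitted curve per assay
        for (std in c("STD_M", "STD_F"))
          for (d in dil)
            rows[[length(rows) + 1L]] <- data.frame(
              plate_id = pid, assay_id = a, sample_id = std,
              role = "standard", dilution_log10 = d, replicate = 1:3,
              ct = intercept[[a]] + slope * d +
                stats::rnorm(3, 0, config$ct_noise_sd),
              stringsAsFactors = FALSE)
        for (s in plates[[p]]) {
          conc <- if (a == "RNaseP") c0[[s]] else ratios[[s]] / 2 * c0[[s]]
          # the reference assay is duplexed into every target well, so it
          # accrues one triplicate per target assay
          nrep <- if (a == "RNaseP") 3 * config$n_assays else 3
          rows[[length(rows) + 1L]] <- data.frame(
            plate_id = pid, assay_id = a, sample_id = s,
            role = "sample", dilution_log10 = NA_real_,
            replicate = seq_len(nrep),
            ct = intercept[[a]] + slope * log10(conc) +
              stats::rnorm(nrep, 0, config$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Analyze qPCR plate tables into per-sample copy ratios
#'
#' Fits per-plate standard curves for every assay and runs
#' [x_copy_ratio()] for each sample on its plate's curves.
#'
#' @param plates `data.frame` in the layout written by [simulate_qpcr()].
#' @param reference_assay reference assay id.
#' @return `data.frame` with `sample_id`, `mean_ratio`.
#' @export
analyze_qpcr_plates <- function(plates, reference_assay = "RNaseP") {
  assays <- setdiff(unique(plates$assay_id), reference_assay)
  out <- list()
  for (pid in unique(plates$plate_id)) {
    pl <- plates[plates$plate_id == pid, ]
    std <- pl[pl$role == "standard", ]
    curves <- lapply(stats::setNames(nm = unique(pl$assay_id)), function(a) {
      s <- std[std$assay_id == a, ]
      fit_standard_curve(10^s$dilution_log10, s$ct, assay_id = a)
    })
    for (s in unique(pl$sample_id[pl$role == "sample"])) {
      sc <- pl[pl$role == "sample" & pl$sample_id == s,
               c("assay_id", "replicate", "ct")]
      r <- x_copy_ratio(sc, curves, assays, reference_assay, sample_id = s)
      out[[length(out) + 1L]] <- data.frame(sample_id = s,
                                            mean_ratio = r$mean_ratio,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' True X copy ratio implied by an event
#'
#' `2 * (2 - f) / 2` for losses, `2 * (2 + f) / 2` for gains, 2 for
#' copy-neutral events and non-carriers.
#' @param state event state (or `"none"`).
#' @param f mosaic fraction.
#' @return expected mean qPCR ratio.
#' @export
qpcr_ratio_for_event <- function(state, f) {
  if (state == "none") return(2)
  state <- match.arg(state, c("loss", "gain", "copy-neutral"))
  switch(state, "loss" = 2 - f, "gain" = 2 + f, "copy-neutral" = 2)
}
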