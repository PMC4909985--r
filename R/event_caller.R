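# Event typing: Gaussian-mixture BAF-band structure, copy state from
# adjusted LRR, mosaic-fraction estimation, location classification, and
# constitutional-aneuploidy screening.

#' Fit Gaussian mixtures to a segment's BAF bands
#'
#' Fits univariate Gaussian mixtures with k = 2, 3, 4 components to all BAF
#' values of a candidate segment (homozygotes included) and selects the
#' model with minimum BIC, resolving near-ties (delta BIC < 2) toward the
#' smaller k.  Fixed initializations anchor the fits: k = 2 starts at the
#' homozygous bands (0.05, 0.95); k = 3 adds an undisplaced het band at 0.5;
#' k = 4 replaces it with a split band at `0.5 - delta` / `0.5 + delta`.
#' All parameters are free after initialization, with a component SD floor
#' that prevents degenerate spikes.  A k = 4 winner indicates a mosaic het
#' split with `delta_b_hat = (mu3 - mu2) / 2`.
#'
#' @param baf all BAF values in the segment (at least 50, `NA` dropped).
#' @param delta initial half-separation of the split het band; defaults to
#'   0.1 when unknown.
#' @param sd_floor lower bound on component SDs (default 0.005).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An object of class `GmmFit`: list with `k`, `means`, `sds`,
#'   `weights`, `bic` (named vector for k = 2..4), `delta_b_hat`,
#'   `loglik`, `converged`.
#' @export
fit_baf_mixture <- function(baf, delta = NULL, sd_floor = 0.005,
                            max_iter = 200, tol = 1e-6) {
  x <- baf[!is.na(baf)]
  if (length(x) < 50)
    stop(sprintf("segment has %d BAF values; at least 50 required for mixture typing",
                 length(x)))
  if (is.null(delta) || !is.finite(delta) || delta < 0.02) delta <- 0.1
  delta <- min(delta, 0.45)
  inits <- list(
    `2` = c(0.05, 0.95),
    `3` = c(0.05, 0.5, 0.95),
    `4` = c(0.05, 0.5 - delta, 0.5 + delta, 0.95)
  )
  fits <- lapply(inits, function(mu0) em_gauss_(x, mu0, sd_floor, max_iter, tol))
  ok <- vapply(fits, function(f) f$converged && is.finite(f$loglik), TRUE)
  if (!any(ok))
    stop("Gaussian mixture failed to converge for all k in 2:4; segment rejected")
  bic <- vapply(fits, function(f)
    if (f$converged) -2 * f$loglik + (3 * length(f$means) - 1) * log(length(x)) else Inf, 0)
  # minimum BIC, ties (delta BIC < 2) resolved toward smaller k
  best <- which(bic < min(bic) + 2)[1]
  f <- fits[[best]]
  k <- length(f$means)
  structure(list(
    k = k, means = f$means, sds = f$sds, weights = f$weights,
    bic = stats::setNames(bic, names(inits)),
    delta_b_hat = if (k == 4) (f$means[3] - f$means[2]) / 2 else 0,
    loglik = f$loglik, converged = f$converged
  ), class = "GmmFit")
}

#' @export
print.GmmFit <- function(x, ...) {
  cat(sprintf("GmmFit: k = %d, means = %s, delta_b_hat = %.3f\n",
              x$k, paste(sprintf("%.3f", x$means), collapse = "/"),
              x$delta_b_hat))
  invisible(x)
}

# Univariate Gaussian-mixture EM with fixed mean initialization.
em_gauss_ <- function(x, mu0, sd_floor, max_iter, tol) {
  k <- length(mu0)
  n <- length(x)
  mu <- mu0
  # tight initial SDs: wider ones let narrowly split central components
  # share responsibilities and collapse into the unsplit (k = 3) basin
  sd <- rep(0.02, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 1e-8)) { converged <- FALSE; break }
    w <- nk / n
    mu <- colSums(r * x) / nk
    sd <- vapply(seq_len(k), function(j) {
      v <- sum(r[, j] * (x - mu[j])^2) / nk[j]
      max(sqrt(v), sd_floor)
    }, 0)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  if (!converged && it == max_iter && is.finite(ll_old))
    converged <- TRUE  # slow drift at the iteration cap is still usable
  ord <- order(mu)
  list(means = mu[ord], sds = sd[ord], weights = w[ord],
       loglik = ll_old, converged = converged)
}

#' Assign copy state from a segment's mean adjusted LRR
#'
#' Whole-chromosome events average many probes, so narrow thresholds of
#' +/-0.01 suffice; partial events use the more conservative +/-0.05 because
#' fewer probes span them.  Boundary values are copy-neutral (strict
#' inequalities).
#'
#' @param delta_lrr mean batch-adjusted LRR over the segment (finite).
#' @param whole_flag `TRUE` for whole-chromosome events.
#' @return `"gain"`, `"loss"` or `"copy-neutral"`.
#' @export
classify_copy_state <- function(delta_lrr, whole_flag) {
  if (!is.finite(delta_lrr)) stop("delta_lrr must be finite")
  thr <- if (isTRUE(whole_flag)) 0.01 else 0.05
  if (delta_lrr > thr) "gain" else if (delta_lrr < -thr) "loss" else "copy-neutral"
}

#' Mosaic cell fraction from het-band BAF deviation
#'
#' Closed-form inversions of the allele-dosage model.  With a fraction `f`
#' of cells carrying the event, the displaced heterozygous BAF bands sit at
#' `0.5 +/- delta_b` where
#' copy-neutral: `delta_b = f/2`; loss: `delta_b = (f/2)/(2-f)`;
#' gain: `delta_b = (f/2)/(2+f)`.  Inverting:
#' copy-neutral `f = 2*delta_b`; loss `f = 4*delta_b/(1+2*delta_b)`;
#' gain `f = 4*delta_b/(1-2*delta_b)` (capped at 1 with a warning beyond the
#' pure-trisomic limit `delta_b = 1/6`).
#'
#' @param delta_b het-band deviation in \[0, 0.5\].
#' @param state `"loss"`, `"gain"` or `"copy-neutral"`.
#' @return mosaic fraction in \[0, 1\].
#' @export
#' @examples
#' estimate_mosaic_fraction(0.15, "copy-neutral")  # 0.30
#' estimate_mosaic_fraction(0.125, "loss")         # 0.40
estimate_mosaic_fraction <- function(delta_b, state) {
  if (!is.finite(delta_b) || delta_b < 0)
    stop("delta_b must be non-negative")
  state <- match.arg(state, c("loss", "gain", "copy-neutral"))
  f <- switch(state,
    "copy-neutral" = 2 * delta_b,
    "loss" = 4 * delta_b / (1 + 2 * delta_b),
    "gain" = {
      if (delta_b > 1 / 6) {
        warning(sprintf("delta_b = %.3f exceeds the pure-trisomic limit 1/6; fraction capped at 1",
                        delta_b))
        1
      } else 4 * delta_b / (1 - 2 * delta_b)
    })
  min(max(f, 0), 1)
}

#' Het-band BAF deviation implied by a mosaic fraction
#'
#' Forward direction of the allele-dosage model inverted by
#' [estimate_mosaic_fraction()]; used by the synthetic-data generator and by
#' inverse-consistency tests.
#'
#' @param state `"loss"`, `"gain"` or `"copy-neutral"`.
#' @param f mosaic fraction in \[0, 1\].
#' @return `delta_b` in \[0, 0.5\].
#' @export
delta_b_for_fraction <- function(state, f) {
  if (any(f < 0 | f > 1)) stop("fraction must be in [0, 1]")
  state <- match.arg(state, c("loss", "gain", "copy-neutral"))
  switch(state,
    "copy-neutral" = f / 2,
    "loss" = (f / 2) / (2 - f),
    "gain" = (f / 2) / (2 + f))
}

#' Classify the chromosomal location of an event
#'
#' Categories (mutually exclusive, checked in order): `whole` - both bounds
#' within `end_tol_bp` of the first/last assayed probe; `telomeric p` /
#' `telomeric q` - exactly one bound terminal on the named arm;
#' `spans centromere` - the interval strictly contains the centromere;
#' `interstitial` - otherwise.
#'
#' @param start_bp,end_bp event bounds in base pairs (within the chromosome).
#' @param map a [probe_map()].
#' @param end_tol_bp tolerance for "terminal", default 1 Mb.
#' @return one of `"whole"`, `"telomeric p"`, `"telomeric q"`,
#'   `"spans centromere"`, `"interstitial"`.
#' @export
classify_location <- function(start_bp, end_bp, map, end_tol_bp = 1e6) {
  stopifnot(inherits(map, "ProbeMap"))
  if (start_bp < 1 || end_bp > map$chrom_length || start_bp >= end_bp)
    stop("event bounds outside the chromosome or empty")
  first_bp <- map$position[1]
  last_bp <- map$position[length(map$position)]
  at_p <- abs(start_bp - first_bp) <= end_tol_bp
  at_q <- abs(end_bp - last_bp) <= end_tol_bp
  if (at_p && at_q) return("whole")
  if (at_p) return("telomeric p")
  if (at_q) return("telomeric q")
  if (start_bp < map$centromere_start && end_bp > map$centromere_end)
    return("spans centromere")
  "interstitial"
}

#' Screen out constitutional X aneuploidies
#'
#' Whole-chromosome calls at fraction >= `constitutional_min` are
#' constitutional rather than mosaic: losses flag XO (Turner's syndrome)
#' and gains flag trisomy X.  Flagged samples are excluded from mosaic
#' tallies but reported separately.  Copy-neutral events are never
#' constitutional aneuploidies, whatever their fraction.
#'
#' @param calls `data.frame` of calls for one sample (see [call_events()]).
#' @param constitutional_min fraction threshold, default 0.95.
#' @return list with `retained` (calls minus flagged) and `flagged`
#'   (constitutional rows, with a `flag` column `"XO"` / `"trisomy X"`).
#' @export
screen_constitutional <- function(calls, constitutional_min = 0.95) {
  if (is.null(calls$flag)) calls$flag <- rep("", nrow(calls))
  if (nrow(calls) == 0) return(list(retained = calls, flagged = calls))
  is_const <- calls$location == "whole" & calls$fraction >= constitutional_min &
    calls$state %in% c("loss", "gain")
  flagged <- calls[is_const, , drop = FALSE]
  if (nrow(flagged))
    flagged$flag <- ifelse(flagged$state == "loss", "XO", "trisomy X")
  list(retained = calls[!is_const, , drop = FALSE], flagged = flagged)
}

#' Parameters for the X-mosaicism caller
#'
#' @param alpha,n_perm,min_markers,merge_tol segmentation parameters, see
#'   [cbs_segment()].
#' @param min_size_bp,min_delta_b candidate filters, see [filter_segments()].
#' @param end_tol_bp terminal tolerance for [classify_location()].
#' @param constitutional_min see [screen_constitutional()].
#' @param fraction_ceiling fraction assigned to complete-LOH (k = 2)
#'   segments with corroborating LRR shift; default 0.88, the detection
#'   ceiling observed in validated events.
#' @param seed integer seed controlling permutation reproducibility.
#' @param informative method passed to [select_informative()].
#' @return named list of parameters.
#' @export
call_params <- function(alpha = 0.01, n_perm = 1000, min_markers = 50,
                        merge_tol = 0.005, min_size_bp = 2e6,
                        min_delta_b = 0.03, end_tol_bp = 1e6,
                        constitutional_min = 0.95, fraction_ceiling = 0.88,
                        seed = NULL, informative = "auto") {
  as.list(environment())
}

#' Call mosaic X events for one sample
#'
#' Full per-sample pipeline: informative-probe selection, BAF mirroring,
#' circular binary segmentation, size/deviation filtering, Gaussian-mixture
#' band typing, LRR copy-state assignment, mosaic-fraction estimation,
#' location classification and constitutional screening.  Segments whose
#' best mixture lacks a split het band (k = 3) are rejected as artifacts;
#' k = 2 segments (no het band at all, complete LOH) are retained only with
#' a corroborating LRR shift and reported at the detection-ceiling fraction.
#'
#' @param sample a [sample_intensities()].
#' @param map the matching [probe_map()].
#' @param batch the sample's [cluster_batch()].
#' @param params a [call_params()] list.
#' @return `data.frame` with columns `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_probes` (informative probes in segment), `state`,
#'   `location`, `delta_b`, `delta_lrr`, `fraction`, `flag` (empty string
#'   for mosaic calls; `XO` / `trisomy X` rows are constitutional and are
#'   returned with their flag but excluded by [screen_constitutional()]
#'   semantics downstream), sorted by `start_bp`.  Attribute `"rejected"`
#'   counts segments discarded at the mixture stage.
#' @export
call_events <- function(sample, map, batch, params = call_params()) {
  adj <- adjust_lrr(sample, batch)
  idx <- suppressWarnings(select_informative(sample, map, method = params$informative))
  empty <- empty_calls_()
  if (length(idx) < params$min_markers) {
    warning(sprintf("sample '%s': only %d informative probes; skipped",
                    sample$sample_id, length(idx)))
    return(empty)
  }
  mb <- mirrored_baf(sample$baf[idx])
  pos <- map$position[idx]
  segs <- cbs_segment(mb, pos, alpha = params$alpha, n_perm = params$n_perm,
                      min_markers = params$min_markers,
                      merge_tol = params$merge_tol, seed = params$seed)
  cand <- filter_segments(segs, params$min_size_bp, params$min_delta_b)
  if (nrow(cand) == 0) return(empty)
  rejected <- 0L
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    sbp <- cand$start_bp[r]; ebp <- cand$end_bp[r]
    in_seg <- map$position >= sbp & map$position <= ebp & !in_par(map)
    baf_all <- sample$baf[in_seg]
    d_lrr <- mean(adj[in_seg], na.rm = TRUE)
    location <- classify_location(sbp, ebp, map, params$end_tol_bp)
    whole_flag <- location == "whole"
    fit <- tryCatch(fit_baf_mixture(baf_all, delta = cand$delta_b[r]),
                    error = function(e) NULL)
    if (is.null(fit)) { rejected <- rejected + 1L; next }
    if (fit$k == 3) { rejected <- rejected + 1L; next }
    if (fit$k == 2) {
      thr <- if (whole_flag) 0.01 else 0.05
      if (!is.finite(d_lrr) || abs(d_lrr) <= thr) { rejected <- rejected + 1L; next }
      delta_b <- cand$delta_b[r]
      state <- classify_copy_state(d_lrr, whole_flag)
      fraction <- params$fraction_ceiling
    } else {
      delta_b <- fit$delta_b_hat
      state <- classify_copy_state(d_lrr, whole_flag)
      fraction <- suppressWarnings(estimate_mosaic_fraction(delta_b, state))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample$sample_id, chrom = map$chromosome,
      start_bp = sbp, end_bp = ebp, n_probes = cand$n_probes[r],
      state = state, location = location, delta_b = delta_b,
      delta_lrr = d_lrr, fraction = fraction, flag = "",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) { attr(empty, "rejected") <- rejected; return(empty) }
  calls <- do.call(rbind, rows)
  scr <- screen_constitutional(calls, params$constitutional_min)
  out <- rbind(scr$retained, scr$flagged)  # same columns: flag marks constitutional rows
  out <- out[order(out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

empty_calls_ <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start_bp = numeric(), end_bp = numeric(), n_probes = integer(),
             state = character(), location = character(),
             delta_b = numeric(), delta_lrr = numeric(),
             fraction = numeric(), flag = character(),
             stringsAsFactors = FALSE)
}
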