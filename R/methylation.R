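# X-inactivation phasing from promoter methylation beta values.
#
# Female X promoters carry one methylated (Xi) and one unmethylated (Xa)
# copy, putting control-female beta in the 0.35-0.5 band; men (Xa only) sit
# near 0.  A mosaic event shifts carrier beta toward or away from the
# methylated state depending on which homolog is involved, which is what
# the z-score phasing exploits.

#' Select sex-differentially methylated X promoter probes
#'
#' Computes per-probe control means/SDs for each sex and flags probes that
#' pass the differential-methylation box: mean beta in \[0.35, 0.5\] and
#' SD < 0.09 in women, mean beta < 0.15 and SD < 0.05 in men (means
#' inclusive, SDs strict).
#'
#' @param control_betas_women,control_betas_men numeric matrices, probes in
#'   rows (rownames = probe ids), control samples in columns.
#' @param annotation `data.frame` with columns `probe_id`, `chrom`, `pos`,
#'   `promoter_region_id` covering all matrix rows.
#' @param min_controls minimum controls per sex (default 20).
#' @return A `data.frame` of class `MethylationReference`: one row per
#'   probe with `probe_id`, `pos`, `promoter_region_id`, `mean_beta_women`,
#'   `sd_beta_women`, `mean_beta_men`, `sd_beta_men`, `passed_filter`;
#'   attributes `n_control_women` / `n_control_men`.
#' @export
select_reference_probes <- function(control_betas_women, control_betas_men,
                                    annotation, min_controls = 20) {
  need <- c("probe_id", "chrom", "pos", "promoter_region_id")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (ncol(control_betas_women) < min_controls ||
      ncol(control_betas_men) < min_controls)
    stop(sprintf("need at least %d controls per sex (have %d women, %d men)",
                 min_controls, ncol(control_betas_women), ncol(control_betas_men)))
  ids <- rownames(control_betas_women)
  if (!identical(ids, rownames(control_betas_men)))
    stop("control matrices must share identical probe rows")
  ann <- annotation[match(ids, annotation$probe_id), ]
  if (anyNA(ann$probe_id))
    stop("annotation does not cover all probes in the beta matrices")
  mw <- rowMeans(control_betas_women)
  sw <- apply(control_betas_women, 1, stats::sd)
  mm <- rowMeans(control_betas_men)
  sm <- apply(control_betas_men, 1, stats::sd)
  ref <- data.frame(
    probe_id = ids, pos = ann$pos,
    promoter_region_id = ann$promoter_region_id,
    mean_beta_women = mw, sd_beta_women = sw,
    mean_beta_men = mm, sd_beta_men = sm,
    passed_filter = mw >= 0.35 & mw <= 0.5 & sw < 0.09 & mm < 0.15 & sm < 0.05,
    stringsAsFactors = FALSE)
  rownames(ref) <- NULL
  attr(ref, "n_control_women") <- ncol(control_betas_women)
  attr(ref, "n_control_men") <- ncol(control_betas_men)
  class(ref) <- c("MethylationReference", "data.frame")
  ref
}

#' Expected carrier beta under an event model
#'
#' Copy bookkeeping for a promoter probe that is methylated on Xi and
#' unmethylated on Xa, in a mixture where a fraction `f` of cells carry the
#' event.  The methylated-copy fraction `m` is: loss of Xi `(1-f)/(2-f)`;
#' loss of Xa `1/(2-f)`; gain of Xi `(1+f)/(2+f)`; gain of Xa `1/(2+f)`;
#' copy-neutral with Xi replacing Xa `(1+f)/2`; Xa replacing Xi `(1-f)/2`.
#' Scaled by `beta0 / 0.5` so that `f = 0` returns the normal female mean
#' `beta0`.
#'
#' @param state `"loss"`, `"gain"` or `"copy-neutral"`.
#' @param homolog homolog involved: `"Xi"` or `"Xa"` (for copy-neutral,
#'   the homolog that is *duplicated*, i.e. `"Xi"` means Xi replaced Xa).
#' @param f mosaic fraction in \[0, 1\].
#' @param beta0 normal female mean beta in (0, 1).
#' @return expected carrier beta.
#' @export
#' @examples
#' expected_beta("gain", "Xi", 0.4, 0.5)   # (1+0.4)/(2+0.4) = 0.583
#' expected_beta("loss", "Xa", 0.5, 0.5)   # 1/(2-0.5) = 0.667
expected_beta <- function(state, homolog, f, beta0) {
  state <- match.arg(state, c("loss", "gain", "copy-neutral"))
  homolog <- match.arg(homolog, c("Xi", "Xa"))
  if (any(f < 0 | f > 1)) stop("fraction must be in [0, 1]")
  if (beta0 <= 0 || beta0 >= 1) stop("beta0 must be in (0, 1)")
  m <- switch(paste(state, homolog),
    "loss Xi" = (1 - f) / (2 - f),
    "loss Xa" = 1 / (2 - f),
    "gain Xi" = (1 + f) / (2 + f),
    "gain Xa" = 1 / (2 + f),
    "copy-neutral Xi" = (1 + f) / 2,
    "copy-neutral Xa" = (1 - f) / 2)
  m * beta0 / 0.5
}

#' Phase one detected event to the inactive or active X
#'
#' For passed-filter reference probes inside the event, carrier z-scores
#' against control-female statistics are averaged; the sign of the mean z,
#' combined with the event's copy state, identifies the involved homolog:
#' losses with depressed beta lose Xi, gains with elevated beta gain Xi,
#' copy-neutral events with elevated beta replaced Xa with Xi, and vice
#' versa.  Calls require at least `min_promoters` distinct promoter regions
#' and `|mean z| >= z_threshold`; otherwise the result is indeterminate.
#'
#' @param carrier_betas named numeric vector of the carrier's beta values
#'   (names = probe ids; must cover the reference probes in the event).
#' @param reference a [select_reference_probes()] result.
#' @param call one row of a [call_events()] result (needs `state`,
#'   `start_bp`, `end_bp`, `sample_id`).
#' @param min_promoters minimum promoter regions spanned (default 5).
#' @param z_threshold minimum `|mean z|` for a determinate call
#'   (default 0.5).
#' @return A one-row `data.frame`: `sample_id`, `state`, `start_bp`,
#'   `end_bp`, `n_probes`, `n_promoters`, `mean_z`, `direction`,
#'   `homolog_call` (`Xi`/`Xa`/`indeterminate`), `interpretation`.
#' @export
phase_event <- function(carrier_betas, reference, call,
                        min_promoters = 5, z_threshold = 0.5) {
  stopifnot(inherits(reference, "MethylationReference"))
  in_ev <- reference$passed_filter &
    reference$pos >= call$start_bp & reference$pos <= call$end_bp
  probes <- reference[in_ev, , drop = FALSE]
  res <- data.frame(sample_id = call$sample_id, state = call$state,
                    start_bp = call$start_bp, end_bp = call$end_bp,
                    n_probes = nrow(probes),
                    n_promoters = length(unique(probes$promoter_region_id)),
                    mean_z = NA_real_, direction = NA_character_,
                    homolog_call = "indeterminate",
                    interpretation = "indeterminate",
                    stringsAsFactors = FALSE)
  if (nrow(probes) == 0) {
    attr(res, "diagnostic") <- "no passed-filter reference probes span the event"
    return(res)
  }
  beta <- carrier_betas[probes$probe_id]
  if (anyNA(beta))
    stop("carrier beta values missing for reference probes in the event")
  z <- (beta - probes$mean_beta_women) / probes$sd_beta_women
  res$mean_z <- mean(z)
  res$direction <- if (res$mean_z >= 0) "increase" else "decrease"
  if (res$n_promoters < min_promoters || abs(res$mean_z) < z_threshold)
    return(res)
  up <- res$mean_z > 0
  res$homolog_call <- switch(call$state,
    "loss" = if (up) "Xa" else "Xi",
    "gain" = if (up) "Xi" else "Xa",
    "copy-neutral" = if (up) "Xi" else "Xa")
  res$interpretation <- switch(call$state,
    "loss" = paste("loss of", res$homolog_call),
    "gain" = paste("gain of", res$homolog_call),
    "copy-neutral" = if (up) "Xi replaced Xa" else "Xa replaced Xi")
  res
}

#' Exact binomial test for preferential Xi involvement
#'
#' Pools determinate losses and gains (copy-neutral events are excluded:
#' both homologs change there) and tests whether Xi is involved more often
#' than the 50:50 expectation with a two-sided exact binomial test
#' (tail-doubling, capped at 1).
#'
#' @param results `data.frame` of [phase_event()] rows restricted to
#'   losses and gains with determinate `homolog_call`.
#' @return list with `k` (Xi-involving events), `n`, `p_value`.
#' @export
xi_preference_test <- function(results) {
  if (is.data.frame(results)) {
    if (any(results$homolog_call == "indeterminate"))
      stop("all results must have a determinate homolog call")
    if (any(!results$state %in% c("loss", "gain")))
      stop("restrict results to losses and gains before testing")
    k <- sum(results$homolog_call == "Xi")
    n <- nrow(results)
  } else stop("results must be a data.frame of phasing results")
  if (n == 0) stop("no phased losses/gains to test")
  list(k = k, n = n, p_value = two_sided_binomial(k, n, 0.5))
}
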