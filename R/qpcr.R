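# qPCR relative X copy number: standard curves, ratio quantification,
# 3-SD calling, and concordance with array calls.

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on log10(concentration) over a dilution series.
#' Amplification efficiency follows from the slope:
#' `efficiency = 10^(-1/slope) - 1` (1.0 = perfect doubling,
#' slope -3.3219).
#'
#' @param dilution_concentrations positive concentrations (any consistent
#'   unit), at least 4 points.
#' @param ct_values observed Ct per dilution point.
#' @param assay_id identifier carried on the result.
#' @return An object of class `StandardCurve`: `assay_id`, `slope`,
#'   `intercept`, `efficiency`, `r_squared`.
#' @export
fit_standard_curve <- function(dilution_concentrations, ct_values,
                               assay_id = "assay") {
  if (length(dilution_concentrations) < 4)
    stop("at least 4 dilution points are required")
  if (any(dilution_concentrations <= 0))
    stop("concentrations must be positive")
  if (length(ct_values) != length(dilution_concentrations))
    stop("ct_values and dilution_concentrations must have equal length")
  lx <- log10(dilution_concentrations)
  fit <- stats::lm.fit(cbind(1, lx), ct_values)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope >= 0)
    stop(sprintf("assay '%s': non-negative standard-curve slope (%.3f); invalid curve",
                 assay_id, slope))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ct_values - mean(ct_values))^2)
  structure(list(assay_id = as.character(assay_id), slope = slope,
                 intercept = unname(fit$coefficients[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("StandardCurve %s: slope %.3f, intercept %.2f, efficiency %.3f, R2 %.4f\n",
              x$assay_id, x$slope, x$intercept, x$efficiency, x$r_squared))
  invisible(x)
}

ct_to_conc_ <- function(ct, curve) 10^((ct - curve$intercept) / curve$slope)

#' X copy ratio of one sample from triplicate Ct values
#'
#' For each of the 12 target assays, the median triplicate Ct is
#' interpolated to a concentration through that assay's standard curve; the
#' target:reference concentration ratio is multiplied by 2 (the reference,
#' RNase P, is autosomal and diploid) to give the X copy number in that
#' region, and the 12 assay ratios are averaged.
#'
#' @param sample_cts `data.frame` with columns `assay_id`, `replicate`,
#'   `ct` covering the target assays and the reference assay.
#' @param curves named list of [fit_standard_curve()] objects, one per
#'   assay (targets and reference).
#' @param target_assays character vector of the 12 target assay ids.
#' @param reference_assay reference assay id (default `"RNaseP"`).
#' @param sample_id identifier carried on the result.
#' @return An object of class `QpcrAssayResult`: `sample_id`, `ratios`
#'   (named per-assay), `mean_ratio`, `call` (`NA` until
#'   [call_qpcr_state()]).
#' @export
x_copy_ratio <- function(sample_cts, curves, target_assays,
                         reference_assay = "RNaseP", sample_id = "sample") {
  all_assays <- c(target_assays, reference_assay)
  miss <- setdiff(all_assays, unique(sample_cts$assay_id))
  if (length(miss))
    stop(sprintf("sample '%s': missing Ct values for assay(s): %s",
                 sample_id, paste(miss, collapse = ", ")))
  miss_c <- setdiff(all_assays, names(curves))
  if (length(miss_c))
    stop("no standard curve for assay(s): ", paste(miss_c, collapse = ", "))
  med_ct <- vapply(all_assays, function(a) {
    ct <- sample_cts$ct[sample_cts$assay_id == a]
    if (diff(range(ct)) > 1)
      warning(sprintf("sample '%s', assay '%s': triplicate Ct range %.2f > 1; using the median",
                      sample_id, a, diff(range(ct))))
    stats::median(ct)
  }, 0)
  conc <- vapply(all_assays, function(a) ct_to_conc_(med_ct[[a]], curves[[a]]), 0)
  ratios <- 2 * conc[target_assays] / conc[[reference_assay]]
  structure(list(sample_id = as.character(sample_id),
                 ratios = ratios, mean_ratio = mean(ratios),
                 call = NA_character_),
            class = "QpcrAssayResult")
}

#' Call copy state from a mean qPCR ratio
#'
#' Gains are ratios more than 3 control SDs above the control mean, losses
#' more than 3 SDs below; everything between is normal.
#'
#' @param mean_ratio mean X copy ratio of the sample.
#' @param control_mean,control_sd normal-control ratio mean and SD
#'   (`control_sd > 0`).
#' @param n_sd threshold multiplier, default 3.
#' @return `"gain"`, `"normal"` or `"loss"`.
#' @export
call_qpcr_state <- function(mean_ratio, control_mean, control_sd, n_sd = 3) {
  if (control_sd <= 0) stop("control_sd must be positive")
  if (mean_ratio > control_mean + n_sd * control_sd) "gain"
  else if (mean_ratio < control_mean - n_sd * control_sd) "loss"
  else "normal"
}

#' Concordance between array and qPCR copy-state calls
#'
#' Pairs calls by sample (array copy-neutral maps to qPCR `normal`) and
#' reports per-array-class and overall agreement fractions.
#'
#' @param array_calls named character vector (`loss`/`gain`/`copy-neutral`),
#'   names = sample ids.
#' @param qpcr_calls named character vector (`loss`/`gain`/`normal`).
#' @return list with `per_class` (named agreement fractions by array
#'   class), `overall`, and `n` pairs.
#' @export
concordance <- function(array_calls, qpcr_calls) {
  if (length(array_calls) == 0) stop("no calls to compare")
  unpaired <- setdiff(names(array_calls), names(qpcr_calls))
  if (length(unpaired))
    stop("unpaired sample(s): ", paste(unpaired, collapse = ", "))
  q <- qpcr_calls[names(array_calls)]
  a_mapped <- ifelse(array_calls == "copy-neutral", "normal", array_calls)
  agree <- a_mapped == q
  per_class <- tapply(agree, array_calls, mean)
  list(per_class = per_class[!is.na(per_class)],
       overall = mean(agree), n = length(agree))
}
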