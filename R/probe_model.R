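# Core data model: probe maps, per-sample intensity vectors, batch baselines.

#' Probe map for one chromosome
#'
#' A `ProbeMap` holds the assayed probe positions of one chromosome together
#' with the chromosome geometry needed for event location classification:
#' total length, centromere interval and pseudoautosomal regions (PARs).
#'
#' Positions are 1-based base-pair coordinates, as in Illumina final reports;
#' intervals (`centromere`, `par_regions`) are 1-based inclusive.  BED-style
#' output produced elsewhere in the package converts to 0-based half-open at
#' the file boundary.
#'
#' @param probe_id character vector of probe identifiers.
#' @param position integer vector of 1-based probe positions, strictly
#'   increasing.
#' @param chromosome chromosome label, e.g. `"X"`.
#' @param chrom_length chromosome length in base pairs.
#' @param centromere length-2 numeric `c(start, end)` of the centromere.
#' @param par_regions list of length-2 numeric vectors `c(start, end)`,
#'   non-overlapping pseudoautosomal intervals; may be empty.
#' @return An object of class `ProbeMap`.
#' @export
probe_map <- function(probe_id, position, chromosome = "X",
                      chrom_length, centromere, par_regions = list()) {
  position <- as.numeric(position)
  if (length(probe_id) != length(position))
    stop("probe_id and position must have equal length")
  if (length(position) && any(diff(position) <= 0))
    stop("probe positions must be strictly increasing")
  if (length(position) && (position[1] < 1 || position[length(position)] > chrom_length))
    stop("probe positions must lie in [1, chrom_length]")
  if (length(centromere) != 2 || centromere[1] > centromere[2] ||
      centromere[1] < 1 || centromere[2] > chrom_length)
    stop("centromere interval must lie inside the chromosome")
  par_regions <- lapply(par_regions, as.numeric)
  if (length(par_regions) > 1) {
    m <- do.call(rbind, par_regions)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("PAR intervals must be non-overlapping")
  }
  structure(list(
    probe_id = as.character(probe_id),
    position = position,
    chromosome = as.character(chromosome),
    chrom_length = as.numeric(chrom_length),
    centromere_start = as.numeric(centromere[1]),
    centromere_end = as.numeric(centromere[2]),
    par_regions = par_regions
  ), class = "ProbeMap")
}

#' @export
print.ProbeMap <- function(x, ...) {
  cat(sprintf("ProbeMap: chr%s, %d probes, length %.1f Mb, centromere %.1f-%.1f Mb, %d PAR(s)\n",
              x$chromosome, length(x$position), x$chrom_length / 1e6,
              x$centromere_start / 1e6, x$centromere_end / 1e6,
              length(x$par_regions)))
  invisible(x)
}

#' Logical index of probes falling inside a PAR
#' @param map a [probe_map()].
#' @return logical vector along the map's probes.
#' @export
in_par <- function(map) {
  stopifnot(inherits(map, "ProbeMap"))
  hit <- rep(FALSE, length(map$position))
  for (pr in map$par_regions)
    hit <- hit | (map$position >= pr[1] & map$position <= pr[2])
  hit
}

#' Per-sample intensity vector on a probe map
#'
#' Bundles one woman's B-allele frequencies (BAF), log R ratios (LRR) and
#' genotype calls, aligned to a `ProbeMap`.  Missing values are `NA` (BAF,
#' LRR) or `"NC"` (genotype) and are carried, never dropped.
#'
#' @param sample_id sample identifier.
#' @param baf numeric vector in \[0, 1\] (or `NA`).
#' @param lrr numeric vector of log2 ratios (or `NA`).
#' @param genotype character vector with values `AA`, `AB`, `BB`, `NC`.
#' @param batch_id genotyping-cluster batch identifier.
#' @param map the [probe_map()] the vectors are aligned to.
#' @return An object of class `SampleIntensities`.
#' @export
sample_intensities <- function(sample_id, baf, lrr, genotype, batch_id, map) {
  stopifnot(inherits(map, "ProbeMap"))
  n <- length(map$position)
  if (length(baf) != n || length(lrr) != n || length(genotype) != n)
    stop(sprintf("sample '%s': vectors must match the probe map (%d probes)",
                 sample_id, n))
  baf <- as.numeric(baf)
  ok <- is.na(baf) | (baf >= 0 & baf <= 1)
  if (!all(ok))
    stop(sprintf("sample '%s': BAF values outside [0, 1]", sample_id))
  genotype <- as.character(genotype)
  if (!all(genotype %in% c("AA", "AB", "BB", "NC")))
    stop(sprintf("sample '%s': genotype values must be AA/AB/BB/NC", sample_id))
  structure(list(
    sample_id = as.character(sample_id),
    baf = baf, lrr = as.numeric(lrr), genotype = genotype,
    batch_id = as.character(batch_id)
  ), class = "SampleIntensities")
}

#' @export
print.SampleIntensities <- function(x, ...) {
  cat(sprintf("SampleIntensities: %s (batch %s), %d probes, %.1f%% AB, %d missing BAF\n",
              x$sample_id, x$batch_id, length(x$baf),
              100 * mean(x$genotype == "AB"), sum(is.na(x$baf))))
  invisible(x)
}

#' Batch LRR baseline
#'
#' Expected female X LRR offset for one genotyping-cluster batch.  Batches
#' clustered with many men have depressed female X baselines because the
#' cluster centers are dosage-mixed, so event calling subtracts a per-batch
#' baseline before interpreting LRR shifts.
#'
#' @param batch_id batch identifier.
#' @param male_fraction fraction of men in the original clustering group.
#' @param lrr_baseline expected female X LRR offset (log2 ratio).
#' @return An object of class `ClusterBatch`.
#' @export
cluster_batch <- function(batch_id, male_fraction, lrr_baseline) {
  if (male_fraction < 0 || male_fraction > 1)
    stop("male_fraction must be in [0, 1]")
  if (!is.finite(lrr_baseline)) stop("lrr_baseline must be finite")
  structure(list(batch_id = as.character(batch_id),
                 male_fraction = as.numeric(male_fraction),
                 lrr_baseline = as.numeric(lrr_baseline)),
            class = "ClusterBatch")
}

#' Mirrored B-allele frequency
#'
#' Folds BAF about 0.5: `mBAF = max(baf, 1 - baf)`.  Mirroring collapses the
#' symmetric heterozygous band split caused by mosaicism onto one side so
#' segmentation sees a single shifted mean rather than two diverging bands.
#'
#' @param baf numeric vector in \[0, 1\]; `NA` propagates.
#' @return numeric vector in \[0.5, 1\].
#' @export
#' @examples
#' mirrored_baf(c(0.3, 0.5, 0.92))  # 0.70 0.50 0.92
mirrored_baf <- function(baf) {
  bad <- !is.na(baf) & (baf < 0 | baf > 1)
  if (any(bad)) stop("BAF values outside [0, 1]")
  pmax(baf, 1 - baf)
}

#' Select probes informative for BAF segmentation
#'
#' Returns indices of probes usable as evidence of allelic imbalance:
#' heterozygous calls (`AB`) when genotype calls exist, otherwise probes with
#' BAF inside an open window that retains displaced het bands while excluding
#' the homozygote tails.  PAR probes and probes with missing BAF are always
#' excluded.  Probe order is preserved.
#'
#' @param sample a [sample_intensities()].
#' @param map the matching [probe_map()].
#' @param method `"genotype"` (default when calls exist), `"baf_window"`, or
#'   `"auto"` which uses genotype calls iff any non-`NC` call is present.
#' @param baf_window open interval used by the fallback, default `(0.10, 0.90)`.
#' @return integer vector of probe indices (possibly empty, with a warning).
#' @export
select_informative <- function(sample, map,
                               method = c("auto", "genotype", "baf_window"),
                               baf_window = c(0.10, 0.90)) {
  stopifnot(inherits(sample, "SampleIntensities"), inherits(map, "ProbeMap"))
  method <- match.arg(method)
  has_calls <- any(sample$genotype != "NC")
  if (method == "auto") method <- if (has_calls) "genotype" else "baf_window"
  keep <- if (method == "genotype") {
    sample$genotype == "AB"
  } else {
    !is.na(sample$baf) & sample$baf > baf_window[1] & sample$baf < baf_window[2]
  }
  keep <- keep & !is.na(sample$baf) & !in_par(map)
  idx <- which(keep)
  if (length(idx) == 0)
    warning(sprintf("sample '%s': no informative probes on chr%s; segmentation will be skipped",
                    sample$sample_id, map$chromosome))
  idx
}

#' Estimate a batch's expected female X LRR baseline
#'
#' The baseline is the median over female controls of each control's median
#' X-chromosome LRR: the median-of-medians is robust both to probe-level
#' outliers and to the occasional mosaic carrier among controls.
#'
#' @param samples list of [sample_intensities()] restricted to female
#'   controls of one batch.
#' @param batch_id the batch identifier.
#' @param male_fraction fraction of men in the original genotyping cluster
#'   (carried as metadata; default `NA`).
#' @param min_controls minimum number of controls required (default 20).
#' @return A [cluster_batch()].
#' @export
estimate_batch_baseline <- function(samples, batch_id, male_fraction = NA_real_,
                                    min_controls = 20) {
  if (length(samples) < min_controls)
    stop(sprintf("batch '%s': %d female controls, need at least %d",
                 batch_id, length(samples), min_controls))
  med <- vapply(samples, function(s) stats::median(s$lrr, na.rm = TRUE), 0)
  cluster_batch(batch_id,
                if (is.na(male_fraction)) 0 else male_fraction,
                stats::median(med))
}

#' Subtract a batch baseline from a sample's LRR
#'
#' @param sample a [sample_intensities()].
#' @param batch the sample's [cluster_batch()].
#' @return numeric vector of adjusted LRR; `NA` stays `NA`.
#' @export
adjust_lrr <- function(sample, batch) {
  stopifnot(inherits(sample, "SampleIntensities"))
  if (!inherits(batch, "ClusterBatch"))
    stop(sprintf("sample '%s': unknown batch", sample$sample_id))
  if (!identical(sample$batch_id, batch$batch_id))
    stop(sprintf("sample '%s' belongs to batch '%s', not '%s'",
                 sample$sample_id, sample$batch_id, batch$batch_id))
  sample$lrr - batch$lrr_baseline
}

# Run code with a temporarily-seeded RNG, restoring prior state afterwards.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-unit child seed from a master seed (kept below 2^31).
child_seed_ <- function(master, i) {
  as.integer((as.numeric(master) %% 1e9) * 2 + 104729 * (i %% 10007) + i) %% 2147483647L
}
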