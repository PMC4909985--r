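# Circular binary segmentation of mirrored BAF and candidate filtering.

#' Circular binary segmentation of a mirrored-BAF series
#'
#' Recursive change-point search: at each step the arc (i, j) maximizing the
#' two-sample t-statistic between arc and complement is found over the
#' circularized current stretch; the split is accepted when its permutation
#' p-value (label permutations of the same statistic) falls below `alpha`,
#' and the search recurses into the resulting pieces.  Adjacent output
#' segments whose means differ by less than `merge_tol` are merged back.
#' The returned segments tile the input series.
#'
#' @param values numeric mirrored-BAF series (finite).
#' @param positions base-pair positions, same length as `values`.
#' @param alpha permutation p-value threshold for accepting a split.
#' @param n_perm number of permutations (at least 100).
#' @param min_markers series shorter than this is returned as a single
#'   segment with a warning.
#' @param merge_tol adjacent segments closer than this in mean are merged.
#' @param seed optional integer; permutations are reproducible under it.
#' @return A `data.frame` with one row per segment: `start_idx`, `end_idx`
#'   (1-based inclusive indices into the input), `start_bp`, `end_bp`
#'   (positions of first/last probe in the segment), `n_probes`,
#'   `mean_mbaf`, `delta_b` (`mean_mbaf - 0.5`).
#' @export
cbs_segment <- function(values, positions, alpha = 0.01, n_perm = 1000,
                        min_markers = 50, merge_tol = 0.005, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100 (p-value resolution)")
  n <- length(values)
  if (length(positions) != n) stop("values and positions must have equal length")
  if (n > 0 && any(!is.finite(values))) stop("values must be finite")
  if (n < min_markers) {
    warning(sprintf("series of %d values is shorter than min_markers = %d; returning a single segment",
                    n, min_markers))
    return(segments_from_bounds_(if (n) c(1L, n + 1L) else integer(), values, positions))
  }
  bounds <- with_seed_(seed, cbs_recurse_(values, 1L, n, alpha, n_perm))
  segs <- segments_from_bounds_(bounds, values, positions)
  merge_segments_(segs, values, positions, merge_tol)
}

# Recursive splitter on values[lo..hi] (1-based inclusive); returns sorted
# unique boundary vector b with segments [b[k], b[k+1]) in index space.
cbs_recurse_ <- function(values, lo, hi, alpha, n_perm) {
  n <- hi - lo + 1L
  if (n < 4L) return(c(lo, hi + 1L))
  sp <- .cbs_split_test(values[lo:hi], as.integer(n_perm), alpha)
  if (sp$p >= alpha) return(c(lo, hi + 1L))
  i <- lo + sp$i          # arc is values[i .. j-1] in absolute 1-based terms
  j <- lo + sp$j - 1L
  cuts <- sort(unique(c(lo, i, j + 1L, hi + 1L)))
  out <- integer(0)
  for (k in seq_len(length(cuts) - 1L))
    out <- c(out, cbs_recurse_(values, cuts[k], cuts[k + 1L] - 1L, alpha, n_perm))
  sort(unique(out))
}

segments_from_bounds_ <- function(bounds, values, positions) {
  if (!length(bounds))
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_probes = integer(), mean_mbaf = numeric(),
                      delta_b = numeric()))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L] - 1L
  mean_mbaf <- vapply(seq_along(starts),
                      function(k) mean(values[starts[k]:ends[k]]), 0)
  data.frame(start_idx = as.integer(starts), end_idx = as.integer(ends),
             start_bp = positions[starts], end_bp = positions[ends],
             n_probes = as.integer(ends - starts + 1L),
             mean_mbaf = mean_mbaf, delta_b = mean_mbaf - 0.5)
}

merge_segments_ <- function(segs, values, positions, merge_tol) {
  if (nrow(segs) < 2) return(segs)
  repeat {
    d <- abs(diff(segs$mean_mbaf))
    k <- which(d < merge_tol)
    if (!length(k)) break
    k <- k[which.min(d[k])]
    bounds <- c(segs$start_idx, segs$end_idx[nrow(segs)] + 1L)
    bounds <- bounds[-(k + 1L)]
    segs <- segments_from_bounds_(bounds, values, positions)
    if (nrow(segs) < 2) break
  }
  segs
}

#' Filter candidate mosaic segments by size and BAF deviation
#'
#' Keeps segments at least `min_size_bp` wide (controls the false-positive
#' rate of small spurious splits) whose het-band deviation `delta_b` is at
#' least `min_delta_b`; with `f = 2 * delta_b` for copy-neutral events the
#' default deviation floor corresponds to a mosaic-fraction detection floor
#' of about 6%.
#'
#' @param segments output of [cbs_segment()].
#' @param min_size_bp minimum `end_bp - start_bp`, default 2 Mb.
#' @param min_delta_b minimum mean mirrored-BAF deviation, default 0.03.
#' @return The retained rows (possibly zero), probe indices preserved.
#' @export
filter_segments <- function(segments, min_size_bp = 2e6, min_delta_b = 0.03) {
  keep <- (segments$end_bp - segments$start_bp) >= min_size_bp &
    segments$delta_b >= min_delta_b
  segments[keep, , drop = FALSE]
}
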