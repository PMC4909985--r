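# File formats.  All on-disk coordinates are 1-based inclusive except the
# BED-like calls table, which is 0-based half-open per BED convention.
# '.' denotes missing in the per-probe table.  Package writers prepend
# '#'-prefixed provenance lines; all package readers skip them.

count_comment_lines_ <- function(path) {
  n <- 0L
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

read_table_ <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path)
  data.table::fread(path, sep = sep, skip = count_comment_lines_(path),
                    header = TRUE, data.table = FALSE, na.strings = ".")
}

# Atomic write: temp file in the target directory, then rename.
write_table_ <- function(df, path, sep = "\t", header_lines = character()) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, "w")
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  close(con)
  data.table::fwrite(df, tmp, sep = sep, append = length(header_lines) > 0,
                     col.names = TRUE, na = ".", quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write per-probe intensity tables (final-report layout)
#'
#' Tab-separated with columns `sample_id`, `probe_id`, `chrom`, `pos`,
#' `genotype`, `baf`, `lrr`; `.` denotes missing; one block per sample.
#'
#' @param samples list of [sample_intensities()].
#' @param map the shared [probe_map()].
#' @param path output path.
#' @param header_lines optional provenance comment lines.
#' @return the path, invisibly.
#' @export
write_final_report <- function(samples, map, path, header_lines = character()) {
  blocks <- lapply(samples, function(s)
    data.frame(sample_id = s$sample_id, probe_id = map$probe_id,
               chrom = map$chromosome, pos = map$position,
               genotype = s$genotype,
               baf = round(s$baf, 4), lrr = round(s$lrr, 4),
               stringsAsFactors = FALSE))
  write_table_(do.call(rbind, blocks), path, header_lines = header_lines)
}

#' Read per-probe intensity tables
#'
#' @param path a file written in the [write_final_report()] layout.
#' @param map the [probe_map()] the samples must align to.
#' @param batch_ids optional named character vector sample_id -> batch_id;
#'   defaults to `"B1"`.
#' @return named list of [sample_intensities()].
#' @export
read_final_report <- function(path, map, batch_ids = NULL) {
  df <- read_table_(path)
  need <- c("sample_id", "probe_id", "chrom", "pos", "genotype", "baf", "lrr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("final report is missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$sample_id), function(d) {
    ord <- match(map$probe_id, d$probe_id)
    if (anyNA(ord))
      stop(sprintf("sample '%s' does not cover the probe map", d$sample_id[1]))
    d <- d[ord, ]
    geno <- ifelse(is.na(d$genotype), "NC", d$genotype)
    bid <- if (is.null(batch_ids)) "B1" else batch_ids[[d$sample_id[1]]]
    sample_intensities(d$sample_id[1], d$baf, d$lrr, geno, bid, map)
  })
  out
}

#' Write a probe-map sidecar (probe_id, chrom, pos)
#' @param map a [probe_map()].
#' @param path output path.
#' @param header_lines optional provenance comment lines.
#' @return the path, invisibly.
#' @export
write_probe_map <- function(map, path, header_lines = character()) {
  write_table_(data.frame(probe_id = map$probe_id, chrom = map$chromosome,
                          pos = map$position, stringsAsFactors = FALSE),
               path, header_lines = header_lines)
}

#' Read a probe-map sidecar plus a geometry block
#' @param path sidecar path.
#' @param geometry chromosome geometry list (from the run config), see
#'   [hg18_x_geometry()].
#' @return a [probe_map()].
#' @export
read_probe_map <- function(path, geometry = hg18_x_geometry()) {
  df <- read_table_(path)
  probe_map(df$probe_id, df$pos, chromosome = geometry$chromosome,
            chrom_length = geometry$chrom_length,
            centromere = geometry$centromere,
            par_regions = geometry$par_regions)
}

#' Write detected calls as a BED-like table
#'
#' Tab-separated, 0-based half-open coordinates, columns `chrom`, `start`,
#' `end`, `sample_id`, `state`, `location`, `delta_b`, `delta_lrr`,
#' `fraction`, `n_probes`, `flag`; rows ordered by sample then start.
#'
#' @param calls a [call_events()]-style `data.frame` (1-based bounds).
#' @param path output path.
#' @param header_lines optional provenance comment lines.
#' @return the path, invisibly.
#' @export
write_calls_bed <- function(calls, path, header_lines = character()) {
  bed <- data.frame(chrom = calls$chrom, start = calls$start_bp - 1,
                    end = calls$end_bp, sample_id = calls$sample_id,
                    state = calls$state, location = calls$location,
                    delta_b = round(calls$delta_b, 4),
                    delta_lrr = round(calls$delta_lrr, 4),
                    fraction = round(calls$fraction, 4),
                    n_probes = calls$n_probes, flag = calls$flag,
                    stringsAsFactors = FALSE)
  bed <- bed[order(bed$sample_id, bed$start), , drop = FALSE]
  write_table_(bed, path,
               header_lines = c("coordinates: 0-based half-open (BED)",
                                header_lines))
}

#' Read a BED-like calls table back to 1-based bounds
#' @param path file written by [write_calls_bed()].
#' @return `data.frame` in [call_events()] layout.
#' @export
read_calls_bed <- function(path) {
  bed <- read_table_(path)
  df <- data.frame(sample_id = bed$sample_id, chrom = bed$chrom,
                   start_bp = bed$start + 1, end_bp = bed$end,
                   n_probes = bed$n_probes, state = bed$state,
                   location = bed$location, delta_b = bed$delta_b,
                   delta_lrr = bed$delta_lrr, fraction = bed$fraction,
                   flag = ifelse(is.na(bed$flag), "", bed$flag),
                   stringsAsFactors = FALSE)
  df
}

#' Write / read a beta-value matrix (probes x samples)
#' @param betas numeric matrix with probe rownames and sample colnames.
#' @param path file path.
#' @param header_lines optional provenance comment lines.
#' @return path (write) / matrix (read).
#' @export
write_beta_matrix <- function(betas, path, header_lines = character()) {
  df <- data.frame(probe_id = rownames(betas),
                   signif(betas, 5), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_(df, path, header_lines = header_lines)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  df <- read_table_(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Write / read qPCR plate tables (CSV)
#' @param plates `data.frame` in the [simulate_qpcr()] layout.
#' @param path file path.
#' @param header_lines optional provenance comment lines.
#' @return path (write) / `data.frame` (read).
#' @export
write_plates_csv <- function(plates, path, header_lines = character()) {
  write_table_(plates, path, sep = ",", header_lines = header_lines)
}

#' @rdname write_plates_csv
#' @export
read_plates_csv <- function(path) read_table_(path, sep = ",")
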