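#' The four calibration read totals
#'
#' Container for the unique-alignment read counts of one sample: IP and WCE
#' libraries, each split between the sample genome and the calibration
#' (spike-in) genome.
#'
#' @param ip_sample,ip_calib,wce_sample,wce_calib non-negative integer
#'   unique-read counts.
#' @return A `CalibrationCounts` object.
#' @seealso [occupancy_ratio()], [counts_from_partition()]
#' @export
calibration_counts <- function(ip_sample, ip_calib, wce_sample, wce_calib) {
  x <- list(ip_sample = ip_sample, ip_calib = ip_calib,
            wce_sample = wce_sample, wce_calib = wce_calib)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) != 1 || is.na(v) || v < 0)
      stopf("%s must be a single non-negative count", nm)
  }
  structure(lapply(x, as.numeric), class = "CalibrationCounts")
}

#' @export
print.CalibrationCounts <- function(x, ...) {
  cat(sprintf("CalibrationCounts: IP %s/%s WCE %s/%s (sample/calib), OR = %.4g\n",
              format(x$ip_sample), format(x$ip_calib),
              format(x$wce_sample), format(x$wce_calib),
              tryCatch(occupancy_ratio(x), error = function(e) NA)))
  invisible(x)
}

#' Calibration counts from partitioned IP and WCE libraries
#'
#' @param ip,wce results of [partition_reads()] (or [aligned_from_truth()])
#'   for the IP and WCE libraries.
#' @return A [calibration_counts()] object.
#' @export
counts_from_partition <- function(ip, wce) {
  calibration_counts(ip_sample = nrow(ip$sample$placements),
                     ip_calib = nrow(ip$calib$placements),
                     wce_sample = nrow(wce$sample$placements),
                     wce_calib = nrow(wce$calib$placements))
}

#' Occupancy ratio (OR)
#'
#' The spike-in calibration factor that makes ChIP signal quantitatively
#' comparable between samples:
#' \deqn{OR = \frac{WCE_{calib} \times IP_{sample}}{WCE_{sample} \times IP_{calib}}}
#' computed per sample from that sample's own IP and WCE libraries. It is
#' dimensionless and linear in each count: doubling `ip_sample` doubles OR.
#'
#' @param counts a [calibration_counts()] object.
#' @return Positive scalar.
#' @examples
#' occupancy_ratio(calibration_counts(2e6, 5e5, 1e6, 1e6))  # 4
#' @export
occupancy_ratio <- function(counts) {
  stopifnot(inherits(counts, "CalibrationCounts"))
  if (counts$ip_calib == 0)
    stopf("cannot compute OR: ip_calib (calibration-genome IP reads) is zero")
  if (counts$wce_sample == 0)
    stopf("cannot compute OR: wce_sample (sample-genome WCE reads) is zero")
  if (counts$ip_sample == 0 || counts$wce_calib == 0)
    warning("zero numerator count; OR is 0")
  (counts$wce_calib * counts$ip_sample) / (counts$wce_sample * counts$ip_calib)
}

calibration_factor <- function(counts, denominator) {
  or <- occupancy_ratio(counts)
  denom <- if (is.numeric(denominator)) denominator
           else switch(match.arg(denominator, c("ip_sample", "ip_total")),
                       ip_sample = counts$ip_sample,
                       ip_total = counts$ip_sample + counts$ip_calib)
  if (denom <= 0) stopf("per-million normalization denominator must be > 0")
  list(or = or, denominator = denom, factor = or * 1e6 / denom)
}

#' Calibrate a coverage track or meta-profile
#'
#' Multiplies every value by `OR x 1e6 / denominator`: the sample's
#' occupancy ratio followed by normalization to 1 million reads. The default
#' denominator is the IP library's unique sample-genome read count (the
#' track being scaled); `"ip_total"` uses sample + calibration IP reads, and
#' a plain number may be supplied instead. Calibrating an already-calibrated
#' object is an error — the scale factor is recorded, not compounded.
#'
#' @param x a `CoverageTrack` or `MetaProfile`.
#' @param counts a [calibration_counts()] object.
#' @param denominator `"ip_sample"` (default), `"ip_total"`, or a positive
#'   number.
#' @return The calibrated object; the applied factor, OR and denominator are
#'   stored in its `scale` field.
#' @export
calibrate <- function(x, counts, denominator = "ip_sample") {
  UseMethod("calibrate")
}

#' @export
calibrate.CoverageTrack <- function(x, counts, denominator = "ip_sample") {
  if (isTRUE(x$calibrated))
    stopf("track is already calibrated (factor %.4g)", x$scale$factor)
  sc <- calibration_factor(counts, denominator)
  x$values <- lapply(x$values, function(v) v * sc$factor)
  x$calibrated <- TRUE
  x$scale <- sc
  x
}

#' @export
calibrate.MetaProfile <- function(x, counts, denominator = "ip_sample") {
  if (isTRUE(x$calibrated))
    stopf("profile is already calibrated (factor %.4g)", x$scale$factor)
  sc <- calibration_factor(counts, denominator)
  x$value <- x$value * sc$factor
  x$calibrated <- TRUE
  x$scale <- sc
  x
}

#' Read or write calibration count tables
#'
#' TSV with one row per sample: `sample`, `ip_sample`, `ip_calib`,
#' `wce_sample`, `wce_calib` and the derived `or`.
#'
#' @param counts_list named list of [calibration_counts()] objects.
#' @param path TSV path.
#' @return `write_counts_tsv`: `path` invisibly; `read_counts_tsv`: a named
#'   list of `CalibrationCounts`.
#' @export
write_counts_tsv <- function(counts_list, path) {
  df <- do.call(rbind, lapply(names(counts_list), function(nm) {
    ct <- counts_list[[nm]]
    data.frame(sample = nm, ip_sample = ct$ip_sample, ip_calib = ct$ip_calib,
               wce_sample = ct$wce_sample, wce_calib = ct$wce_calib,
               or = occupancy_ratio(ct))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    calibration_counts(df$ip_sample[i], df$ip_calib[i],
                       df$wce_sample[i], df$wce_calib[i]))
  names(out) <- df$sample
  out
}
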