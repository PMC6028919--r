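meta_profile <- function(offset, value, n, calibrated = FALSE, scale = NULL,
                         units = "coverage") {
  stopifnot(length(offset) == length(value), length(value) == length(n),
            !is.unsorted(offset, strictly = TRUE))
  structure(list(offset = as.integer(offset), value = as.numeric(value),
                 n = as.integer(n), calibrated = calibrated, scale = scale,
                 units = units),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf("MetaProfile: offsets %d..%d bp (%d points), %s, units: %s\n",
              min(x$offset), max(x$offset), length(x$offset),
              if (isTRUE(x$calibrated)) "calibrated" else "uncalibrated",
              x$units))
  invisible(x)
}

#' @export
as.data.frame.MetaProfile <- function(x, ...) {
  data.frame(offset = x$offset, value = x$value, n = x$n)
}

#' Plot a meta-profile
#'
#' @param x a `MetaProfile` (or named list of them, overlaid).
#' @param ... passed to [graphics::plot()].
#' @export
plot.MetaProfile <- function(x, ...) {
  graphics::plot(x$offset, x$value, type = "l",
                 xlab = "Distance from anchor (bp)",
                 ylab = if (x$units == "percent") "Percent of reference"
                        else "Mean coverage", ...)
  graphics::abline(v = 0, lty = 3, col = "grey")
  invisible(x)
}

# Core anchored averaging: windows[i] drawn at anchor + direction * offset,
# averaging only anchors for which the position is on-chromosome.
accumulate_windows <- function(values, chrom, anchor0, direction, offsets) {
  sums <- numeric(length(offsets))
  nn <- integer(length(offsets))
  for (i in seq_along(chrom)) {
    v <- values[[chrom[i]]]
    if (is.null(v)) stopf("track has no chromosome %s", chrom[i])
    idx <- anchor0[i] + direction[i] * offsets + 1L
    ok <- idx >= 1L & idx <= length(v)
    sums[ok] <- sums[ok] + v[idx[ok]]
    nn[ok] <- nn[ok] + 1L
  }
  list(value = ifelse(nn > 0, sums / nn, NA_real_), n = nn)
}

#' Centromere-anchored meta-profile
#'
#' Averages coverage at each signed offset from the CDEIII anchor across
#' chromosomes: the value at offset d is the mean over chromosomes of
#' `coverage(chrom, anchor + d)`, counting only chromosomes whose anchor + d
#' is on-chromosome (anchors closer than `half_width` to a chromosome end
#' contribute truncated windows — "up to" the window, with no zero-padding).
#' Centromere windows are not strand-oriented. Supplying `counts` applies
#' the OR x per-million calibration to the averaged profile (this commutes
#' with averaging, so it equals profiling an already-calibrated track).
#'
#' @param track a `CoverageTrack`.
#' @param anchors named 0-based anchor positions (vector, `(chrom, pos0)`
#'   table, or a `GenomeAnnotation`).
#' @param half_width window half-width in bp (default 60000, i.e. 60 kb
#'   either side).
#' @param counts optional [calibration_counts()]; only valid on an
#'   uncalibrated track.
#' @param denominator see [calibrate()].
#' @return A `MetaProfile` with offsets `-half_width..half_width` and
#'   per-offset contributing-anchor counts.
#' @export
cen_meta_profile <- function(track, anchors, half_width = 60000,
                             counts = NULL, denominator = "ip_sample") {
  stopifnot(inherits(track, "CoverageTrack"))
  anchors <- as_anchors(anchors)
  if (length(anchors) == 0) stopf("anchor set is empty")
  offsets <- seq.int(-half_width, half_width)
  acc <- accumulate_windows(track$values, names(anchors),
                            as.integer(anchors),
                            rep(1L, length(anchors)), offsets)
  prof <- meta_profile(offsets, acc$value, acc$n,
                       calibrated = isTRUE(track$calibrated),
                       scale = track$scale)
  if (!is.null(counts)) {
    if (isTRUE(track$calibrated))
      stopf("track is already calibrated; omit counts")
    prof <- calibrate(prof, counts, denominator)
  }
  prof
}

#' Strand-oriented TSS/TES metagene profiles
#'
#' Averages coverage around gene anchors (TSS or TES), orienting each
#' window by gene strand so positive offsets always point downstream of the
#' anchor (minus-strand windows are reversed). Genes of length <=
#' `min_length` are excluded (the convention "genes longer than 2 kb").
#' With `classes` (e.g. from [classify_gene_pairs()]) a separate profile is
#' produced per gene class, so convergent and tandem genes can be compared.
#'
#' @param track a `CoverageTrack`.
#' @param genes gene annotation (internal table, `GRanges`, BED/GFF path or
#'   `GenomeAnnotation`).
#' @param anchor `"TES"` (default) or `"TSS"`.
#' @param half_width window half-width in bp.
#' @param min_length exclusive minimum gene length in bp (default 2000).
#' @param classes optional per-gene classes: a [classify_gene_pairs()]
#'   result or a character vector named by gene name.
#' @return A `MetaProfile`, or a named list of them (one per class).
#' @export
feature_meta_profile <- function(track, genes, anchor = c("TES", "TSS"),
                                 half_width = 2000, min_length = 2000,
                                 classes = NULL) {
  stopifnot(inherits(track, "CoverageTrack"))
  anchor <- match.arg(anchor)
  if (half_width <= 0) stopf("half_width must be > 0")
  g <- as_gene_table(genes)
  g <- g[(g$end0 - g$start0) > min_length, , drop = FALSE]
  if (nrow(g) == 0) stopf("no genes longer than %d bp survive the filter", min_length)
  anchor0 <- if (anchor == "TES") ifelse(g$strand == "+", g$end0 - 1L, g$start0)
             else ifelse(g$strand == "+", g$start0, g$end0 - 1L)
  direction <- ifelse(g$strand == "+", 1L, -1L)
  offsets <- seq.int(-half_width, half_width)
  one <- function(sel) {
    acc <- accumulate_windows(track$values, g$chrom[sel],
                              as.integer(anchor0[sel]), direction[sel],
                              offsets)
    meta_profile(offsets, acc$value, acc$n,
                 calibrated = isTRUE(track$calibrated), scale = track$scale)
  }
  if (is.null(classes)) return(one(rep(TRUE, nrow(g))))
  if (is.data.frame(classes)) classes <- setNames(classes$class, classes$name)
  cls <- classes[g$name]
  keep <- !is.na(cls)
  if (!any(keep)) stopf("no surviving gene has a class assignment")
  out <- lapply(split(which(keep), cls[keep]), function(ix) {
    sel <- rep(FALSE, nrow(g)); sel[ix] <- TRUE; one(sel)
  })
  out
}

#' Classify genes by the orientation of their nearest neighbour
#'
#' At each gene's TES the partner is the nearest gene lying downstream of
#' the TES (in the gene's direction of transcription, on either strand):
#' partner on the opposite strand is transcribed head-on toward the gene
#' (**convergent**); partner on the same strand is **tandem**; no
#' downstream partner means **boundary**. At the TSS the partner is the
#' nearest gene lying upstream: same strand is tandem, opposite strand is
#' transcribed away (**divergent**). Genes nested inside another gene are
#' assigned the boundary class; overlapping same-strand genes are flagged
#' with a warning.
#'
#' @param genes gene annotation (any representation [feature_meta_profile()]
#'   accepts).
#' @param at classify at the `"TES"` (default) or `"TSS"`.
#' @return Data frame with columns `name`, `chrom`, `strand`, `class`.
#' @export
classify_gene_pairs <- function(genes, at = c("TES", "TSS")) {
  at <- match.arg(at)
  g <- as_gene_table(genes)
  if (nrow(g) == 0) return(data.frame(name = character(), chrom = character(),
                                      strand = character(), class = character()))
  out <- vector("list", 0)
  for (cn in unique(g$chrom)) {
    gc <- g[g$chrom == cn, , drop = FALSE]
    gc <- gc[order(gc$start0, gc$end0), , drop = FALSE]
    n <- nrow(gc)
    nested <- vapply(seq_len(n), function(i)
      any(gc$start0 <= gc$start0[i] & gc$end0 >= gc$end0[i] &
            seq_len(n) != i & (gc$start0 < gc$start0[i] | gc$end0 > gc$end0[i])),
      logical(1))
    ovl_same <- vapply(seq_len(n), function(i)
      any(gc$strand == gc$strand[i] & seq_len(n) != i &
            gc$start0 < gc$end0[i] & gc$end0 > gc$start0[i]), logical(1))
    if (any(ovl_same))
      warning("overlapping same-strand genes on ", cn, ": ",
              paste(gc$name[ovl_same], collapse = ", "))
    cls <- character(n)
    for (i in seq_len(n)) {
      if (nested[i]) { cls[i] <- "boundary"; next }
      fwd <- (gc$strand[i] == "+") == (at == "TES")
      if (fwd) {
        # neighbour toward higher coordinates: nearest gene starting beyond
        # this gene's anchor-side end
        ref <- if (at == "TES") gc$end0[i] - 1L else gc$end0[i] - 1L
        cand <- which(gc$start0 > ref & !nested)
        if (!length(cand)) { cls[i] <- "boundary"; next }
        j <- cand[which.min(gc$start0[cand])]
      } else {
        ref <- gc$start0[i]
        cand <- which(gc$end0 - 1L < ref & !nested)
        if (!length(cand)) { cls[i] <- "boundary"; next }
        j <- cand[which.max(gc$end0[cand])]
      }
      same <- gc$strand[j] == gc$strand[i]
      cls[i] <- if (same) "tandem" else if (at == "TES") "convergent" else "divergent"
    }
    out[[length(out) + 1L]] <- data.frame(name = gc$name, chrom = cn,
                                          strand = gc$strand, class = cls,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Difference between two meta-profiles
#'
#' Offset-wise `a - b`, revealing net redistribution of signal between two
#' conditions or time points (e.g. translocation away from centromeres
#' shows as a negative lobe at the origin with positive flanking lobes).
#' The two profiles must share the same offsets and calibration state; no
#' silent resampling is performed.
#'
#' @param a,b `MetaProfile`s on identical windows.
#' @return A `MetaProfile`; `n` is the per-offset minimum of the inputs.
#' @export
difference_profile <- function(a, b) {
  stopifnot(inherits(a, "MetaProfile"), inherits(b, "MetaProfile"))
  if (!identical(a$offset, b$offset))
    stopf("profiles have mismatched windows; refusing to resample")
  if (!identical(isTRUE(a$calibrated), isTRUE(b$calibrated)))
    stopf("cannot subtract a calibrated from an uncalibrated profile")
  meta_profile(a$offset, a$value - b$value, pmin(a$n, b$n),
               calibrated = a$calibrated, units = a$units)
}

#' Express a profile as a percentage of a reference profile
#'
#' Each value becomes `100 * value / mean(reference)` where the mean is
#' taken over the reference's full window — the percent-of-wild-type
#' convention used to compare mutant and wild-type profiles.
#'
#' @param profile,reference `MetaProfile`s; the reference window mean must
#'   be positive.
#' @return A `MetaProfile` in percent units.
#' @export
percent_of_reference <- function(profile, reference) {
  stopifnot(inherits(profile, "MetaProfile"), inherits(reference, "MetaProfile"))
  ref_mean <- mean(reference$value[reference$n > 0])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stopf("reference profile mean must be > 0")
  meta_profile(profile$offset, 100 * profile$value / ref_mean, profile$n,
               calibrated = profile$calibrated, scale = profile$scale,
               units = "percent")
}

#' Pericentric versus arm coverage summary
#'
#' Splits the genome at `arm_threshold` from the centromere anchors (arms
#' defined as > 30 kb from the CEN by default): `pericentric_mean` is the
#' mean coverage over all positions within the threshold of an anchor,
#' `arm_mean` over everything else, and `ratio` their quotient.
#'
#' @param track a `CoverageTrack` (normally calibrated).
#' @param anchors anchor positions (as in [cen_meta_profile()]).
#' @param arm_threshold distance (bp) from the anchor separating pericentric
#'   from arm positions.
#' @return List with `pericentric_mean`, `arm_mean`, `ratio`.
#' @export
region_summary <- function(track, anchors, arm_threshold = 30000) {
  stopifnot(inherits(track, "CoverageTrack"))
  anchors <- as_anchors(anchors)
  peri <- numeric(0); arm <- numeric(0)
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    a <- anchors[[cn]]
    if (is.null(a) || is.na(a)) { arm <- c(arm, v); next }
    pos <- seq_along(v) - 1L
    m <- abs(pos - a) <= arm_threshold
    peri <- c(peri, v[m]); arm <- c(arm, v[!m])
  }
  if (length(arm) == 0)
    stopf("arm region is empty: threshold %d covers every position", arm_threshold)
  pm <- mean(peri); am <- mean(arm)
  list(pericentric_mean = pm, arm_mean = am, ratio = pm / am)
}

#' Binned two-track comparison with proportional fit
#'
#' Tiles the genome into non-overlapping `bin_size` bins, takes each
#' track's per-bin mean, and fits a least-squares slope through the origin
#' (`b ~ slope * a`), the proportional-occupancy model. Per-bin ratios are
#' reported, and bins whose ratio falls below half the global slope are
#' flagged as reduced-slope candidates.
#'
#' @param track_a,track_b `CoverageTrack`s on the same chromosome set.
#' @param bin_size bin width in bp (>= 1).
#' @return List with `bins` (data frame `chrom`, `start0`, `end0`, `mean_a`,
#'   `mean_b`, `ratio`, `flagged`) and `slope`.
#' @export
track_scatter <- function(track_a, track_b, bin_size) {
  stopifnot(inherits(track_a, "CoverageTrack"), inherits(track_b, "CoverageTrack"))
  if (bin_size < 1) stopf("bin_size must be >= 1")
  if (!identical(sort(names(track_a$values)), sort(names(track_b$values))))
    stopf("tracks cover different chromosome sets")
  rows <- lapply(names(track_a$values), function(cn) {
    va <- track_a$values[[cn]]; vb <- track_b$values[[cn]]
    if (length(va) != length(vb))
      stopf("chromosome %s has different lengths in the two tracks", cn)
    L <- length(va)
    starts <- seq.int(0L, L - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    csa <- c(0, cumsum(va)); csb <- c(0, cumsum(vb))
    data.frame(chrom = cn, start0 = starts, end0 = ends,
               mean_a = (csa[ends + 1L] - csa[starts + 1L]) / (ends - starts),
               mean_b = (csb[ends + 1L] - csb[starts + 1L]) / (ends - starts),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  if (sum(bins$mean_a^2) == 0) stopf("track A is identically zero")
  slope <- sum(bins$mean_a * bins$mean_b) / sum(bins$mean_a^2)
  bins$ratio <- ifelse(bins$mean_a > 0, bins$mean_b / bins$mean_a, NA_real_)
  bins$flagged <- !is.na(bins$ratio) & bins$ratio < 0.5 * slope
  list(bins = bins, slope = slope)
}

#' Write a meta-profile as TSV
#'
#' Columns `offset`, `value`, `n`.
#'
#' @param profile a `MetaProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
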