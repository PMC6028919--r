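#' Quality-control trimming of reads
#'
#' Removes the first `trim5` bases and any base after position `keep_to` of
#' each read, then drops reads whose trimmed length is below `min_len`.
#' Defaults follow the Ion Torrent single-end convention of removing the
#' first 10 bases and everything after the 200th, then discarding reads
#' shorter than 50 bp. Read order is preserved; per-read qualities stored in
#' `mcols(reads)$qualities` (as returned by [read_fastq()]) are trimmed in
#' step with the sequences.
#'
#' @param reads a [Biostrings::DNAStringSet] (or character vector).
#' @param trim5 number of 5' bases to remove (>= 0).
#' @param keep_to last base position to keep (1-based, in the untrimmed
#'   read); `Inf` keeps to the end. Must exceed `trim5`.
#' @param min_len minimum trimmed length; shorter reads are dropped.
#' @return The trimmed, filtered read set.
#' @examples
#' r <- Biostrings::DNAStringSet(c(a = strrep("ACGT", 55), b = strrep("A", 55)))
#' Biostrings::width(qc_trim(r))  # 220 bp -> 190 bp; 55 bp read dropped
#' @export
qc_trim <- function(reads, trim5 = 10, keep_to = 200, min_len = 50) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (trim5 < 0) stopf("trim5 must be >= 0")
  if (keep_to <= trim5) stopf("keep_to must be greater than trim5")
  w <- Biostrings::width(reads)
  end <- pmin(keep_to, w)
  keep <- (end - trim5) >= max(min_len, 1) & w > trim5
  out <- reads[keep]
  if (length(out)) {
    out <- Biostrings::subseq(out, start = trim5 + 1L, end = end[keep])
    q <- S4Vectors::mcols(reads)$qualities
    if (!is.null(q)) {
      S4Vectors::mcols(out)$qualities <-
        Biostrings::subseq(q[keep], start = trim5 + 1L, end = end[keep])
    }
  }
  out
}

aligned_read_set <- function(genome, placements, source, chrom_lengths = NULL) {
  structure(list(genome = genome, placements = placements, source = source,
                 chrom_lengths = chrom_lengths),
            class = "AlignedReadSet")
}

#' @export
print.AlignedReadSet <- function(x, ...) {
  cat(sprintf("AlignedReadSet (%s genome, %s): %d unique placements\n",
              x$genome, x$source, nrow(x$placements)))
  invisible(x)
}

# All exact full-length placements of each read in a genome, both strands.
# Returns per-read placement counts and the placement table for reads with
# exactly one (deduplicated) location.
exact_placements <- function(reads, genome) {
  n <- length(reads)
  counts <- integer(n)
  plc <- list()
  widths <- Biostrings::width(reads)
  freq <- Biostrings::letterFrequency(reads, c("A", "C", "G", "T"))
  clean <- rowSums(freq) == widths & widths > 0
  max_len <- max(Biostrings::width(genome))
  too_long <- widths > max_len
  if (any(too_long))
    warning(sum(too_long), " read(s) longer than every chromosome; unassigned")
  for (w in unique(widths[clean & !too_long])) {
    grp <- which(clean & widths == w)
    sub <- reads[grp]
    pd_f <- Biostrings::PDict(sub)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(sub))
    for (cn in names(genome)) {
      subj <- genome[[cn]]
      if (length(subj) < w) next
      for (pd in list(pd_f, pd_r)) {
        mi <- Biostrings::matchPDict(pd, subj)
        cnt <- S4Vectors::elementNROWS(mi)
        hit <- which(cnt > 0)
        if (!length(hit)) next
        st <- Biostrings::startIndex(mi)
        plc[[length(plc) + 1L]] <- data.frame(
          read = grp[rep(hit, cnt[hit])],
          chrom = cn,
          start0 = unlist(st[hit], use.names = FALSE) - 1L,
          width = w, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(plc)) {
    all_p <- do.call(rbind, plc)
    # a palindromic read matches the same interval on both strands: one locus
    all_p <- all_p[!duplicated(all_p[c("read", "chrom", "start0")]), ,
                   drop = FALSE]
    tab <- table(all_p$read)
    counts[as.integer(names(tab))] <- as.integer(tab)
    uniq <- all_p[counts[all_p$read] == 1L, , drop = FALSE]
  } else {
    uniq <- data.frame(read = integer(), chrom = character(),
                       start0 = integer(), width = integer())
  }
  list(counts = counts, unique = uniq)
}

#' Partition reads between calibration and sample genomes
#'
#' Sequential two-genome assignment mirroring the calibrated ChIP-seq
#' alignment contract: reads are matched against the calibration genome
#' first; a read with exactly one exact full-length match (either strand)
#' is assigned there. Reads with no calibration match are then matched
#' against the sample genome under the same uniqueness rule. Reads matching
#' neither genome, or matching a genome at more than one locus, are
#' unassigned. Matching is exact full-length string matching — gapped or
#' mismatched alignment of real data enters via [import_alignments()]
#' instead. Reverse-complement matches are reported as the forward-strand
#' interval they cover; strand is not retained.
#'
#' @param reads a [Biostrings::DNAStringSet] (e.g. [qc_trim()] output).
#' @param calib_genome,sample_genome named [Biostrings::DNAStringSet]s (e.g.
#'   the `calib` and `sample` elements of a `ToyGenomePair`).
#' @return List with `calib` and `sample` (`AlignedReadSet`s whose
#'   `placements` are `(read_id, chrom, start0, end0)`) and `unassigned`
#'   (the remaining reads). `|calib| + |sample| + |unassigned| = |reads|`.
#' @export
partition_reads <- function(reads, calib_genome, sample_genome) {
  if (is.character(reads)) {
    nm <- names(reads)
    reads <- Biostrings::DNAStringSet(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read_%07d", seq_along(reads))
  pc <- exact_placements(reads, calib_genome)
  calib_idx <- which(pc$counts == 1L)
  rest <- which(pc$counts == 0L)
  ps <- exact_placements(reads[rest], sample_genome)
  sample_idx <- rest[ps$counts == 1L]
  mk <- function(res, idx_map, genome, seqs) {
    u <- res$unique
    data.frame(read_id = names(reads)[idx_map[u$read]],
               chrom = u$chrom, start0 = u$start0,
               end0 = u$start0 + u$width, stringsAsFactors = FALSE)
  }
  calib_pl <- mk(pc, seq_along(reads))
  sample_pl <- mk(ps, rest)
  assigned <- c(calib_idx, sample_idx)
  unassigned <- reads[setdiff(seq_along(reads), assigned)]
  list(
    calib = aligned_read_set("calibration", calib_pl, "pseudo",
                             setNames(Biostrings::width(calib_genome),
                                      names(calib_genome))),
    sample = aligned_read_set("sample", sample_pl, "pseudo",
                              setNames(Biostrings::width(sample_genome),
                                       names(sample_genome))),
    unassigned = unassigned)
}

#' Build AlignedReadSets from a simulation truth table
#'
#' Converts the ground-truth read origins of a [simulate_experiment()]
#' result directly into `AlignedReadSet`s, bypassing the pseudo-aligner.
#' On substring-disjoint toy genomes this is exactly what
#' [partition_reads()] recovers.
#'
#' @param sim a `ChipSimulation`.
#' @param pair the `ToyGenomePair` the simulation was drawn from.
#' @param library `"ip"` or `"wce"`.
#' @return List with `sample` and `calib` `AlignedReadSet`s.
#' @export
aligned_from_truth <- function(sim, pair, library = c("ip", "wce")) {
  stopifnot(inherits(sim, "ChipSimulation"), inherits(pair, "ToyGenomePair"))
  library <- match.arg(library)
  tt <- sim$truth[[library]]
  rl <- sim$truth$config$read_length
  mk <- function(genome_label, seqs) {
    t1 <- tt[tt$genome == genome_label, , drop = FALSE]
    aligned_read_set(
      if (genome_label == "sample") "sample" else "calibration",
      data.frame(read_id = t1$read_id, chrom = t1$chrom, start0 = t1$start0,
                 end0 = t1$start0 + rl, stringsAsFactors = FALSE),
      "pseudo",
      setNames(Biostrings::width(seqs), names(seqs)))
  }
  list(sample = mk("sample", pair$sample),
       calib = mk("calibration", pair$calib))
}

read_one_alignment_file <- function(path, genome_label) {
  bam <- tryCatch({
    if (grepl("\\.sam$", path, ignore.case = TRUE))
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE)
    else path
  }, error = function(e) stopf("failed to parse %s: %s", path, conditionMessage(e)))
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("qname", "rname", "pos", "cigar"))
  x <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                error = function(e) stopf("failed to parse %s: %s", path,
                                          conditionMessage(e)))
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar)
  pl <- data.frame(read_id = x$qname, chrom = as.character(x$rname),
                   start0 = x$pos - 1L, end0 = x$pos - 1L + rw,
                   stringsAsFactors = FALSE)
  # unique placements only: one primary record per read
  pl <- pl[!duplicated(pl$read_id), , drop = FALSE]
  aligned_read_set(genome_label, pl, "imported", hdr)
}

#' Import externally produced alignments
#'
#' Reads the sample- and calibration-genome SAM/BAM files produced by an
#' external aligner run in the sequential two-genome mode (align to the
#' calibration genome, re-align the unaligned reads to the sample genome).
#' Unmapped, secondary and supplementary records are ignored; one primary
#' placement per read is kept.
#'
#' @param sam_or_bam_sample,sam_or_bam_calib paths to SAM or BAM files.
#' @return List with `sample` and `calib` `AlignedReadSet`s
#'   (`source = "imported"`).
#' @export
import_alignments <- function(sam_or_bam_sample, sam_or_bam_calib) {
  s <- read_one_alignment_file(sam_or_bam_sample, "sample")
  c_ <- read_one_alignment_file(sam_or_bam_calib, "calibration")
  if (nrow(s$placements) == 0 && nrow(c_$placements) == 0)
    stopf("no mapped records in %s or %s", sam_or_bam_sample, sam_or_bam_calib)
  list(sample = s, calib = c_)
}

#' Export an AlignedReadSet as SAM
#'
#' Writes minimal single-end SAM records (flag 0, full-match CIGAR, no
#' stored sequence), sufficient to round-trip placements through
#' [import_alignments()].
#'
#' @param aligned an `AlignedReadSet` with known `chrom_lengths`.
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
export_alignments <- function(aligned, path) {
  stopifnot(inherits(aligned, "AlignedReadSet"))
  cl <- aligned$chrom_lengths
  if (is.null(cl)) stopf("chromosome lengths unknown; cannot write SAM header")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(cl), as.integer(cl)))
  p <- aligned$placements
  body <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                  p$read_id, p$chrom, p$start0 + 1L, p$end0 - p$start0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
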