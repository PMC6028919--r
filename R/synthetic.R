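#' Construct a genome annotation
#'
#' Bundles the three pieces of annotation the pipeline needs: chromosome
#' lengths, one CDEIII (centromere) anchor per chromosome, and stranded gene
#' intervals. Coordinates are 0-based, half-open throughout the package;
#' 1-based coordinates appear only at the VCF/GFF boundary.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param anchors named numeric vector of 0-based CDEIII positions, one per
#'   chromosome; must lie strictly inside the chromosome.
#' @param genes data frame with columns `chrom`, `start0`, `end0`, `strand`
#'   (`"+"`/`"-"`) and `name`.
#' @return A `GenomeAnnotation` object.
#' @export
genome_annotation <- function(chrom_lengths, anchors, genes) {
  if (is.null(names(chrom_lengths)) || anyNA(chrom_lengths))
    stopf("chrom_lengths must be a named vector without NAs")
  anchors <- as_anchors(anchors)
  bad <- names(anchors)[!(names(anchors) %in% names(chrom_lengths))]
  if (length(bad)) stopf("anchor on unknown chromosome: %s", bad[1])
  inside <- anchors > 0 & anchors < chrom_lengths[names(anchors)] - 1
  if (!all(inside))
    stopf("CDEIII anchor not strictly inside chromosome: %s",
          names(anchors)[!inside][1])
  genes <- as_gene_table(genes)
  if (nrow(genes)) {
    if (!all(genes$strand %in% c("+", "-")))
      stopf("gene strands must be '+' or '-'")
    len <- chrom_lengths[genes$chrom]
    if (anyNA(len) || any(genes$start0 < 0) || any(genes$end0 > len) ||
        any(genes$end0 <= genes$start0))
      stopf("gene intervals must lie within chromosome bounds")
  }
  structure(list(chrom_lengths = chrom_lengths, anchors = anchors,
                 genes = genes),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d chromosomes (%.0f bp total), %d anchors, %d genes\n",
              length(x$chrom_lengths), sum(as.numeric(x$chrom_lengths)),
              length(x$anchors), nrow(x$genes)))
  invisible(x)
}

# Reject genome pairs sharing any read-length substring (either strand), or
# repeating one internally. Checking k-mers at k <= read_length is
# conservative: uniqueness at smaller k implies uniqueness at read length.
kmer_collision <- function(sample_seqs, calib_seqs, k) {
  windows <- function(ss) {
    unlist(lapply(as.character(ss), function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      i <- seq_len(n - k + 1)
      substring(s, i, i + k - 1)
    }), use.names = FALSE)
  }
  both <- function(ss) c(windows(ss), windows(Biostrings::reverseComplement(ss)))
  anyDuplicated(c(both(sample_seqs), both(calib_seqs))) > 0
}

place_genes <- function(chrom, L, n_genes, min_long = 2100) {
  slot <- L %/% n_genes
  if (slot < min_long + 500)
    stopf("chromosome %s too short to hold %d genes > 2 kb", chrom, n_genes)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  # Force the leading pattern so convergent, divergent and tandem neighbour
  # pairs are all guaranteed to occur in every annotation.
  if (n_genes >= 4) strand[1:4] <- c("+", "-", "+", "+")
  else if (n_genes >= 2) strand[1:2] <- c("+", "-")
  max_long <- min(5000, slot - 400)
  len <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    # ~1 in 5 genes is short so the > 2 kb metagene filter has work to do
    len[i] <- if (runif(1) < 0.2) sample(900:1600, 1)
              else sample(min_long:max_long, 1)
  }
  start0 <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    lo <- (i - 1L) * slot + 100L
    hi <- (i - 1L) * slot + slot - len[i] - 100L
    start0[i] <- sample(lo:hi, 1)
  }
  data.frame(chrom = chrom, start0 = start0, end0 = start0 + len,
             strand = strand,
             name = sprintf("%s_g%02d", chrom, seq_len(n_genes)),
             stringsAsFactors = FALSE)
}

#' Generate a toy sample/calibration genome pair
#'
#' Builds a random sample genome (16 chromosomes by default, mimicking
#' *S. cerevisiae* with one CDEIII anchor per chromosome, placed
#' mid-chromosome) and a smaller random calibration genome (mimicking the
#' *C. glabrata* spike-in), together with a stranded gene annotation. A
#' rejection step regenerates the pair until no `read_length` substring is
#' shared between the two genomes on either strand or repeated within one,
#' so exact-match read partitioning is unambiguous by construction.
#'
#' @param n_sample_chrom,sample_length number and length (bp) of sample
#'   chromosomes.
#' @param n_calib_chrom,calib_length number and length (bp) of calibration
#'   chromosomes.
#' @param genes_per_chrom genes per sample chromosome (>= 2 so
#'   convergent/tandem pairs exist).
#' @param seed RNG seed; identical seeds reproduce identical genomes
#'   byte-for-byte.
#' @param read_length the simulated read length whose substring-uniqueness
#'   the rejection step guarantees.
#' @return A `ToyGenomePair`: list with `sample` and `calib`
#'   ([Biostrings::DNAStringSet]), `annotation` ([genome_annotation()]) and
#'   `read_length`.
#' @examples
#' pair <- make_toy_genomes(4, 20000, 2, 8000, genes_per_chrom = 5, seed = 1)
#' pair$annotation
#' @export
make_toy_genomes <- function(n_sample_chrom = 16, sample_length = 130000,
                             n_calib_chrom = 3, calib_length = 50000,
                             genes_per_chrom = 10, seed = 1,
                             read_length = 50) {
  for (v in c(n_sample_chrom, sample_length, n_calib_chrom, calib_length,
              genes_per_chrom, read_length))
    if (!is_count(v) || v <= 0) stopf("all dimensions must be positive integers")
  if (genes_per_chrom < 2)
    stopf("genes_per_chrom must be >= 2 so neighbour pairs exist")
  with_seed(seed, {
    k <- min(read_length, 32L)
    for (attempt in 1:10) {
      sample_seqs <- Biostrings::DNAStringSet(
        vapply(seq_len(n_sample_chrom), function(i) random_dna(sample_length),
               character(1)))
      names(sample_seqs) <- paste0("chr", as.character(utils::as.roman(seq_len(n_sample_chrom))))
      calib_seqs <- Biostrings::DNAStringSet(
        vapply(seq_len(n_calib_chrom), function(i) random_dna(calib_length),
               character(1)))
      names(calib_seqs) <- paste0("calib", seq_len(n_calib_chrom))
      if (!kmer_collision(sample_seqs, calib_seqs, k)) break
      if (attempt == 10) stopf("could not generate substring-disjoint genomes")
    }
    genes <- do.call(rbind, lapply(names(sample_seqs), place_genes,
                                   L = sample_length,
                                   n_genes = genes_per_chrom))
    anchors <- setNames(rep(sample_length %/% 2, n_sample_chrom),
                        names(sample_seqs))
    ann <- genome_annotation(
      chrom_lengths = setNames(rep(sample_length, n_sample_chrom),
                               names(sample_seqs)),
      anchors = anchors, genes = genes)
    structure(list(sample = sample_seqs, calib = calib_seqs,
                   annotation = ann, read_length = read_length),
              class = "ToyGenomePair")
  })
}

#' @export
print.ToyGenomePair <- function(x, ...) {
  cat(sprintf("ToyGenomePair: %d sample + %d calibration chromosomes, read length %d\n",
              length(x$sample), length(x$calib), x$read_length))
  print(x$annotation)
  invisible(x)
}

gauss_bump <- function(w, center0, height, width) {
  if (height == 0) return(w)
  L <- length(w)
  span <- ceiling(6 * width)
  lo <- max(1L, center0 + 1L - span)
  hi <- min(L, center0 + 1L + span)
  x <- (lo:hi) - 1L - center0
  w[lo:hi] <- w[lo:hi] + height * exp(-0.5 * (x / width)^2)
  w
}

#' Build a ground-truth occupancy landscape
#'
#' The landscape is a per-base, non-negative weight vector per chromosome
#' from which IP read positions are drawn. It is a sum of interpretable
#' components: a uniform background, a Gaussian centromeric peak at the
#' CDEIII anchor, a bimodal pair of Gaussian peaks flanking the anchor
#' (emulating the pericentric accumulation 500 bp either side of
#' centromeres), and a Gaussian peak at every gene's 3' end (TES). Peak
#' heights are additive on top of the background, so with a single peak of
#' height h the weight at its center is exactly `background + h`.
#'
#' @param annotation a [genome_annotation()] (or `ToyGenomePair`).
#' @param background uniform per-base weight, must be > 0.
#' @param cen_height,cen_width centromeric peak height and Gaussian sd (bp).
#' @param flank_height,flank_offset,flank_width bimodal pericentric peaks:
#'   height, distance from the anchor (bp, default 500) and Gaussian sd.
#' @param tes_height,tes_width 3'-gene-end peak height and Gaussian sd,
#'   applied at the strand-aware TES of every annotated gene.
#' @return An `OccupancyLandscape`: per-chromosome weight vectors plus the
#'   parameter set.
#' @export
make_landscape <- function(annotation, background = 1,
                           cen_height = 0, cen_width = 500,
                           flank_height = 0, flank_offset = 500,
                           flank_width = 150,
                           tes_height = 0, tes_width = 200) {
  if (inherits(annotation, "ToyGenomePair")) annotation <- annotation$annotation
  if (!inherits(annotation, "GenomeAnnotation"))
    stopf("annotation must be a GenomeAnnotation or ToyGenomePair")
  if (background <= 0) stopf("background weight must be > 0")
  for (v in c(cen_height, cen_width, flank_height, flank_offset, flank_width,
              tes_height, tes_width))
    if (v < 0) stopf("peak heights, widths and offsets must be non-negative")
  genes <- annotation$genes
  weights <- lapply(names(annotation$chrom_lengths), function(cn) {
    L <- annotation$chrom_lengths[[cn]]
    w <- rep(background, L)
    a <- annotation$anchors[[cn]]
    if (!is.null(a) && !is.na(a)) {
      w <- gauss_bump(w, a, cen_height, cen_width)
      w <- gauss_bump(w, a - flank_offset, flank_height, flank_width)
      w <- gauss_bump(w, a + flank_offset, flank_height, flank_width)
    }
    if (tes_height > 0 && nrow(genes)) {
      g <- genes[genes$chrom == cn, , drop = FALSE]
      if (nrow(g)) {
        tes <- ifelse(g$strand == "+", g$end0 - 1L, g$start0)
        for (p in tes) w <- gauss_bump(w, p, tes_height, tes_width)
      }
    }
    w
  })
  names(weights) <- names(annotation$chrom_lengths)
  structure(list(weights = weights,
                 params = list(background = background,
                               cen_height = cen_height, cen_width = cen_width,
                               flank_height = flank_height,
                               flank_offset = flank_offset,
                               flank_width = flank_width,
                               tes_height = tes_height, tes_width = tes_width),
                 annotation = annotation),
            class = "OccupancyLandscape")
}

#' Read-simulation configuration
#'
#' Houses the free parameters of the simulated mixed-species sequencing
#' design. `spike_fraction_*` is the fraction of reads drawn from the
#' calibration genome in the reference condition (`true_enrichment = 1`);
#' under enrichment `f` the effective IP calibration fraction becomes
#' `sf / (sf + (1 - sf) f)`, which makes the implied true occupancy ratio
#' exactly linear in `f` (see [true_occupancy_ratio()]).
#'
#' @param n_reads_ip,n_reads_wce read counts for the IP and WCE libraries.
#' @param read_length read length (bp).
#' @param spike_fraction_ip,spike_fraction_wce calibration-genome read
#'   fractions, strictly between 0 and 1.
#' @param true_enrichment scalar multiplier on the sample-genome landscape
#'   relative to the reference condition.
#' @param error_rate per-base substitution error probability (default 0;
#'   the pipeline is exercised downstream of base-calling).
#' @param seed RNG seed; identical seeds give byte-identical read sets.
#' @return A `ReadSimConfig`.
#' @export
sim_config <- function(n_reads_ip, n_reads_wce, read_length = 50,
                       spike_fraction_ip = 0.2, spike_fraction_wce = 0.2,
                       true_enrichment = 1, error_rate = 0, seed = 1) {
  if (!is_count(n_reads_ip) || n_reads_ip <= 0 ||
      !is_count(n_reads_wce) || n_reads_wce <= 0)
    stopf("read counts must be positive integers")
  for (sf in c(spike_fraction_ip, spike_fraction_wce))
    if (!(sf > 0 && sf < 1)) stopf("spike fractions must be strictly in (0, 1)")
  if (true_enrichment <= 0) stopf("true_enrichment must be > 0")
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  structure(list(n_reads_ip = as.integer(n_reads_ip),
                 n_reads_wce = as.integer(n_reads_wce),
                 read_length = as.integer(read_length),
                 spike_fraction_ip = spike_fraction_ip,
                 spike_fraction_wce = spike_fraction_wce,
                 true_enrichment = true_enrichment,
                 error_rate = error_rate, seed = seed),
            class = "ReadSimConfig")
}

#' Implied true occupancy ratio of a simulation configuration
#'
#' Computed analytically from the configuration (not empirically from the
#' sampled reads), giving an exact recovery target:
#' `OR_true = f * sf_wce (1 - sf_ip) / ((1 - sf_wce) sf_ip)` where `f` is
#' `true_enrichment`. With equal spike fractions and `f = 1` this is 1, and
#' doubling `f` doubles it.
#'
#' @param config a [sim_config()].
#' @return Positive scalar.
#' @export
true_occupancy_ratio <- function(config) {
  stopifnot(inherits(config, "ReadSimConfig"))
  with(config, true_enrichment * spike_fraction_wce * (1 - spike_fraction_ip) /
         ((1 - spike_fraction_wce) * spike_fraction_ip))
}

# Sample n uniform read start positions (0-based) across a genome.
uniform_positions <- function(seqs, n, read_length) {
  lens <- Biostrings::width(seqs)
  nvalid <- lens - read_length + 1L
  if (any(nvalid <= 0)) stopf("read length %d exceeds a chromosome length", read_length)
  cum <- cumsum(as.numeric(nvalid))
  g <- ceiling(runif(n) * cum[length(cum)])
  ci <- findInterval(g - 0.5, c(0, cum))
  start0 <- as.integer(g - c(0, cum)[ci] - 1)
  data.frame(chrom = names(seqs)[ci], start0 = start0, stringsAsFactors = FALSE)
}

# Sample n read start positions with midpoint probability proportional to
# the landscape weights.
landscape_positions <- function(landscape, n, read_length) {
  half <- read_length %/% 2L
  per <- lapply(names(landscape$weights), function(cn) {
    w <- landscape$weights[[cn]]
    L <- length(w)
    if (L < read_length) stopf("read length %d exceeds chromosome %s", read_length, cn)
    mids <- half:(L - read_length + half)         # 0-based midpoints
    list(chrom = cn, mids = mids, w = w[mids + 1L])
  })
  wall <- unlist(lapply(per, `[[`, "w"))
  if (sum(wall) <= 0) stopf("landscape has zero total weight")
  idx <- sample.int(length(wall), n, replace = TRUE, prob = wall)
  sizes <- vapply(per, function(p) length(p$mids), integer(1))
  ci <- findInterval(idx - 0.5, c(0, cumsum(sizes)))
  off <- idx - c(0, cumsum(sizes))[ci]
  mids <- integer(n); chrom <- character(n)
  for (i in seq_along(per)) {
    sel <- ci == i
    if (!any(sel)) next
    mids[sel] <- per[[i]]$mids[off[sel]]
    chrom[sel] <- per[[i]]$chrom
  }
  data.frame(chrom = chrom, start0 = mids - half, stringsAsFactors = FALSE)
}

extract_read_seqs <- function(seqs, chrom, start0, read_length) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    v <- Biostrings::Views(seqs[[cn]], start = start0[sel] + 1L,
                           width = read_length)
    out[sel] <- as.character(v)
  }
  out
}

apply_substitution_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(reads)) {
    n <- nchar(reads[i])
    nmut <- rbinom(1, n, error_rate)
    if (nmut == 0) next
    pos <- sample.int(n, nmut)
    s <- strsplit(reads[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

simulate_library <- function(pair, landscape, n, spike_fraction, read_length,
                             error_rate, prefix, weighted_sample) {
  is_calib <- runif(n) < spike_fraction
  n_c <- sum(is_calib)
  n_s <- n - n_c
  chrom <- character(n); start0 <- integer(n)
  if (n_c > 0) {
    posc <- uniform_positions(pair$calib, n_c, read_length)
    chrom[is_calib] <- posc$chrom; start0[is_calib] <- posc$start0
  }
  if (n_s > 0) {
    poss <- if (weighted_sample) landscape_positions(landscape, n_s, read_length)
            else uniform_positions(pair$sample, n_s, read_length)
    chrom[!is_calib] <- poss$chrom; start0[!is_calib] <- poss$start0
  }
  seqs <- character(n)
  if (n_c > 0) seqs[is_calib] <- extract_read_seqs(pair$calib, chrom[is_calib],
                                                   start0[is_calib], read_length)
  if (n_s > 0) seqs[!is_calib] <- extract_read_seqs(pair$sample, chrom[!is_calib],
                                                    start0[!is_calib], read_length)
  minus <- runif(n) < 0.5
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  }
  seqs <- apply_substitution_errors(seqs, error_rate)
  ids <- sprintf("%s_%07d", prefix, seq_len(n))
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- ids
  truth <- data.frame(read_id = ids,
                      genome = ifelse(is_calib, "calibration", "sample"),
                      chrom = chrom, start0 = start0,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a calibrated ChIP-seq experiment
#'
#' Draws an IP library (calibration reads uniform on the calibration genome
#' with the enrichment-adjusted spike fraction; sample reads with per-base
#' midpoint probability proportional to the occupancy landscape) and a WCE
#' library (uniform on both genomes at the WCE spike fraction). Reads are
#' single-end, fixed-length, taken from either strand, and error-free by
#' default. The truth table records each read's genome of origin, chromosome
#' and 0-based start, and the analytically implied true occupancy ratio.
#'
#' @param pair a [make_toy_genomes()] result.
#' @param landscape a [make_landscape()] result on the pair's annotation.
#' @param config a [sim_config()].
#' @return A `ChipSimulation`: list with `ip_reads`, `wce_reads` (named
#'   [Biostrings::DNAStringSet]) and `truth` (list of per-library truth
#'   tables, `or_true` and the config).
#' @export
simulate_experiment <- function(pair, landscape, config) {
  stopifnot(inherits(pair, "ToyGenomePair"),
            inherits(landscape, "OccupancyLandscape"),
            inherits(config, "ReadSimConfig"))
  if (!identical(names(landscape$weights), names(pair$sample)))
    stopf("landscape chromosomes do not match the genome pair")
  rl <- config$read_length
  if (rl > min(Biostrings::width(pair$sample), Biostrings::width(pair$calib)))
    stopf("read length %d exceeds a chromosome length", rl)
  f <- config$true_enrichment
  sfi <- config$spike_fraction_ip
  sf_ip_eff <- sfi / (sfi + (1 - sfi) * f)
  with_seed(config$seed, {
    ip <- simulate_library(pair, landscape, config$n_reads_ip, sf_ip_eff, rl,
                           config$error_rate, "ip", weighted_sample = TRUE)
    wce <- simulate_library(pair, landscape, config$n_reads_wce,
                            config$spike_fraction_wce, rl,
                            config$error_rate, "wce", weighted_sample = FALSE)
    structure(list(ip_reads = ip$reads, wce_reads = wce$reads,
                   truth = list(ip = ip$truth, wce = wce$truth,
                                or_true = true_occupancy_ratio(config),
                                config = config)),
              class = "ChipSimulation")
  })
}

#' @export
print.ChipSimulation <- function(x, ...) {
  cat(sprintf("ChipSimulation: %d IP + %d WCE reads, true OR = %.4g\n",
              length(x$ip_reads), length(x$wce_reads), x$truth$or_true))
  invisible(x)
}

#' Write simulated reads to FASTQ
#'
#' Fixed quality `I` (Phred 40) for every base.
#'
#' @param reads named [Biostrings::DNAStringSet].
#' @param path output file (plain or `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (plain or `.gz`).
#' @return A named [Biostrings::DNAStringSet] with per-read qualities kept
#'   in `mcols(x)$qualities`.
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
}

#' Write a simulated dataset to disk
#'
#' Emits the genome FASTAs, IP/WCE FASTQs, per-library truth tables (TSV:
#' `read_id`, `genome`, `chrom`, `start0`), the CDEIII anchor table (TSV:
#' `chrom`, `cdeiii_pos0`), a BED6 gene annotation and a `chrom.sizes` file.
#'
#' @param pair a `ToyGenomePair`.
#' @param sim a `ChipSimulation` (optional; omit to write genomes/annotation
#'   only).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(pair, sim = NULL, dir) {
  stopifnot(inherits(pair, "ToyGenomePair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(pair$sample, file.path(dir, "sample_genome.fa"))
  Biostrings::writeXStringSet(pair$calib, file.path(dir, "calib_genome.fa"))
  ann <- pair$annotation
  write.table(data.frame(chrom = names(ann$anchors),
                         cdeiii_pos0 = as.integer(ann$anchors)),
              file.path(dir, "anchors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(chrom = names(ann$chrom_lengths),
                         length = as.integer(ann$chrom_lengths)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g <- ann$genes
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$start0 + 1L, g$end0),
                               strand = g$strand, name = g$name, score = 0L)
  rtracklayer::export(gr, file.path(dir, "genes.bed"), format = "bed")
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "ChipSimulation"))
    write_fastq(sim$ip_reads, file.path(dir, "ip.fastq"))
    write_fastq(sim$wce_reads, file.path(dir, "wce.fastq"))
    write.table(sim$truth$ip, file.path(dir, "truth_ip.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$truth$wce, file.path(dir, "truth_wce.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
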