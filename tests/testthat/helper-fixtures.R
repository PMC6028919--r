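# Shared fixtures (built once per session) and independent oracles.

.fix <- new.env(parent = emptyenv())

small_pair <- function() {
  if (is.null(.fix$pair))
    .fix$pair <- make_toy_genomes(4, 20000, 2, 8000, genes_per_chrom = 5,
                                  seed = 11, read_length = 40)
  .fix$pair
}

# Simulation with bimodal pericentric flank peaks on the small pair.
small_sim <- function() {
  if (is.null(.fix$sim)) {
    ls <- make_landscape(small_pair(), background = 1, flank_height = 20,
                         flank_offset = 500, flank_width = 150)
    .fix$sim <- simulate_experiment(small_pair(), ls,
                                    sim_config(20000, 20000, read_length = 40,
                                               seed = 5))
  }
  .fix$sim
}

# Uniform-coverage track over the small pair's chromosomes.
uniform_track <- function(value = 1) {
  lens <- small_pair()$annotation$chrom_lengths
  coverage_track(lapply(lens, function(L) rep(value, L)))
}

random_track <- function(lens, seed) {
  set.seed(seed)
  coverage_track(lapply(lens, function(L) round(runif(L) * 10)))
}

# Naive window-matrix oracle for anchored averaging: materialize one row per
# anchor with NA outside the chromosome, then column-average.
profile_oracle <- function(values, chrom, anchor0, direction, half_width) {
  offsets <- seq.int(-half_width, half_width)
  mat <- t(vapply(seq_along(chrom), function(i) {
    v <- values[[chrom[i]]]
    idx <- anchor0[i] + direction[i] * offsets + 1
    out <- rep(NA_real_, length(offsets))
    ok <- idx >= 1 & idx <= length(v)
    out[ok] <- v[idx[ok]]
    out
  }, numeric(length(offsets))))
  list(value = colMeans(mat, na.rm = TRUE), n = colSums(!is.na(mat)))
}

# Exhaustive pairwise classification oracle, independent of the package's
# sweep: for every gene scan all other genes on the chromosome.
classify_oracle <- function(genes, at = "TES") {
  g <- genes[order(genes$chrom, genes$start0, genes$end0), , drop = FALSE]
  cls <- character(nrow(g))
  nested <- vapply(seq_len(nrow(g)), function(i) {
    any(g$chrom == g$chrom[i] & g$start0 <= g$start0[i] & g$end0 >= g$end0[i] &
          seq_len(nrow(g)) != i & (g$start0 < g$start0[i] | g$end0 > g$end0[i]))
  }, logical(1))
  for (i in seq_len(nrow(g))) {
    if (nested[i]) { cls[i] <- "boundary"; next }
    right <- (g$strand[i] == "+") == (at == "TES")
    best <- NA_integer_; bestd <- Inf
    for (j in seq_len(nrow(g))) {
      if (j == i || g$chrom[j] != g$chrom[i] || nested[j]) next
      if (right) {
        d <- g$start0[j] - (g$end0[i] - 1)
        if (d > 0 && d < bestd) { best <- j; bestd <- d }
      } else {
        d <- g$start0[i] - (g$end0[j] - 1)
        if (d > 0 && d < bestd) { best <- j; bestd <- d }
      }
    }
    if (is.na(best)) { cls[i] <- "boundary"; next }
    same <- g$strand[best] == g$strand[i]
    cls[i] <- if (same) "tandem" else if (at == "TES") "convergent" else "divergent"
  }
  data.frame(name = g$name, class = cls, stringsAsFactors = FALSE)
}

# Minimal VCF writer independent of the package (for read_snps tests).
write_vcf_text <- function(df, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\t.",
                       df$chrom, df$pos1, df$ref, df$alt)), path)
  path
}

random_snp_records <- function(n, seed, chroms = c("chrI", "chrII")) {
  set.seed(seed)
  pos <- sample.int(50000, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  data.frame(chrom = sample(chroms, n, replace = TRUE), pos1 = pos,
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# Delta-method 4-sigma band for an occupancy-ratio estimate on the log scale.
or_within_4sigma <- function(or_hat, or_true, counts) {
  sd_log <- sqrt(1 / counts$ip_sample + 1 / counts$ip_calib +
                   1 / counts$wce_sample + 1 / counts$wce_calib)
  abs(log(or_hat) - log(or_true)) < 4 * sd_log
}
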