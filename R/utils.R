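# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs user-level reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x)
}

# Normalize an anchor specification (named vector, two-column data frame, or
# a GenomeAnnotation) to a named numeric vector of 0-based positions.
as_anchors <- function(anchors) {
  if (inherits(anchors, "GenomeAnnotation")) return(anchors$anchors)
  if (is.data.frame(anchors)) {
    if (ncol(anchors) < 2) stopf("anchor table needs (chrom, pos0) columns")
    return(setNames(as.numeric(anchors[[2]]), as.character(anchors[[1]])))
  }
  if (is.numeric(anchors) && !is.null(names(anchors))) return(anchors)
  stopf("anchors must be a named vector, a (chrom, pos0) table, or a GenomeAnnotation")
}

# Normalize a gene specification to the internal 0-based half-open table
# with columns chrom, start0, end0, strand, name.
as_gene_table <- function(genes) {
  if (inherits(genes, "GenomeAnnotation")) return(genes$genes)
  if (is(genes, "GRanges")) {
    nm <- if (!is.null(genes$name)) as.character(genes$name) else
      paste0("gene_", seq_along(genes))
    return(data.frame(
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start0 = GenomicRanges::start(genes) - 1L,
      end0 = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes)),
      name = nm, stringsAsFactors = FALSE))
  }
  if (is.data.frame(genes)) {
    need <- c("chrom", "start0", "end0", "strand", "name")
    if (!all(need %in% names(genes)))
      stopf("gene table must have columns %s", paste(need, collapse = ", "))
    return(genes[need])
  }
  if (is.character(genes) && length(genes) == 1) {
    return(as_gene_table(rtracklayer::import(genes)))
  }
  stopf("unsupported gene annotation representation")
}
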