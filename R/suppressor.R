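#' Construct a SNP set
#'
#' A strain's set of single-nucleotide variants. SNP identity throughout the
#' mapping pipeline is the key `(chrom, pos1, alt)` — genotype and quality
#' fields play no role, because strain SNP *lists* are being compared.
#' Coordinates are 1-based (VCF convention).
#'
#' @param strain strain label.
#' @param records data frame with columns `chrom`, `pos1`, `ref`, `alt`.
#' @return A `SnpSet`; duplicate keys are collapsed.
#' @export
snp_set <- function(strain, records) {
  need <- c("chrom", "pos1", "ref", "alt")
  if (!all(need %in% names(records)))
    stopf("SNP records need columns %s", paste(need, collapse = ", "))
  records <- records[need]
  records$chrom <- as.character(records$chrom)
  records$pos1 <- as.integer(records$pos1)
  records$ref <- as.character(records$ref)
  records$alt <- as.character(records$alt)
  if (any(records$ref == records$alt)) stopf("ref and alt alleles must differ")
  key <- snp_key(records)
  records <- records[!duplicated(key), , drop = FALSE]
  records <- records[order(records$chrom, records$pos1, records$alt), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(list(strain = strain, records = records), class = "SnpSet")
}

snp_key <- function(records) paste(records$chrom, records$pos1, records$alt)

#' @export
print.SnpSet <- function(x, ...) {
  cat(sprintf("SnpSet '%s': %d SNVs on %d chromosomes\n", x$strain,
              nrow(x$records), length(unique(x$records$chrom))))
  invisible(x)
}

#' @export
length.SnpSet <- function(x) nrow(x$records)

#' Read SNVs from a VCF file
#'
#' Parses a VCF 4.x file into a [snp_set()]. Indel and symbolic records are
#' skipped (the upstream variant calls are made with indels excluded; a
#' message reports how many were dropped here); multi-allelic rows
#' contribute one record per alternate allele.
#'
#' @param path VCF path (plain or bgzipped).
#' @param strain strain label; defaults to the file name.
#' @return A `SnpSet`.
#' @export
read_snps <- function(path, strain = NULL) {
  if (is.null(strain)) strain <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stopf("failed to parse %s: %s", path,
                                            conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(snp_set(strain, data.frame(chrom = character(),
                                                        pos1 = integer(),
                                                        ref = character(),
                                                        alt = character())))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  rec <- data.frame(chrom = rep(fix$CHROM, lengths(alts)),
                    pos1 = rep(as.integer(fix$POS), lengths(alts)),
                    ref = rep(fix$REF, lengths(alts)),
                    alt = unlist(alts), stringsAsFactors = FALSE)
  snv <- nchar(rec$ref) == 1 & nchar(rec$alt) == 1 &
    rec$ref %in% c("A", "C", "G", "T") & rec$alt %in% c("A", "C", "G", "T")
  if (any(!snv))
    message(sum(!snv), " non-SNV record(s) skipped in ", basename(path))
  snp_set(strain, rec[snv, , drop = FALSE])
}

#' Write a SnpSet as a minimal VCF
#'
#' @param snps a `SnpSet`.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  stopifnot(inherits(snps, "SnpSet"))
  r <- snps$records
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=calichip (%s)", snps$strain),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", r$chrom, r$pos1, r$ref, r$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Remove SNPs shared with a parental strain
#'
#' Mutations present in both the suppressor and the parental strain are
#' removed — they predate the suppressor and cannot be causal.
#'
#' @param suppressor,parental `SnpSet`s called against the same reference.
#' @return A `SnpSet` of suppressor records absent from the parental set.
#' @export
subtract_parental <- function(suppressor, parental) {
  stopifnot(inherits(suppressor, "SnpSet"), inherits(parental, "SnpSet"))
  keep <- !(snp_key(suppressor$records) %in% snp_key(parental$records))
  snp_set(suppressor$strain, suppressor$records[keep, , drop = FALSE])
}

#' Keep SNPs shared with every backcrossed clone
#'
#' Backcrossed clones of the suppressor retain the causal mutation through
#' each cross, so only mutations present in *every* backcross set are kept.
#'
#' @param suppressor a `SnpSet`.
#' @param backcrosses non-empty list of `SnpSet`s.
#' @return A `SnpSet`.
#' @export
intersect_backcross <- function(suppressor, backcrosses) {
  stopifnot(inherits(suppressor, "SnpSet"))
  if (!is.list(backcrosses) || length(backcrosses) == 0)
    stopf("at least one backcross SNP set is required")
  keep <- rep(TRUE, nrow(suppressor$records))
  key <- snp_key(suppressor$records)
  for (b in backcrosses) {
    stopifnot(inherits(b, "SnpSet"))
    keep <- keep & (key %in% snp_key(b$records))
  }
  snp_set(suppressor$strain, suppressor$records[keep, , drop = FALSE])
}

#' Build a queryable gene index
#'
#' @param genes gene annotation in any representation accepted by
#'   [feature_meta_profile()] (internal 0-based table, `GRanges`, BED/GFF3
#'   path, or `GenomeAnnotation`).
#' @return A `GeneIndex` wrapping a [GenomicRanges::GRanges] in 1-based
#'   closed coordinates.
#' @export
gene_index <- function(genes) {
  g <- as_gene_table(genes)
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$start0 + 1L, g$end0),
                               strand = g$strand)
  gr$name <- g$name
  structure(list(granges = gr), class = "GeneIndex")
}

#' Keep SNPs that fall inside genes
#'
#' Positions are tested for containment in gene spans inclusively of both
#' endpoints (1-based closed coordinates); surviving records are annotated
#' with the overlapping gene name(s), comma-separated when a position lies
#' in more than one gene.
#'
#' @param snps a `SnpSet`.
#' @param genes a [gene_index()] (or anything coercible to one).
#' @return A `SnpSet` whose records gain a `gene` column.
#' @export
filter_genic <- function(snps, genes) {
  stopifnot(inherits(snps, "SnpSet"))
  if (!inherits(genes, "GeneIndex")) genes <- gene_index(genes)
  r <- snps$records
  if (nrow(r) == 0) { r$gene <- character(0); return(snps) }
  q <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos1, r$pos1))
  hits <- GenomicRanges::findOverlaps(q, genes$granges, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  gn <- genes$granges$name[S4Vectors::subjectHits(hits)]
  keep <- sort(unique(qh))
  out <- r[keep, , drop = FALSE]
  out$gene <- vapply(keep, function(i) paste(gn[qh == i], collapse = ","),
                     character(1))
  res <- snp_set(snps$strain, out)
  res$records$gene <- out$gene[match(snp_key(res$records), snp_key(out))]
  res
}

#' Map a suppressor mutation by SNP subtraction and intersection
#'
#' Composes the full suppressor-mapping pipeline: subtract every parental
#' strain's SNPs, intersect with every backcrossed clone's SNPs, and keep
#' only genic positions. At least one parental or backcross comparison is
#' required.
#'
#' @param suppressor a `SnpSet` or VCF path for the suppressor strain.
#' @param parental list of `SnpSet`s/VCF paths for parental strains.
#' @param backcross list of `SnpSet`s/VCF paths for backcrossed clones.
#' @param genes gene annotation (see [gene_index()]).
#' @return Candidate table: data frame `chrom`, `pos1`, `ref`, `alt`,
#'   `gene`, sorted by chromosome and position.
#' @export
map_suppressor <- function(suppressor, parental = list(), backcross = list(),
                           genes) {
  as_set <- function(x, label) {
    if (inherits(x, "SnpSet")) x else read_snps(x)
  }
  if (length(parental) == 0 && length(backcross) == 0)
    stopf("at least one parental or backcross comparison is required")
  s <- as_set(suppressor)
  for (p in parental) s <- subtract_parental(s, as_set(p))
  if (length(backcross) > 0)
    s <- intersect_backcross(s, lapply(backcross, as_set))
  s <- filter_genic(s, genes)
  r <- s$records[order(s$records$chrom, s$records$pos1), , drop = FALSE]
  rownames(r) <- NULL
  r
}
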