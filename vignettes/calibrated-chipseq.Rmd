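---
title: "Calibrated ChIP-seq quantification with calichip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated ChIP-seq quantification with calichip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calichip)
```

## The quantification problem

Conventional ChIP-seq profiles are only *relative*: library size, IP
efficiency and sequencing depth all scale the track arbitrarily, so two
samples cannot be compared on a common vertical axis. Spike-in calibration
fixes this by mixing the sample cells (*S. cerevisiae* in the assay this
package models) with a fixed proportion of cells from a related species
(*C. glabrata*) **before** chromatin immunoprecipitation. Both genomes then
travel through fixation, IP and sequencing together, and the
calibration-genome reads act as an internal yardstick.

Reads are assigned to a genome sequentially: align to the calibration
genome first, keep the unaligned reads, align those to the sample genome,
and count only reads that align **uniquely**. Doing this for both the IP
and the whole-cell-extract (WCE, input) library yields four counts, from
which the **occupancy ratio** is

$$
OR = \frac{W_C \times IP_S}{W_S \times IP_C},
$$

where $W$ and $IP$ are unique-read totals on the calibration ($C$) and
sample ($S$) genomes. The WCE factor cancels differences in the cell-mix
proportion, the IP factor carries the genuine occupancy signal, and the
ratio is invariant to uniform subsampling of any library. A quantitative
track is then the raw coverage multiplied by $OR \times 10^6 / N$
("multiplied by the occupancy ratio and normalized to 1 million reads").

### The per-million denominator

Which $N$ the per-million normalization divides by is a genuine design
choice: we use the IP library's unique **sample-genome** read count by
default, because that is the library whose coverage is being scaled.
`calibrate(..., denominator = "ip_total")` (or a plain number) is available
for pipelines that normalize by total library size. Since every value in a
track gets the same factor, the choice affects absolute axis units, never
comparisons made with a consistent setting.

## Anchored profile analyses

* `cen_meta_profile()` averages coverage at each base-pair offset up to
  60 kb either side of the per-chromosome centromere (CDEIII) anchor,
  across all 16 chromosomes. Averaging at each offset divides by the
  number of chromosomes actually contributing there — an anchor closer
  than the half-width to a chromosome end contributes a truncated window
  ("up to 60 kb"), avoiding zero-padding bias. Centromere windows are
  unstranded. The calibration factor is applied after averaging; because
  multiplication commutes with the mean this equals calibrating the track
  first, and the test suite asserts that identity.
* `feature_meta_profile()` does the same around gene TSSs or TESs,
  orienting each window by strand so positive offsets point downstream,
  and excluding genes of length ≤ 2 kb by default (the "genes longer than
  2 kb" convention for TES metagenes).
* `classify_gene_pairs()` labels each gene by its nearest neighbour in the
  direction of transcription past the TES: opposite strand → *convergent*
  (head-on), same strand → *tandem*, none → *boundary*; at the TSS the
  upstream neighbour on the opposite strand is *divergent*. The
  nearest-downstream-neighbour rule is the simplest one consistent with
  the convergent/tandem dichotomy; genes nested inside another gene are
  set aside in the boundary class rather than forced into a pair.
* `difference_profile()` subtracts two profiles offset-wise (windows must
  match exactly — no silent resampling), revealing redistribution such as
  translocation away from centromeres: a negative lobe at the origin with
  positive destination lobes.
* `percent_of_reference()` rescales a profile to percent of the
  *reference profile's window mean*, the percent-of-wild-type convention.
* `region_summary()` splits the genome at 30 kb from the anchors
  (pericentric vs arm, the operational definition of "arm" loading) and
  reports both means and their ratio.
* `track_scatter()` bins two calibrated tracks, fits a least-squares slope
  **through the origin** (proportional-occupancy model) and flags bins
  whose ratio falls below half the global slope. The binning and fit are
  package choices; nothing in the assay prescribes them.

## The synthetic-data generator

Every stage above is validated against `make_toy_genomes()`,
`make_landscape()` and `simulate_experiment()`, which emulate the essential
geometry of the real experiment with known ground truth:

* a 16-chromosome sample genome with one mid-chromosome CDEIII anchor
  each, plus a smaller calibration genome. A rejection step guarantees
  that no read-length substring is shared between (or repeated within)
  the genomes on either strand, so exact-match partitioning has a single
  correct answer and the truth table is an exact oracle;
* an occupancy landscape that is a sum of interpretable components:
  uniform background, a Gaussian centromeric peak, bimodal flank peaks
  (default ±500 bp, where pericentric accumulation concentrates), and
  3′-gene-end peaks;
* IP reads drawn with midpoint probability proportional to the landscape
  (midpoint rather than 5′-end sampling keeps coverage maxima centred on
  landscape peaks), WCE reads drawn uniformly, both on either strand;
* a spike fraction for each library. Under enrichment $f$ the effective
  IP calibration fraction is $sf/(sf + (1-sf)f)$ — the calibration
  material is fixed while sample signal scales — which makes the implied
  true OR exactly linear in $f$. The true OR is stored analytically, not
  empirically, so recovery tests have an exact target. The effective
  spike-in fraction achieved by the real 3:1 cell mix is not a published
  number, so it is a free parameter (default 0.2) rather than a constant.

Reads are single-end, fixed-length and error-free by default (a
substitution-error option exists), with fixed quality `I`. The generator
deliberately omits PCR duplicates, indels, paired ends, mappability
structure and nucleosome realism: passing tests demonstrate the
*computational* correctness of partitioning, calibration and averaging,
not robustness to every artefact of real libraries — real data should
enter through `import_alignments()` after a proper aligner.

## Read processing

`qc_trim()` removes the first 10 bases and everything after base 200, then
drops reads shorter than 50 bp (all configurable). `partition_reads()`
implements the sequential two-genome contract with exact full-length
matching on both strands (`Biostrings` PDict); "uniquely align" is read
strictly as *exactly one placement*, and a read matching a genome at two
or more loci is unassigned — it would not have reached the second genome
in the sequential pipeline, because multi-mapping reads still align.
Gapped, mismatch-tolerant alignment is intentionally out of scope.

## Suppressor mapping and kinetics

`map_suppressor()` composes three set operations on SNP lists keyed by
`(chrom, pos, alt)` — genotype and quality are irrelevant when comparing
presence/absence: remove SNPs shared with parental strains, keep SNPs
present in every backcrossed clone, and keep only positions inside genes
(both endpoints inclusive, 1-based closed spans taken from the supplied
annotation as-is — whether UTRs belong in the span is the annotation's
decision, not the algorithm's). Indel records are skipped at VCF parse
time, matching upstream variant calling that excludes indels.

`fit_standard_curve()` and `atpase_rate()` convert 360 nm absorbance
series (one reading every 30 s for 90 min) to phosphate-release rates via
an OLS standard curve and the slope of a fixed linear-phase window,
default the first 10 minutes — a fixed window exactly as stated, with no
automatic linearity detection. Rates are blank-invariant by construction.
Replicates aggregate to mean ± SD with n reported; no inferential testing
is attached. Output units are concentration per second; an optional
enzyme concentration (e.g. 50 nM complex) converts to per-enzyme turnover.

## Numerical conventions and problem sizes

Coordinates are 0-based half-open everywhere inside the package; 1-based
conventions appear only at the VCF/GFF/SAM boundaries. bedGraph export
writes maximal equal-value runs including explicit zero runs (suppressible);
wiggle export is per-base. Degenerate inputs fail loudly: zero OR
denominators name the offending count, out-of-bounds placements name the
read, mismatched profile windows refuse to resample, an empty arm region
(threshold beyond the chromosome) is an error.

The test and acceptance workloads use a 16 × 120 kb genome with 10^5–2×10^5
reads per library — large enough that binomial recovery bands (4σ) and
peak-position bounds (±25 bp) are meaningful, small enough to run
comfortably on a laptop. Statistical checks are seeded and compared at
4σ / χ² (α = 0.001) bounds, so they are deterministic in practice.

## Limitations

* The pseudo-aligner is for synthetic data only; it will call almost every
  real read "unassigned" because real reads contain errors.
* Calibration assumes the four counts come from *unique* alignments of the
  same trimmed read set; mixing filters between libraries biases OR.
* `track_scatter()`'s through-origin slope is sensitive to bins where the
  reference track is near zero; such bins are reported with `NA` ratios
  rather than flagged.
* Gene classification assumes non-nested, essentially non-overlapping
  annotations (warnings are emitted otherwise).
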