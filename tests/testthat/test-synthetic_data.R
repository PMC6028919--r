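test_that("toy genome pair has the requested dimensions and valid annotation", {
  pair <- small_pair()
  ann <- pair$annotation
  expect_length(pair$sample, 4)
  expect_length(pair$calib, 2)
  expect_equal(unname(Biostrings::width(pair$sample)), rep(20000, 4))
  expect_equal(nrow(ann$genes), 20)
  expect_length(ann$anchors, 4)
  expect_true(all(ann$anchors > 0 & ann$anchors < ann$chrom_lengths - 1))
  expect_true(all(ann$genes$start0 >= 0 &
                    ann$genes$end0 <= ann$chrom_lengths[ann$genes$chrom]))
  # some genes long enough for the metagene filter, some not
  len <- ann$genes$end0 - ann$genes$start0
  expect_true(any(len > 2000))
})

test_that("identical seeds reproduce identical genomes byte-for-byte", {
  a <- make_toy_genomes(2, 12000, 1, 6000, genes_per_chrom = 3, seed = 42,
                        read_length = 40)
  b <- make_toy_genomes(2, 12000, 1, 6000, genes_per_chrom = 3, seed = 42,
                        read_length = 40)
  expect_identical(as.character(a$sample), as.character(b$sample))
  expect_identical(as.character(a$calib), as.character(b$calib))
  expect_identical(a$annotation$genes, b$annotation$genes)
  da <- file.path(tempdir(), "dsA"); db <- file.path(tempdir(), "dsB")
  write_dataset(a, dir = da); write_dataset(b, dir = db)
  expect_identical(unname(tools::md5sum(file.path(da, "sample_genome.fa"))),
                   unname(tools::md5sum(file.path(db, "sample_genome.fa"))))
})

test_that("gene strands provide convergent and tandem neighbour pairs", {
  pair <- make_toy_genomes(1, 130000, 1, 50000, genes_per_chrom = 4, seed = 7,
                           read_length = 40)
  g <- pair$annotation$genes[order(pair$annotation$genes$start0), ]
  s <- g$strand
  adj <- paste0(s[-length(s)], s[-1])
  expect_true("+-" %in% adj)                      # convergent pair
  expect_true(any(adj %in% c("++", "--")))        # tandem pair
})

test_that("invalid genome dimensions are rejected", {
  expect_error(make_toy_genomes(0, 10000, 1, 5000, seed = 1), "positive")
  expect_error(make_toy_genomes(1, 10000, 1, 5000, genes_per_chrom = 1,
                                seed = 1), ">= 2")
  # 3 kb chromosome cannot hold 2 genes > 2 kb
  expect_error(make_toy_genomes(1, 3000, 1, 2000, genes_per_chrom = 2,
                                seed = 1), "too short")
})

test_that("landscape components are additive with exact peak values", {
  pair <- small_pair()
  flat <- make_landscape(pair, background = 1)
  expect_true(all(vapply(flat$weights, function(w) all(w == 1), logical(1))))
  cen <- make_landscape(pair, background = 1, cen_height = 9, cen_width = 200)
  a <- pair$annotation$anchors[["chrI"]]
  expect_equal(cen$weights[["chrI"]][a + 1], 10.0)
  # bimodal flanks: argmax within +/- 2 kb of the anchor sits at +/- 500
  fl <- make_landscape(pair, background = 1, flank_height = 20,
                       flank_offset = 500, flank_width = 150)
  w <- fl$weights[["chrII"]]
  a <- pair$annotation$anchors[["chrII"]]
  win <- (a - 2000):(a + 2000)
  peaks <- win[order(w[win + 1], decreasing = TRUE)][1:2] - a
  expect_setequal(peaks, c(-500, 500))
  expect_error(make_landscape(pair, cen_height = -1), "non-negative")
  expect_error(make_landscape(pair, background = 0), "> 0")
})

test_that("simulation marginals follow the landscape and spike fractions", {
  sim <- small_sim()
  pair <- small_pair()
  cfg <- sim$truth$config
  # spike-fraction recovery within 4 binomial sigma (IP at f = 1 and WCE)
  for (lib in c("ip", "wce")) {
    tt <- sim$truth[[lib]]
    p_hat <- mean(tt$genome == "calibration")
    p <- if (lib == "ip") cfg$spike_fraction_ip else cfg$spike_fraction_wce
    expect_lt(abs(p_hat - p), 4 * sqrt(p * (1 - p) / nrow(tt)))
  }
  # uniform-landscape WCE: per-chromosome counts match the multinomial
  # expectation within 4 sigma
  tt <- sim$truth$wce
  tt <- tt[tt$genome == "sample", ]
  lens <- pair$annotation$chrom_lengths
  nvalid <- lens - cfg$read_length + 1
  p <- nvalid / sum(nvalid)
  obs <- table(factor(tt$chrom, names(lens)))
  for (cn in names(lens)) {
    expect_lt(abs(obs[[cn]] - nrow(tt) * p[[cn]]),
              4 * sqrt(nrow(tt) * p[[cn]] * (1 - p[[cn]])) + 1)
  }
  # binned chi-square on IP sample-read midpoints against the landscape
  ls <- make_landscape(pair, background = 1, flank_height = 20,
                       flank_offset = 500, flank_width = 150)
  ip <- sim$truth$ip[sim$truth$ip$genome == "sample", ]
  half <- cfg$read_length %/% 2
  bin <- 1000
  obs <- numeric(0); expct <- numeric(0)
  for (cn in names(lens)) {
    w <- ls$weights[[cn]]
    mids <- half:(lens[[cn]] - cfg$read_length + half)
    wv <- w[mids + 1]
    b <- (mids %/% bin) + 1
    e_cn <- tapply(wv, b, sum)
    m <- ip$start0[ip$chrom == cn] + half
    o_cn <- tabulate((m %/% bin) + 1, nbins = max(b))
    obs <- c(obs, o_cn[as.integer(names(e_cn))])
    expct <- c(expct, e_cn)
  }
  expct <- expct / sum(expct) * sum(obs)
  stat <- sum((obs - expct)^2 / expct)
  expect_lt(stat, qchisq(1 - 0.001, df = length(obs) - 1))
})

test_that("the implied true OR is linear in enrichment and unit at symmetry", {
  base <- sim_config(1000, 1000, spike_fraction_ip = 0.2,
                     spike_fraction_wce = 0.2, true_enrichment = 1)
  expect_equal(true_occupancy_ratio(base), 1)
  doubled <- sim_config(1000, 1000, spike_fraction_ip = 0.2,
                        spike_fraction_wce = 0.2, true_enrichment = 2)
  expect_equal(true_occupancy_ratio(doubled), 2 * true_occupancy_ratio(base))
  asym <- sim_config(1000, 1000, spike_fraction_ip = 0.1,
                     spike_fraction_wce = 0.3, true_enrichment = 1)
  expect_equal(true_occupancy_ratio(asym), (0.3 * 0.9) / (0.7 * 0.1))
})

test_that("simulation is deterministic for identical inputs", {
  pair <- small_pair()
  ls <- make_landscape(pair, background = 1, cen_height = 5, cen_width = 300)
  cfg <- sim_config(3000, 3000, read_length = 40, seed = 99)
  a <- simulate_experiment(pair, ls, cfg)
  b <- simulate_experiment(pair, ls, cfg)
  expect_identical(as.character(a$ip_reads), as.character(b$ip_reads))
  expect_identical(as.character(a$wce_reads), as.character(b$wce_reads))
  expect_identical(a$truth$ip, b$truth$ip)
  expect_identical(a$truth$wce, b$truth$wce)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(0, 100), "positive")
  expect_error(sim_config(100, 100, spike_fraction_ip = 0), "strictly")
  expect_error(sim_config(100, 100, spike_fraction_wce = 1), "strictly")
  pair <- small_pair()
  ls <- make_landscape(pair)
  expect_error(simulate_experiment(pair, ls,
                                   sim_config(10, 10, read_length = 9000)),
               "exceeds")
})
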