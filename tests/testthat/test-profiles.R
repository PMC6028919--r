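test_that("uniform tracks give constant anchored profiles", {
  tr <- uniform_track(1)
  ann <- small_pair()$annotation
  cts <- calibration_counts(1e6, 1e6, 1e6, 1e6)  # OR 1, denominator 1e6
  prof <- cen_meta_profile(tr, ann, half_width = 1500, counts = cts)
  expect_equal(prof$value, rep(1.0, 3001))
  expect_equal(prof$offset, -1500:1500)
  expect_equal(prof$n, rep(4L, 3001))
  expect_error(cen_meta_profile(tr, c(chrZ = 5)[0], half_width = 10), "empty")
})

test_that("anchored averaging equals the naive window-matrix oracle", {
  lens <- c(chrA = 4000, chrB = 4000, chrC = 4000)
  tr <- random_track(lens, seed = 3)
  # anchors include one close enough to the end for window truncation
  anchors <- c(chrA = 2000, chrB = 700, chrC = 3600)
  for (hw in c(250, 1000)) {
    prof <- cen_meta_profile(tr, anchors, half_width = hw)
    orc <- profile_oracle(tr$values, names(anchors), anchors,
                          rep(1, 3), hw)
    expect_equal(prof$value, orc$value, tolerance = 1e-12)
    expect_equal(prof$n, unname(orc$n))
  }
  # truncated windows: offsets beyond a chromosome end lose that anchor
  prof <- cen_meta_profile(tr, anchors, half_width = 1000)
  expect_equal(prof$n[prof$offset > 400], rep(2L, 600))
})

test_that("gene metagenes are strand-oriented with downstream positive", {
  L <- 10000
  v <- numeric(L)
  # plus-strand gene [1000, 3500); delta peak 100 bp after its TES (3499)
  v[3599 + 1] <- 7
  genes <- data.frame(chrom = "c1", start0 = 1000, end0 = 3500, strand = "+",
                      name = "gp", stringsAsFactors = FALSE)
  tr <- coverage_track(list(c1 = v))
  prof <- feature_meta_profile(tr, genes, anchor = "TES", half_width = 300)
  expect_equal(prof$value[prof$offset == 100], 7)
  expect_equal(sum(prof$value != 0), 1)
  # mirror-image minus-strand gene gives the same profile
  vm <- numeric(L)
  vm[(L - 3599 - 1) + 1] <- 7
  genes_m <- data.frame(chrom = "c1", start0 = L - 3500, end0 = L - 1000,
                        strand = "-", name = "gm", stringsAsFactors = FALSE)
  prof_m <- feature_meta_profile(coverage_track(list(c1 = vm)), genes_m,
                                 anchor = "TES", half_width = 300)
  expect_equal(prof_m$value, prof$value)
  # TSS anchoring: peak 50 bp downstream of the plus-strand TSS (1000)
  v2 <- numeric(L); v2[1050 + 1] <- 3
  prof_tss <- feature_meta_profile(coverage_track(list(c1 = v2)), genes,
                                   anchor = "TSS", half_width = 300)
  expect_equal(prof_tss$value[prof_tss$offset == 50], 3)
})

test_that("metagenes match the per-gene window oracle and filter lengths", {
  pair <- small_pair()
  ann <- pair$annotation
  tr <- random_track(ann$chrom_lengths, seed = 17)
  g <- ann$genes
  long <- g[(g$end0 - g$start0) > 2000, ]
  prof <- feature_meta_profile(tr, ann, anchor = "TES", half_width = 500)
  anchor0 <- ifelse(long$strand == "+", long$end0 - 1, long$start0)
  dir <- ifelse(long$strand == "+", 1, -1)
  orc <- profile_oracle(tr$values, long$chrom, anchor0, dir, 500)
  expect_equal(prof$value, orc$value, tolerance = 1e-12)
  expect_equal(prof$n, unname(orc$n))
  # length filter is exclusive at min_length
  expect_equal(max(prof$n), nrow(long))
  expect_error(feature_meta_profile(tr, ann, min_length = 1e6), "survive")
  # per-class averaging splits genes by classification
  cls <- classify_gene_pairs(ann)
  profs <- feature_meta_profile(tr, ann, half_width = 500, classes = cls)
  expect_true(all(names(profs) %in% c("convergent", "tandem", "boundary")))
  got_total <- sum(vapply(profs, function(p) max(p$n), integer(1)))
  expect_equal(got_total, nrow(long))
})

test_that("gene pair classes follow orientation definitions", {
  g <- data.frame(
    chrom = "c1",
    start0 = c(100, 3000, 6000, 9000),
    end0 = c(2500, 5500, 8500, 11500),
    strand = c("+", "-", "+", "+"),
    name = paste0("g", 1:4), stringsAsFactors = FALSE)
  cls <- classify_gene_pairs(g, at = "TES")
  got <- setNames(cls$class, cls$name)
  expect_equal(got[["g1"]], "convergent")  # + then -: both face each other
  expect_equal(got[["g2"]], "convergent")
  expect_equal(got[["g3"]], "tandem")      # + then +
  expect_equal(got[["g4"]], "boundary")    # chromosome-terminal
  # at the TSS, back-to-back opposite-strand genes are divergent
  tss <- classify_gene_pairs(g, at = "TSS")
  got_tss <- setNames(tss$class, tss$name)
  expect_equal(got_tss[["g1"]], "boundary")   # nothing upstream of g1
  expect_equal(got_tss[["g2"]], "divergent")  # - gene, + gene back-to-back
  expect_equal(got_tss[["g3"]], "divergent")
  expect_equal(got_tss[["g4"]], "tandem")
  # nested genes take the boundary class
  gn <- rbind(g, data.frame(chrom = "c1", start0 = 3500, end0 = 4000,
                            strand = "+", name = "inner"))
  cn <- classify_gene_pairs(gn)
  expect_equal(cn$class[cn$name == "inner"], "boundary")
})

test_that("random gene sets match the exhaustive pairwise oracle", {
  for (seed in c(2, 9, 23)) {
    set.seed(seed)
    n <- 50
    starts <- sort(sample.int(200000, n)) * 1L
    lens <- sample(500:3000, n, replace = TRUE)
    g <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                    start0 = starts, end0 = starts + lens,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    name = sprintf("s%02d", 1:n), stringsAsFactors = FALSE)
    # drop overlaps so the fixture is clean, as the classifier assumes
    g <- do.call(rbind, lapply(split(g, g$chrom), function(gc) {
      gc <- gc[order(gc$start0), ]
      keep <- c(TRUE, gc$start0[-1] >= cummax(gc$end0)[-nrow(gc)])
      gc[keep, ]
    }))
    for (at in c("TES", "TSS")) {
      got <- classify_gene_pairs(g, at = at)
      orc <- classify_oracle(g, at = at)
      m <- merge(got, orc, by = "name")
      expect_identical(m$class.x, m$class.y)
    }
  }
})

test_that("difference profiles subtract offset-wise with strict windows", {
  lens <- c(chrA = 3000)
  tr <- random_track(lens, seed = 5)
  a <- cen_meta_profile(tr, c(chrA = 1500), half_width = 400)
  expect_equal(difference_profile(a, a)$value, rep(0, 801))
  b <- a; b$value <- a$value + 2.5
  d <- difference_profile(b, a)
  expect_equal(d$value, rep(2.5, 801))
  expect_equal(d$n, a$n)
  wrong <- cen_meta_profile(tr, c(chrA = 1500), half_width = 300)
  expect_error(difference_profile(a, wrong), "mismatched")
  cal <- a; cal$calibrated <- TRUE
  expect_error(difference_profile(cal, a), "calibrated")
})

test_that("percent-of-reference scales by the reference window mean", {
  off <- -100:100
  ref <- calichip:::meta_profile(off, rep(4, 201), rep(16L, 201))
  p <- calichip:::meta_profile(off, rep(4, 201), rep(16L, 201))
  expect_equal(percent_of_reference(p, ref)$value, rep(100, 201))
  z <- calichip:::meta_profile(off, rep(0, 201), rep(16L, 201))
  expect_equal(percent_of_reference(z, ref)$value, rep(0, 201))
  # mutant at 25% of a uniform reference has window mean 25
  mut <- calichip:::meta_profile(off, rep(1, 201), rep(16L, 201))
  expect_equal(mean(percent_of_reference(mut, ref)$value), 25)
  expect_equal(percent_of_reference(mut, ref)$units, "percent")
  expect_error(percent_of_reference(p, z), "> 0")
})

test_that("pericentric/arm summary matches masked means", {
  lens <- c(chrA = 100000)
  anchors <- c(chrA = 50000)
  tr <- uniform_track_custom <- coverage_track(list(chrA = rep(2, 100000)))
  rs <- region_summary(tr, anchors, arm_threshold = 30000)
  expect_equal(rs$ratio, 1.0)
  # all signal within +/- 30 kb leaves empty arms at zero
  v <- numeric(100000); v[(50000 - 30000):(50000 + 30000) + 1] <- 5
  rs2 <- region_summary(coverage_track(list(chrA = v)), anchors)
  expect_equal(rs2$arm_mean, 0)
  # random fixture against brute-force masked means
  tr3 <- random_track(lens, seed = 77)
  rs3 <- region_summary(tr3, anchors, arm_threshold = 30000)
  pos <- 0:(100000 - 1)
  m <- abs(pos - 50000) <= 30000
  expect_equal(rs3$pericentric_mean, mean(tr3$values$chrA[m]))
  expect_equal(rs3$arm_mean, mean(tr3$values$chrA[!m]))
  expect_error(region_summary(tr3, anchors, arm_threshold = 2e5), "empty")
})

test_that("two-track scatter fits a through-origin slope and flags bins", {
  lens <- c(chrA = 6000, chrB = 6000)
  a <- random_track(lens, seed = 31)
  a$values <- lapply(a$values, function(v) v + 1)   # strictly positive
  b <- a
  b$values <- lapply(b$values, function(v) 2 * v)
  sc <- track_scatter(a, b, bin_size = 500)
  expect_equal(sc$slope, 2.0)
  expect_true(all(abs(sc$bins$ratio - 2) < 1e-12))
  expect_false(any(sc$bins$flagged))
  # zeroing near anchors halves... removes those bins' signal in b
  anchors <- c(chrA = 3000, chrB = 3000)
  b2 <- a
  for (cn in names(anchors)) {
    v <- b2$values[[cn]]
    v[(anchors[[cn]] - 300):(anchors[[cn]] + 300) + 1] <- 0
    b2$values[[cn]] <- v
  }
  sc2 <- track_scatter(a, b2, bin_size = 500)
  # brute-force expected flags: bins mostly covered by the zeroed window
  expected_flag <- with(sc2$bins, mapply(function(cn, s, e) {
    z0 <- anchors[[cn]] - 300; z1 <- anchors[[cn]] + 300
    min(e, z1 + 1) - max(s, z0) >= 250
  }, chrom, start0, end0))
  expect_equal(sc2$bins$flagged, unname(expected_flag))
  # single-bin genome: slope is mean_b / mean_a
  a1 <- coverage_track(list(c1 = c(1, 2, 3)))
  b1 <- coverage_track(list(c1 = c(2, 2, 5)))
  s1 <- track_scatter(a1, b1, bin_size = 10)
  expect_equal(s1$slope, 3 / 2)
  expect_error(track_scatter(a1, random_track(lens, 1), 10), "different")
})

test_that("a landscape symmetric about anchors yields a symmetric profile", {
  pair <- small_pair()
  ls <- make_landscape(pair, background = 1, cen_height = 10, cen_width = 300,
                       flank_height = 15, flank_offset = 500,
                       flank_width = 120)
  tr <- coverage_track(ls$weights)
  prof <- cen_meta_profile(tr, pair$annotation, half_width = 1500)
  expect_equal(prof$value, rev(prof$value), tolerance = 1e-12)
})
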