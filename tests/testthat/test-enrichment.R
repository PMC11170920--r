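test_that("overlap fraction counts oCGIs touching any peak", {
  ocgis <- bed_frame("chr1", seq(0, 9000, by = 1000),
                     seq(0, 9000, by = 1000) + 200)
  peaks <- bed_frame("chr1", c(100, 2100, 4100, 6199), c(150, 2150, 4150,
                                                         6300))
  expect_equal(overlap_fraction(ocgis, peaks), 40.0)
  expect_equal(overlap_fraction(ocgis, peaks[0, ]), 0.0)
  expect_error(overlap_fraction(ocgis[0, ], peaks), "empty")
  # 200-interval fixture against the quadratic oracle
  set.seed(3)
  q <- random_intervals(200)
  s <- random_intervals(120)
  expect_equal(overlap_fraction(q, s), 100 * mean(overlap_oracle(q, s)))
})

test_that("shuffled intervals preserve length and chromosome and avoid exclusions", {
  set.seed(5)
  ocgis <- random_intervals(60, chroms = c("chr1", "chr2"), size = 9e4)
  excl <- bed_frame(rep(c("chr1", "chr2"), each = 5),
                    rep(seq(0, 40000, by = 10000), 2),
                    rep(seq(0, 40000, by = 10000), 2) + 3000)
  sizes <- c(chr1 = 1e5, chr2 = 1e5)
  for (r in 1:25) {
    sh <- shuffle_intervals(ocgis, sizes, excl)
    expect_equal(sh$end - sh$start, ocgis$end - ocgis$start)
    expect_equal(sh$chrom, ocgis$chrom)
    expect_false(any(overlap_any(sh, excl)))
    m <- merge_intervals(sh)
    expect_equal(sum(m$end - m$start), sum(sh$end - sh$start))  # disjoint
  }
  # impossible placement errors out naming the chromosome
  expect_error(
    shuffle_intervals(bed_frame("chr1", 0, 50),
                      c(chr1 = 100), bed_frame("chr1", 0, 99),
                      max_attempts = 50),
    "chr1")
})

test_that("saturated peak coverage gives p = 1 and p-values stay in (0,1]", {
  ocgis <- bed_frame("chr1", c(100, 500, 900), c(200, 600, 1000))
  peaks <- bed_frame("chr1", 0, 10000)  # tiles everything
  res <- shuffle_test(ocgis, peaks, c(chr1 = 10000), rounds = 200,
                      seed = 1)
  expect_equal(res$observed, 100)
  expect_equal(res$expected, 100)
  expect_equal(res$p_value, 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("planted overlap enrichment is detected against the shuffle null", {
  set.seed(3)
  sizes <- c(chr1 = 2e5, chr2 = 2e5)
  # peaks tile ~10% of each chromosome
  peaks <- bed_frame(rep(names(sizes), each = 10),
                     rep(seq(0, 1.8e5, by = 2e4), 2),
                     rep(seq(0, 1.8e5, by = 2e4), 2) + 2000)
  # 80% of oCGIs planted inside peaks
  n <- 100
  inside <- peaks[sample.int(nrow(peaks), 0.8 * n, replace = TRUE), ]
  ocgis <- rbind(
    bed_frame(inside$chrom, inside$start + 500, inside$start + 800),
    random_intervals(0.2 * n, chroms = names(sizes), size = 1.9e5,
                     max_len = 300))
  res <- shuffle_test(ocgis, peaks, sizes, rounds = 1000, seed = 3)
  expect_gt(res$observed, 75)
  expect_lt(res$expected, 30)
  expect_lt(res$p_value, 0.005)
})

test_that("RPKM follows its closed form", {
  expect_equal(quantify_rpkm(500, 10, 1e7), 2.0)
  expect_equal(quantify_rpkm(500, 0, 1e7), 0.0)
  expect_equal(quantify_rpkm(1000, 1000, 1e6), 1000.0)
  expect_error(quantify_rpkm(500, 10, 0), "library")
})

test_that("conservation summaries aggregate overlapping elements", {
  none <- conservation_summary("chr1", 0, 100,
                               bed_frame("chr2", 0, 100, score = 5))
  expect_equal(none, list(max_lod = 0, aggregate_lod = 0,
                          covered_fraction = 0))
  elements <- bed_frame("chr1", c(10, 50), c(20, 90), score = c(5, 7))
  cs <- conservation_summary("chr1", 0, 100, elements)
  expect_equal(cs$max_lod, 7)
  expect_equal(cs$aggregate_lod, 12)
  expect_equal(cs$covered_fraction, 0.5)
  full <- conservation_summary("chr1", 10, 20,
                               bed_frame("chr1", 0, 100, score = 3))
  expect_equal(full$covered_fraction, 1.0)
})

test_that("conservation coverage matches a per-base oracle", {
  set.seed(13)
  for (rep in 1:5) {
    elements <- random_intervals(30, chroms = "chr1", size = 9000)
    elements$score <- runif(30, 0, 10)
    cs <- conservation_summary("chr1", 1000, 8000, elements)
    mask <- bitmask_oracle(elements, "chr1", 9000)[1001:8000]
    expect_equal(cs$covered_fraction, mean(mask))
    hit <- elements$start < 8000 & elements$end > 1000
    expect_equal(cs$max_lod, if (any(hit)) max(elements$score[hit]) else 0)
    expect_equal(cs$aggregate_lod, sum(elements$score[hit]))
  }
})

test_that("age assignment takes the oldest age, collapses ancient clades, and validates species", {
  amap <- bed_frame("chr1", c(0, 500, 1000), c(500, 1000, 1500),
                    name = c("Primate", "Amniota", "Tetrapoda"))
  expect_equal(assign_age("chr1", 100, 900, amap), "Amniota")
  expect_equal(assign_age("chr1", 1100, 1400, amap), "OlderThanAmniota")
  expect_equal(assign_age("chr1", 5000, 6000, amap), "Unknown")
  # a pig interval dated "Human" is converted to Unknown
  pig_valid <- c("Eutheria", "Theria", "Mammalia", "Amniota", "Tetrapoda",
                 "Gnathostomata", "Vertebrata")
  hmap <- bed_frame("chr1", 0, 500, name = "Human")
  expect_equal(assign_age("chr1", 0, 400, hmap,
                          species_valid_ages = pig_valid), "Unknown")
  expect_equal(assign_age("chr1", 0, 400, hmap), "Human")
})
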