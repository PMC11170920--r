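identity_map <- function(chroms, size) {
  coordinate_map(data.frame(src_chrom = chroms, src_start = 0,
                            src_end = size, tgt_chrom = chroms,
                            tgt_start = 0, tgt_end = size,
                            stringsAsFactors = FALSE))
}

test_that("interval mapping handles identity, insertions and gaps", {
  idm <- identity_map("chr1", 1e6)
  m <- map_interval("chr1", 1000, 1500, idm)
  expect_equal(m, list(chrom = "chr1", start = 1000, end = 1500))

  # a 100 bp target insertion upstream shifts downstream coordinates +100
  ins <- coordinate_map(data.frame(
    src_chrom = "chr1", src_start = c(0, 500), src_end = c(500, 2000),
    tgt_chrom = "chr1", tgt_start = c(0, 600), tgt_end = c(500, 2100)))
  m <- map_interval("chr1", 1000, 1500, ins)
  expect_equal(m$start, 1100)
  expect_equal(m$end, 1600)

  # 60% of bases unaligned with minMatch 0.8 -> unmapped
  gap <- coordinate_map(data.frame(
    src_chrom = "chr1", src_start = 0, src_end = 200,
    tgt_chrom = "chr1", tgt_start = 0, tgt_end = 200))
  expect_true(is.na(map_interval("chr1", 100, 350, gap)$start))
  # but mapped when 80% of bases align
  expect_false(is.na(map_interval("chr1", 40, 240, gap)$start))
})

test_that("mapping round-trips exactly through indel-free maps", {
  spec <- synthetic_spec(seed = 19, n_chroms = 1, chrom_length_bp = 2e5,
                         n_islands = 20, indel_rate_per_kb = 0)
  pair <- make_species_pair(spec)
  # identity maps when no indels are planted
  expect_equal(pair$maps$A_to_human$blocks$src_start,
               pair$maps$A_to_human$blocks$tgt_start)
  set.seed(1)
  iv <- random_intervals(20, chroms = "chr1", size = 1.9e5)
  there <- map_intervals(iv, pair$maps$A_to_human)
  back <- map_intervals(there, pair$maps$human_to_A)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
})

test_that("orthologous sites classify shared and species-specific oCGIs", {
  idm <- identity_map(c("chr1"), 1e5)
  # species B lacks orthologous sequence beyond 50 kb
  half <- coordinate_map(data.frame(
    src_chrom = "chr1", src_start = 0, src_end = 5e4,
    tgt_chrom = "chr1", tgt_start = 0, tgt_end = 5e4))
  ocgis_A <- bed_frame("chr1", c(1000, 10000, 60000),
                       c(1400, 10400, 60400),
                       name = c("shared1", "Aonly1", "Anoortho"))
  ocgis_A$obs_exp_ratio <- c(0.9, 0.85, 0.8)
  ocgis_B <- bed_frame("chr1", 1100, 1500, name = "shared1B")
  ocgis_B$obs_exp_ratio <- 0.95
  sites <- build_orthologous_sites(ocgis_A, ocgis_B, idm, idm, idm, half)
  # the 60 kb oCGI has no B ortholog -> no site emitted
  expect_equal(nrow(sites), 2)
  expect_setequal(sites$label, c("shared", "A_only"))
  sh <- sites[sites$label == "shared", ]
  expect_equal(sh$oe_A, 0.9)
  expect_equal(sh$oe_B, 0.95)
  # labels partition sites
  expect_equal(sum(table(sites$label)), nrow(sites))
})

test_that("planted turnover fractions are recovered through the full pipeline", {
  spec <- synthetic_spec(seed = 17, n_chroms = 2, chrom_length_bp = 4e5,
                         n_islands = 150,
                         turnover_fractions = c(shared = 0.4, A_only = 0.3,
                                                B_only = 0.3))
  pair <- make_species_pair(spec)
  cgi_A <- call_cgis(pair$A)
  cgi_B <- call_cgis(pair$B)
  sites <- build_orthologous_sites(cgi_A, cgi_B,
                                   pair$maps$A_to_human,
                                   pair$maps$B_to_human,
                                   pair$maps$human_to_A,
                                   pair$maps$human_to_B)
  planted <- prop.table(table(pair$islands$status))
  recovered <- prop.table(table(factor(sites$label,
                                       levels = names(planted))))
  n <- nrow(sites)
  for (lab in names(planted)) {
    half_ci <- 1.96 * sqrt(planted[[lab]] * (1 - planted[[lab]]) / n)
    expect_lt(abs(recovered[[lab]] - planted[[lab]]), half_ci + 0.02)
  }
})

test_that("the minimal O/E difference filter is a monotone filter on specific sites", {
  sites <- data.frame(label = c("A_only", "A_only", "B_only", "shared"),
                      oe_A = c(0.62, 0.80, 0.10, 0.9),
                      oe_B = c(0.59, 0.55, 0.75, 0.8),
                      stringsAsFactors = FALSE)
  expect_identical(apply_min_oe_delta(sites, 0), sites)
  f1 <- apply_min_oe_delta(sites, 0.1)
  expect_false(any(f1$oe_A == 0.62))       # |0.03| < 0.1 removed
  f2 <- apply_min_oe_delta(sites, 0.2)
  expect_true(0.80 %in% f2$oe_A)           # |0.25| >= 0.2 retained
  expect_error(apply_min_oe_delta(sites, -1), "non-negative")
  # monotone: growing delta never increases the species-specific count
  counts <- vapply(seq(0, 1, by = 0.05), function(d) {
    sum(apply_min_oe_delta(sites, d)$label != "shared")
  }, 0)
  expect_true(all(diff(counts) <= 0))
  # shared sites never removed
  expect_true(all(vapply(seq(0, 1, by = 0.25), function(d) {
    sum(apply_min_oe_delta(sites, d)$label == "shared") == 1
  }, TRUE)))
})

test_that("gain/loss polarization follows the outgroup rule", {
  pat <- data.frame(human = c(TRUE, FALSE, TRUE, TRUE),
                    rhesus = c(FALSE, TRUE, FALSE, TRUE),
                    marmoset = c(FALSE, TRUE, TRUE, TRUE))
  counts <- polarize_gain_loss(pat, "human", "rhesus", "marmoset")
  expect_equal(counts[["gain"]], 1)
  expect_equal(counts[["loss"]], 1)
  expect_equal(counts[["unpolarized"]], 2)
  expect_equal(sum(counts), nrow(pat))
  expect_error(polarize_gain_loss(pat, "human", "rhesus", "mouse"),
               "mouse")
})

test_that("presence patterns merge projections across species", {
  idm <- identity_map("chr1", 1e5)
  ocgis <- list(human = bed_frame("chr1", c(100, 5000), c(400, 5300)),
                rhesus = bed_frame("chr1", 150, 450),
                mouse = bed_frame("chr1", 9000, 9300))
  pat <- presence_patterns(ocgis, list(human = idm, rhesus = idm,
                                       mouse = idm))
  expect_equal(nrow(pat), 3)
  expect_equal(pat$human, c(TRUE, TRUE, FALSE))
  expect_equal(pat$rhesus, c(TRUE, FALSE, FALSE))
  expect_equal(pat$mouse, c(FALSE, FALSE, TRUE))
})
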