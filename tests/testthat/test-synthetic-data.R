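test_that("generators are pure functions of their spec", {
  spec <- synthetic_spec(seed = 3, n_chroms = 1, chrom_length_bp = 1e5,
                         n_islands = 10)
  g1 <- make_genome(spec); g2 <- make_genome(spec)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$islands, g2$islands)
  e1 <- make_expression(spec); e2 <- make_expression(spec)
  expect_identical(e1, e2)
})

test_that("planted islands hit their GC and O/E targets", {
  spec <- synthetic_spec(seed = 7, n_chroms = 1, chrom_length_bp = 3e5,
                         n_islands = 30, island_oe_target = 1.0,
                         island_gc = 0.6)
  g <- make_genome(spec)
  for (i in seq_len(nrow(g$islands))) {
    st <- cgi_stats(g$genome[[g$islands$chrom[i]]], g$islands$start[i],
                    g$islands$end[i])
    expect_lt(abs(st$obs_exp_ratio - 1.0), 0.05)
    expect_lt(abs(st$gc_fraction - 0.6), 0.05)
  }
})

test_that("an island-free genome yields almost no calls", {
  spec <- synthetic_spec(seed = 5, n_chroms = 1, chrom_length_bp = 2e6,
                         n_islands = 0)
  g <- make_genome(spec)
  calls <- call_cgis(g$genome)
  expect_lt(nrow(calls), 2)  # < 1 false call per Mb
})

test_that("infeasible island O/E targets are rejected", {
  expect_error(synthetic_spec(island_oe_target = 8, island_gc = 0.5),
               "achievable maximum")
})

test_that("degenerate turnover plants all-shared islands", {
  spec <- synthetic_spec(seed = 37, n_chroms = 1, chrom_length_bp = 3e5,
                         n_islands = 60,
                         turnover_fractions = c(shared = 1, A_only = 0,
                                                B_only = 0))
  pair <- make_species_pair(spec)
  expect_true(all(pair$islands$status == "shared"))
  sites <- build_orthologous_sites(call_cgis(pair$A), call_cgis(pair$B),
                                   pair$maps$A_to_human,
                                   pair$maps$B_to_human,
                                   pair$maps$human_to_A,
                                   pair$maps$human_to_B)
  expect_gt(mean(sites$label == "shared"), 0.97)
})

test_that("degraded islands fall below the O/E threshold in the absent species", {
  spec <- synthetic_spec(seed = 41, n_chroms = 1, chrom_length_bp = 3e5,
                         n_islands = 40,
                         turnover_fractions = c(shared = 0, A_only = 1,
                                                B_only = 0))
  pair <- make_species_pair(spec)
  for (i in seq_len(nrow(pair$islands))) {
    st <- cgi_stats(pair$B[[pair$islands$chrom_B[i]]],
                    pair$islands$start_B[i], pair$islands$end_B[i])
    expect_lt(st$obs_exp_ratio, 0.6)
  }
})

test_that("labeled-site simulation preserves marginals and coupling", {
  null <- simulate_labeled_sites(20000, coupling = 1, seed = 1)
  expect_equal(mean(null$peak_label == "none"), 0.2, tolerance = 0.03)
  tab <- table(null$label, null$peak_label)
  # independence at coupling 1: conditional ~ marginal
  pA_given_A <- tab["A_only", "A_only"] / sum(tab["A_only", ])
  pA <- sum(tab[, "A_only"]) / sum(tab)
  expect_lt(abs(pA_given_A - pA), 0.02)

  coupled <- simulate_labeled_sites(20000, coupling = 3, seed = 2)
  keep <- coupled$peak_label != "none"
  tab <- table(coupled$label[keep], coupled$peak_label[keep])
  pA_given_A <- tab["A_only", "A_only"] / sum(tab["A_only", ])
  pA <- sum(tab[, "A_only"]) / sum(tab)
  expect_equal(pA_given_A / pA, 3, tolerance = 0.15)
  # infeasible coupling rejected
  expect_error(simulate_labeled_sites(10, coupling = 10), "infeasible")
})

test_that("peak placement couples peak labels to island status and boosts signal", {
  spec <- synthetic_spec(seed = 43, n_chroms = 2, chrom_length_bp = 4e5,
                         n_islands = 150, peak_coupling = 2,
                         turnover_fractions = c(shared = 0.6,
                                                A_only = 0.2,
                                                B_only = 0.2),
                         signal_boost_at_ocgi = 3)
  pair <- make_species_pair(spec)
  pk <- make_peaks_and_signal(pair, spec)
  truth <- pk$truth
  keep <- truth$peak_label != "none"
  tab <- table(truth$status[keep], truth$peak_label[keep])
  # matched conditional exceeds the marginal
  pA_given_A <- tab["A_only", "A_only"] / sum(tab["A_only", ])
  pA <- sum(tab[, "A_only"]) / sum(tab)
  expect_gt(pA_given_A, pA)
  # planted peak labels are realized as intervals in the right species:
  # every island peak present in A (A_only or shared) exists in peaks_A
  pa_named <- pk$peaks_A[!grepl("bgpeak", pk$peaks_A$name), ]
  expect_setequal(pa_named$name,
                  truth$name[truth$peak_label %in% c("A_only", "shared") &
                               !is.na(truth$start_A)])
  pb_named <- pk$peaks_B[!grepl("bgpeak", pk$peaks_B$name), ]
  expect_setequal(pb_named$name,
                  truth$name[truth$peak_label %in% c("B_only", "shared") &
                               !is.na(truth$start_B)])
  # signal boost visible at oCGI-containing peaks
  pa <- pk$peaks_A
  expect_gt(median(pa$signal[pa$has_ocgi]),
            2 * median(pa$signal[!pa$has_ocgi]))
  # read counts consistent with RPKM at the library size
  rpkm <- quantify_rpkm(pa$end - pa$start, pa$read_count,
                        pk$library_sizes[["A"]])
  expect_equal(rpkm, pa$signal, tolerance = 0.02)
})
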