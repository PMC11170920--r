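test_that("TPM follows its closed form and sums to one million", {
  expect_equal(compute_tpm(c(100, 300), c(1000, 3000)), c(5e5, 5e5))
  expect_equal(compute_tpm(42, 1234), 1e6)
  expect_error(compute_tpm(c(0, 0), c(100, 100)), "all-zero")
  set.seed(2)
  counts <- rpois(20, 500)
  lens <- round(runif(20, 300, 8000))
  tpm <- compute_tpm(counts, lens, ids = sprintf("g%d", 1:20))
  expect_equal(sum(tpm), 1e6)
  # independent recomputation
  rate <- counts / (lens / 1000)
  expect_equal(unname(tpm), 1e6 * rate / sum(rate))
})

test_that("regulatory domains follow the basal-plus-extension rules", {
  sizes <- c(chr1 = 1e7)
  iso <- data.frame(id = "g1", chrom = "chr1", tss = 2e6, strand = "+",
                    stringsAsFactors = FALSE)
  d <- great_domains(iso, sizes)
  expect_equal(d$basal_start, 1995000)
  expect_equal(d$basal_end, 2001000)
  expect_equal(d$start, 995000)   # 1 Mb beyond the basal edge
  expect_equal(d$end, 3001000)
  expect_equal(d$basal_end - d$basal_start, 6000)
  # minus-strand basal window mirrors
  mi <- great_domains(data.frame(id = "g2", chrom = "chr1", tss = 2e6,
                                 strand = "-"), sizes)
  expect_equal(mi$basal_start, 2e6 - 1000)
  expect_equal(mi$basal_end, 2e6 + 5000)
  # two + strand genes 10 kb apart: upstream extension stops at the
  # downstream gene's basal start
  two <- data.frame(id = c("up", "down"), chrom = "chr1",
                    tss = c(2e6, 2e6 + 1e4), strand = "+",
                    stringsAsFactors = FALSE)
  d2 <- great_domains(two, sizes)
  expect_equal(d2$end[d2$id == "up"], d2$basal_start[d2$id == "down"])
  expect_equal(d2$start[d2$id == "down"], d2$basal_end[d2$id == "up"])
})

test_that("regulatory domains match the brute-force nearest-basal scan", {
  set.seed(50)
  sizes <- c(chrA = 5e6, chrB = 5e6)
  genes <- data.frame(id = sprintf("g%d", 1:50),
                      chrom = sample(names(sizes), 50, replace = TRUE),
                      tss = round(runif(50, 1e4, 4.99e6)),
                      strand = sample(c("+", "-"), 50, replace = TRUE),
                      stringsAsFactors = FALSE)
  d <- great_domains(genes, sizes)
  o <- great_oracle(genes, sizes)
  expect_equal(d$start, o$start)
  expect_equal(d$end, o$end)
  expect_true(all(d$start <= d$basal_start & d$end >= d$basal_end))
})

test_that("gene set assignment partitions genes by qualifying sites", {
  domains <- data.frame(id = c("gA", "gB", "gM", "g0"), chrom = "chr1",
                        basal_start = 0, basal_end = 1,
                        start = c(0, 2e5, 4e5, 6e5),
                        end = c(1e5, 3e5, 5e5, 7e5),
                        stringsAsFactors = FALSE)
  sites <- bed_frame("chr1", c(5e4, 2.5e5, 4.2e5, 4.6e5),
                     c(5e4 + 300, 2.5e5 + 300, 4.2e5 + 300, 4.6e5 + 300))
  sites$label <- c("A_only", "B_only", "A_only", "B_only")
  sets <- assign_gene_sets(domains, sites)
  expect_equal(unname(sets[c("gA", "gB", "gM", "g0")]),
               c("A_only_set", "B_only_set", "mixed_set",
                 "background_set"))
  expect_error(assign_gene_sets(domains,
                                within(sites, label <- "shared")),
               "A_only or B_only")
})

run_expr_test <- function(seed, effect, rounds = 600, n_genes = 2000) {
  spec <- synthetic_spec(seed = seed, n_genes = n_genes,
                         expression_log2_effect = effect)
  genes <- make_expression(spec)
  tpm_A <- compute_tpm(genes$counts_A, genes$exon_length_bp, genes$id)
  tpm_B <- compute_tpm(genes$counts_B, genes$exon_length_bp, genes$id)
  expression_ratio_test(setNames(genes$set_truth, genes$id), tpm_A,
                        tpm_B, rounds = rounds, seed = seed)
}

test_that("a planted expression effect is recovered with the right magnitude", {
  res <- run_expr_test(seed = 13, effect = 1, rounds = 1000)
  a <- res[res$set == "A_only_set", ]
  b <- res[res$set == "B_only_set", ]
  expect_lt(abs(a$normalized_median - 1), 0.15)
  expect_lt(abs(b$normalized_median + 1), 0.15)
  expect_lt(a$p, 0.01)
  expect_lt(b$p, 0.01)
})

test_that("the ratio test sign-flips exactly under species swap", {
  spec <- synthetic_spec(seed = 13, n_genes = 2000,
                         expression_log2_effect = 1)
  genes <- make_expression(spec)
  tpm_A <- compute_tpm(genes$counts_A, genes$exon_length_bp, genes$id)
  tpm_B <- compute_tpm(genes$counts_B, genes$exon_length_bp, genes$id)
  assign <- setNames(genes$set_truth, genes$id)
  fwd <- expression_ratio_test(assign, tpm_A, tpm_B, rounds = 400,
                               seed = 99)
  swapped_assign <- assign
  swapped_assign[assign == "A_only_set"] <- "B_only_set"
  swapped_assign[assign == "B_only_set"] <- "A_only_set"
  rev <- expression_ratio_test(swapped_assign, tpm_B, tpm_A, rounds = 400,
                               seed = 99)
  expect_equal(rev$normalized_median[rev$set == "B_only_set"],
               -fwd$normalized_median[fwd$set == "A_only_set"])
  expect_equal(rev$normalized_median[rev$set == "A_only_set"],
               -fwd$normalized_median[fwd$set == "B_only_set"])
  expect_equal(rev$p[rev$set == "B_only_set"],
               fwd$p[fwd$set == "A_only_set"])
})

test_that("without a planted effect the normalized medians stay near zero", {
  res <- lapply(1:10, function(s) run_expr_test(seed = 100 + s,
                                                effect = 0, rounds = 400))
  meds <- unlist(lapply(res, function(r) r$normalized_median))
  ps <- unlist(lapply(res, function(r) r$p))
  expect_gte(mean(ps >= 0.05), 0.9)
  expect_lt(median(abs(meds)), 0.1)
})

test_that("a test set drawn from the background has a normalized median near zero", {
  spec <- synthetic_spec(seed = 77, n_genes = 500,
                         expression_log2_effect = 0)
  genes <- make_expression(spec, gene_sets_truth = rep("background_set",
                                                       500))
  set.seed(77)
  truth <- rep("background_set", 500)
  truth[sample.int(500, 40)] <- "A_only_set"
  genes$set_truth <- truth
  res <- run_expr_test_from <- expression_ratio_test(
    setNames(truth, genes$id),
    compute_tpm(genes$counts_A, genes$exon_length_bp, genes$id),
    compute_tpm(genes$counts_B, genes$exon_length_bp, genes$id),
    rounds = 600, seed = 77)
  a <- res[res$set == "A_only_set", ]
  expect_lt(abs(a$normalized_median), 0.15)
  expect_gte(a$p, 0.05)
})
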