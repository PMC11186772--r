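test_that("VAF quantiles use the ECDF with shared ties and 0.005 bins", {
  m <- data.table::data.table(
    tumour_id = "t", chrom = "chr1", pos = seq_len(400) * 10L,
    ref = "T", alt = "C", kind = "sub",
    vaf = c(seq(0.001, 0.4, length.out = 398), 0.25, 0.25))
  b <- vaf_quantile_bins(m, s6_spans = data.table::data.table(
    chrom = character(), start = integer(), end = integer()))
  expect_equal(nrow(b), 400L)
  # monotone: higher VAF never gets a lower quantile
  ord <- order(b$vaf)
  expect_true(all(diff(b$quantile[ord]) >= 0))
  # tied VAFs share the maximum rank, hence the same bin
  ties <- b[vaf == 0.25]
  expect_equal(length(unique(ties$quantile)), 1L)
  expect_equal(length(unique(ties$bin)), 1L)
  # top bin holds the ceil(0.5%) highest-VAF mutations
  expect_equal(sum(b$bin == 200L), 2L)
  expect_equal(sort(b[bin == 200L, vaf], decreasing = TRUE),
               sort(m$vaf, decreasing = TRUE)[1:2])
  # bins partition: counts sum to the tumour total
  expect_equal(sum(table(b$bin)), 400L)
})

test_that("small tumours are skipped with a warning", {
  m <- data.table::data.table(
    tumour_id = c(rep("big", 250), rep("small", 10)),
    chrom = "chr1", pos = seq_len(260) * 7L, ref = "T", alt = "C",
    kind = "sub", vaf = runif(260))
  expect_warning(b <- vaf_quantile_bins(m, data.table::data.table(
    chrom = "chr1", start = 0L, end = 10L)), "small")
  expect_false("small" %in% b$tumour_id)
})

test_that("bin enrichment odds ratios follow the cross-product formula", {
  # constructed 2x2: (10, 90) focal vs (5, 195) background
  b <- data.table::data.table(
    tumour_id = rep(c("f", "b"), c(100, 200)),
    chrom = "chr1", pos = 1:300, vaf = 0.5, quantile = 1,
    bin = 200L, in_s6 = c(rep(TRUE, 10), rep(FALSE, 90),
                          rep(TRUE, 5), rep(FALSE, 195)))
  res <- bin_enrichment_test(b, focal_ids = "f")
  top <- res[bin == 200L]
  expect_equal(top$or, (10 * 195) / (90 * 5), tolerance = 1e-12)
  expect_equal(top$or, 4.3333, tolerance = 1e-4)
  expect_false(top$corrected)
  # zero cell triggers the Haldane-Anscombe correction and a flag
  b2 <- data.table::copy(b)[tumour_id == "f" & in_s6 == TRUE, in_s6 := FALSE]
  res2 <- bin_enrichment_test(b2, focal_ids = "f")
  expect_true(res2[bin == 200L, corrected])
  expect_equal(res2[bin == 200L, or], (0.5 * 195.5) / (100.5 * 5.5))
})

test_that("identical focal and background composition gives OR near 1", {
  set.seed(33)
  b <- data.table::data.table(
    tumour_id = rep(c("f", "b1", "b2"), each = 1000),
    chrom = "chr1", pos = 1:3000, vaf = 0.5,
    quantile = runif(3000), in_s6 = runif(3000) < 0.3)
  b[, bin := pmin(as.integer(ceiling(quantile / 0.005)), 200L)]
  res <- top_bin_enrichment(b, focal_ids = "f", n_boot = 50L)
  expect_gte(res$ci[2], 1)
  expect_lte(res$ci[1], 1)
})

test_that("symmetric tumours with TRIM show top-bin enrichment in expressed genes", {
  co <- trim_cohort()
  ph <- trim_phased()
  genes <- dedupe_overlapping_genes(co$annotation$genes)
  genes[, stratum := assign_strata_by_tpm(genes$nascent_tpm)]
  s6 <- genes[stratum == 6L, .(chrom, start, end)]
  bins <- vaf_quantile_bins(ph$mutations, s6)
  sym_ids <- ph$tumours[symmetric == TRUE, tumour_id]
  asym_ids <- ph$tumours[symmetric == FALSE, tumour_id]
  expect_gte(length(sym_ids), 2L)
  res <- top_bin_enrichment(bins, focal_ids = sym_ids,
                            background_ids = asym_ids)
  expect_gt(res$or, 1)
  expect_lt(res$p, 0.05)
  # shared (TRIM) mutations in symmetric tumours have roughly doubled VAF
  tr <- merge(ph$mutations, co$truth, by = c("tumour_id", "chrom", "pos"))
  sym_m <- tr[tumour_id %in% sym_ids & kind == "sub" & generation == 1L]
  expect_gt(sym_m[shared == TRUE, mean(vaf)] /
              sym_m[shared == FALSE, mean(vaf)], 1.6)
  # asymmetric tumours show no comparable top-bin enrichment
  res_null <- top_bin_enrichment(bins, focal_ids = asym_ids[1:3],
                                 background_ids = asym_ids[-(1:3)])
  expect_lt(res_null$or, res$or)
  expect_gt(res_null$p, 0.05)
})

test_that("template-strand A>N rate rises with expression, mirroring the T>N fall", {
  co <- trim_cohort()
  ph <- trim_phased()
  genes <- dedupe_overlapping_genes(co$annotation$genes)
  genes[, stratum := assign_strata_by_tpm(genes$nascent_tpm)]
  pb <- per_base_relative_difference(ph, genes, co$annotation$genome,
                                     n_boot = 60L, seed = 2L)
  a6 <- pb[stratum == 6L & base == "A"]
  t6 <- pb[stratum == 6L & base == "T"]
  expect_gt(a6$rel_diff, 0)
  expect_gt(a6$lo, 0)
  expect_lt(t6$rel_diff, 0)
  expect_lt(t6$hi, 0)
  # monotone direction across strata for both curves
  a_curve <- pb[base == "A"][order(stratum), rel_diff]
  t_curve <- pb[base == "T"][order(stratum), rel_diff]
  expect_gt(stats::cor(seq_along(a_curve), a_curve, method = "spearman"), 0)
  expect_lt(stats::cor(seq_along(t_curve), t_curve, method = "spearman"), 0)
})

test_that("TRIM ablation flattens the A>N curve", {
  cfg <- sim_config(seed = 37, n_chrom = 2L, chrom_length = 4e6,
                    include_x = FALSE, n_tumours = 6L, n_genes = 150L,
                    trim_rate = 0)
  co <- simulate_cohort(cfg)
  ph <- phase_cohort(co$mutations, co$annotation$genome)
  genes <- dedupe_overlapping_genes(co$annotation$genes)
  genes[, stratum := assign_strata_by_tpm(genes$nascent_tpm)]
  pb <- per_base_relative_difference(ph, genes, co$annotation$genome,
                                     n_boot = 60L, seed = 3L)
  a6 <- pb[stratum == 6L & base == "A"]
  # no rise without TRIM (the residual direct A-origin mutations still
  # fall under TCR, so the ablation check is one-sided)
  expect_lte(a6$lo, 0)
})

test_that("labelled VAF bias test is Bonferroni-corrected and null-calibrated", {
  set.seed(35)
  b <- data.table::data.table(quantile = runif(600))
  groups <- rep(c("g1", "g2"), each = 300)
  labels <- runif(600) < 0.1
  res <- labelled_vaf_bias_test(b, labels, groups)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 2))
  # shifted labels are detected
  b2 <- data.table::copy(b)
  lab2 <- logical(600)
  hi <- order(-b2$quantile)[1:30]
  lab2[hi[hi <= 300]] <- TRUE
  res2 <- labelled_vaf_bias_test(b2, lab2, groups)
  expect_lt(res2[group == "g1", p_bonferroni], 0.05)
  # too few labelled mutations: group skipped
  lab3 <- c(TRUE, rep(FALSE, 599))
  res3 <- labelled_vaf_bias_test(b, lab3, groups)
  expect_true(is.na(res3[group == "g1", p_raw]))
})
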