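test_that("nascent TPM normalisation conserves 1e6 per library", {
  # one gene per library takes all of it
  expect_equal(nascent_tpm(matrix(10, 1, 1), 1000), 1e6)
  # two genes with equal rpk split evenly
  expect_equal(nascent_tpm(matrix(c(10, 20), 2, 1), c(1000, 2000)),
               c(5e5, 5e5))
  # random counts: per-library sums are 1e6 before the cross-library mean
  set.seed(10)
  counts <- matrix(rpois(60, 50), 20, 3)
  ib <- sample(500:5000, 20)
  rpk <- counts / (ib / 1e3)
  tpm <- sweep(rpk, 2, colSums(rpk), "/") * 1e6
  expect_equal(colSums(tpm), rep(1e6, 3))
  expect_equal(nascent_tpm(counts, ib), rowMeans(tpm))
  # intron-less genes are excluded as missing
  expect_true(is.na(nascent_tpm(matrix(c(5, 5), 2, 1), c(1000, 0))[2]))
})

test_that("overlap exclusion is greedy from the most expressed gene", {
  g <- data.table::data.table(
    gene_id = c("outer", "inner", "far"),
    chrom = "c1", start = c(100L, 200L, 5000L), end = c(1000L, 300L, 6000L),
    nascent_tpm = c(50, 10, 1))
  kept <- dedupe_overlapping_genes(g)
  expect_equal(sort(kept$gene_id), c("far", "outer"))
  # disjoint genes are all retained
  g2 <- data.table::data.table(gene_id = letters[1:3], chrom = "c1",
                               start = c(0L, 100L, 200L),
                               end = c(50L, 150L, 250L),
                               nascent_tpm = c(1, 2, 3))
  expect_equal(nrow(dedupe_overlapping_genes(g2)), 3L)
  # random overlap graphs match a brute-force greedy oracle
  set.seed(12)
  for (r in 1:20) {
    n <- 15L
    st <- sample.int(500, n)
    gg <- data.table::data.table(gene_id = paste0("g", 1:n), chrom = "c1",
                                 start = st,
                                 end = st + sample.int(80, n, TRUE),
                                 nascent_tpm = runif(n))
    ord <- order(-gg$nascent_tpm, gg$chrom, gg$start)
    sel <- integer(0)
    for (i in ord) {
      if (!any(gg$start[i] < gg$end[sel] & gg$end[i] > gg$start[sel]))
        sel <- c(sel, i)
    }
    expect_equal(sort(dedupe_overlapping_genes(gg)$gene_id),
                 sort(gg$gene_id[sel]))
  }
})

test_that("strata breakpoints are recovered from a flat-sloped-flat profile", {
  set.seed(14)
  n <- 600
  tpm <- rlnorm(n, 0, 2)
  b1 <- 0.3; b2 <- 4
  mu <- ifelse(tpm < b1, 10,
               ifelse(tpm > b2, 4,
                      10 - 6 * (log10(tpm) - log10(b1)) /
                        (log10(b2) - log10(b1))))
  rate <- mu + rnorm(n, 0, 0.3)
  g <- data.table::data.table(nascent_tpm = tpm)
  st <- strata_assign(g, rate)
  expect_lt(abs(st$breakpoints[["low"]] - b1), 0.25 * b1 + 0.15)
  expect_lt(abs(st$breakpoints[["high"]] - b2), 0.25 * b2)
  # strata 2-5 partition the mid range near-evenly
  mid <- table(st$stratum[st$stratum %in% 2:5])
  expect_lte(diff(range(mid)), 1)
  # stratum rule applied on raw TPM
  expect_true(all(st$stratum[tpm < st$breakpoints[["low"]]] == 1L))
  expect_true(all(st$stratum[tpm > st$breakpoints[["high"]]] == 6L))
})

test_that("degenerate expression collapses to a single stratum with a warning", {
  g <- data.table::data.table(nascent_tpm = rep(0, 10))
  expect_warning(st <- strata_assign(g, runif(10)), "degenerate")
  expect_true(all(st$stratum == 1L))
})

test_that("the template/non-template orientation table is exact", {
  expect_equal(tcr_orientation("+", "R"), "template")
  expect_equal(tcr_orientation("-", "F"), "template")
  expect_equal(tcr_orientation("+", "F"), "nontemplate")
  expect_equal(tcr_orientation("-", "R"), "nontemplate")
})

test_that("TCR produces falling template rates over strata with co-falling multiallelism", {
  co <- trim_cohort()
  ph <- trim_phased()
  ann <- co$annotation
  genes <- dedupe_overlapping_genes(ann$genes)
  genes[, stratum := assign_strata_by_tpm(genes$nascent_tpm)]
  tr <- tcr_rates(ph, genes, ann$genome)
  tem <- tr[orientation == "template"][order(stratum)]
  expect_equal(tem$stratum, 1:6)
  expect_true(all(diff(tem$rate) < 0))
  # plateau: the last step is a small share of the total drop
  drop_total <- tem$rate[1] - tem$rate[6]
  expect_lt((tem$rate[5] - tem$rate[6]) / drop_total, 0.35)
  # multiallelic rate co-decreases (Spearman rho < 0)
  expect_lt(stats::cor(tem$stratum, tem$multiallelic, method = "spearman"), 0)
  # repair efficiency near 100% at stratum 1, well below at stratum 6
  expect_equal(tr[stratum == 1, mean(repair_efficiency)], 100,
               tolerance = 0.1)
  expect_lt(tem[stratum == 6, repair_efficiency], 70)
})

test_that("without TCR template and non-template rates agree", {
  cfg <- sim_config(seed = 23, n_chrom = 2L, chrom_length = 4e6,
                    include_x = FALSE, n_tumours = 4L, n_genes = 150L,
                    tcr_strength = 0, trim_rate = 0)
  co <- simulate_cohort(cfg)
  ph <- phase_cohort(co$mutations, co$annotation$genome)
  genes <- dedupe_overlapping_genes(co$annotation$genes)
  genes[, stratum := assign_strata_by_tpm(genes$nascent_tpm)]
  tr <- tcr_rates(ph, genes, co$annotation$genome)
  wide <- data.table::dcast(tr, stratum ~ orientation, value.var = "rate")
  expect_equal(wide$template, wide$nontemplate, tolerance = 0.12)
  expect_equal(tr[stratum == 6, mean(repair_efficiency)], 100,
               tolerance = 12)
})
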