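mk_subs <- function(pos, tumour = "t", chrom = "c1") {
  data.table::data.table(tumour_id = tumour, chrom = chrom, pos = pos,
                         kind = "sub")
}

brute_clusters <- function(pos, x_nt) {
  # O(n^2): a mutation is clustered if chained to any other via gaps < x_nt
  pos <- sort(pos)
  n <- length(pos)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    linked[i, j] <- i != j & abs(pos[i] - pos[j]) < x_nt
  # transitive closure along the line = chain components
  grp <- cumsum(c(TRUE, diff(pos) >= x_nt))
  split(pos, grp)[table(grp) >= 2]
}

test_that("cluster chaining follows the strict spacing rule", {
  cl <- find_clusters(mk_subs(c(100L, 105L, 300L)), x_nt = 11L)
  expect_equal(sort(cl$pos), c(100L, 105L))
  expect_equal(length(unique(cl$cluster_id)), 1L)
  # chain rule: clusters can span more than x_nt
  cl2 <- find_clusters(mk_subs(c(0L, 100L, 200L)), x_nt = 101L)
  expect_equal(nrow(cl2), 3L)
  expect_equal(length(unique(cl2$cluster_id)), 1L)
  # exact threshold does not chain (strictly less than)
  cl3 <- find_clusters(mk_subs(c(0L, 101L)), x_nt = 101L)
  expect_equal(nrow(cl3), 0L)
})

test_that("find_clusters matches the pairwise-scan oracle on random instances", {
  set.seed(15)
  for (r in 1:60) {
    pos <- sort(sample.int(2000, 60))
    x <- sample(c(5L, 11L, 31L, 101L), 1)
    got <- find_clusters(mk_subs(pos), x_nt = x)
    want <- brute_clusters(pos, x)
    expect_equal(sort(got$pos), sort(unlist(want)), ignore_attr = TRUE)
    expect_equal(length(unique(got$cluster_id)), length(want))
  }
})

test_that("between-tumour permutation preserves per-tumour counts", {
  co <- default_cohort()
  m <- co$mutations[kind == "sub", .(tumour_id, chrom, pos, kind)]
  perms <- permute_between_tumours(m, n_perm = 2L, seed = 3L)
  for (p in perms) {
    expect_equal(p[, .N, by = tumour_id][order(tumour_id)],
                 m[, .N, by = tumour_id][order(tumour_id)])
    # proxy positions come from other tumours' call set
    expect_true(all(paste(p$chrom, p$pos) %in% paste(m$chrom, m$pos)))
  }
  expect_error(permute_between_tumours(m[tumour_id == "T001"]), "two tumours")
})

test_that("cluster orientation puts the first-replicated site upstream", {
  mem <- data.table::data.table(pos = c(100L, 105L))
  r <- orient_cluster(mem, "R")
  expect_equal(r[pos == 100L, role], "upstream")
  expect_equal(r[pos == 105L, offset_nt], 5L)
  f <- orient_cluster(mem, "F")
  expect_equal(f[pos == 105L, role], "upstream")
  expect_equal(f[pos == 100L, offset_nt], 5L)
  u <- orient_cluster(mem, "unresolved")
  expect_true(all(is.na(u$role)))
  # mirror involution: flipping class mirrors roles across the cluster
  expect_equal(r[order(pos), role], f[order(-pos), role])
})

test_that("read phasing requires a double-mutant read within 75 nt", {
  reads <- data.table::data.table(
    tumour_id = "t", read_id = c("r1", "r1", "r2", "r3"),
    chrom = "c1", pos = c(10L, 20L, 10L, 20L),
    allele = c("T", "G", "T", "G"), qual_ok = TRUE)
  pairs <- data.table::data.table(tumour_id = "t", chrom = "c1",
                                  pos1 = 10L, alt1 = "T",
                                  pos2 = 20L, alt2 = "G")
  expect_true(phase_pairs(pairs, reads))
  # single-mutant reads only
  expect_false(phase_pairs(pairs, reads[read_id != "r1"]))
  far <- data.table::copy(pairs)[, pos2 := 200L]
  expect_true(is.na(phase_pairs(far, reads)))
})

test_that("simulated same-chromatid pairs phase at high rates", {
  co <- default_cohort()
  tr <- co$truth[!is.na(pair_id)]
  prs <- data.table::rbindlist(lapply(
    split(seq_len(nrow(tr)), paste(tr$tumour_id, tr$pair_id)),
    function(i) {
      if (length(i) != 2L) return(NULL)
      a <- tr[i[1]]; b <- tr[i[2]]
      ma <- co$mutations[tumour_id == a$tumour_id & chrom == a$chrom & pos == a$pos]
      mb <- co$mutations[tumour_id == b$tumour_id & chrom == b$chrom & pos == b$pos]
      if (!nrow(ma) || !nrow(mb)) return(NULL)
      data.table::data.table(tumour_id = a$tumour_id, chrom = a$chrom,
                             pos1 = ma$pos, alt1 = ma$alt,
                             pos2 = mb$pos, alt2 = mb$alt)
    }))
  ph <- phase_pairs(prs, co$reads)
  expect_gte(mean(ph, na.rm = TRUE), 0.9)
})

test_that("lead/lag cluster comparison calibrates and power rises with distortion", {
  set.seed(20)
  lead <- sample(c(rep(2:10, 30), rep(15:40, 5)))
  lag <- sample(c(rep(2:10, 32), rep(15:40, 5)))
  res <- compare_lead_lag_clusters(lead, lag, d_grid = c(0, 0.05, 0.1),
                                   n_boot = 60L, seed = 4L)
  expect_s3_class(res$ks, "htest")
  # d = 0 rejects at roughly the nominal rate
  expect_lt(res$power[d == 0, power], 0.15)
  # monotone power (allowing small resampling wiggle)
  expect_gte(res$power[d == 0.1, power] + 0.05, res$power[d == 0.05, power])
  expect_gt(res$power[d == 0.1, power], res$power[d == 0, power])
  expect_warning(compare_lead_lag_clusters(lead[1:5], lag, d_grid = 0,
                                           n_boot = 2L), "KS skipped")
})

test_that("indel-substitution clustering recovers injected skip-deletion structure", {
  co <- default_cohort()
  ph <- default_phased()
  res <- indel_sub_clusters(ph$mutations, n_perm = 20L, seed = 2L)
  expect_gt(res$or_cluster, 1)
  expect_lt(res$p_cluster, 0.01)
  expect_gt(res$or_tdel, 1)
  # strict window: a substitution just beyond the window does not count
  toy <- data.table::data.table(
    tumour_id = "t", chrom = "c1", pos = c(1000L, 1101L),
    ref = c("CA", "G"), alt = c("C", "T"), kind = c("del", "sub"),
    vaf = 0.5, ad_ref = 20L, ad_alt = 20L, ad_alt2 = 0L, ad_alt3 = 0L,
    context = NA_character_, lesion_strand = "F")
  d <- toy[kind == "del"]
  s <- toy[kind == "sub"]
  expect_equal(abs(s$pos - d$pos), 101L)
})
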