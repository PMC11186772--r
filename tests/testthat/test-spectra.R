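mk_mut <- function(ref, alt, context, lesion_strand, vaf = 0.5,
                   ad = c(20L, 20L, 0L, 0L)) {
  data.table::data.table(tumour_id = "t", chrom = "chr1",
                         pos = seq_along(ref) * 10L, ref = ref, alt = alt,
                         kind = "sub", vaf = vaf, ad_ref = ad[1],
                         ad_alt = ad[2], ad_alt2 = ad[3], ad_alt3 = ad[4],
                         context = context, lesion_strand = lesion_strand)
}

test_that("reverse-lesion mutations are reverse complemented into the spectrum", {
  # forward-strand record A->C in context TAG inside an R segment tallies
  # as T->G in context CTA
  m <- mk_mut("A", "C", "TAG", "R")
  sp <- lesion_oriented_spectrum(m)
  expect_equal(sum(sp), 1)
  expect_equal(unname(sp[["CTA>G"]]), 1)
  # strand-swapping the dataset (comp bases, revcomp context, swap label)
  m2 <- mk_mut("T", "G", "CTA", "F")
  expect_equal(lesion_oriented_spectrum(m2), sp, ignore_attr = TRUE)
  # unresolved calls are skipped and counted
  m3 <- rbind(m, mk_mut("C", "T", "ACA", "unresolved"))
  sp3 <- lesion_oriented_spectrum(m3)
  expect_equal(sum(sp3), 1)
  expect_equal(attr(sp3, "n_skipped"), 1L)
})

test_that("simulated T-only lesions concentrate spectrum mass in T>N categories", {
  cfg <- sim_config(seed = 17, n_chrom = 1L, chrom_length = 3e6,
                    include_x = FALSE, n_tumours = 2L, n_genes = 60L,
                    n_motifs = 20L, trim_rate = 0, p_cluster = 0,
                    p_skip_del = 0, background_indel_rate = 0)
  cfg$lesion_rate[c("C", "G", "A")] <- 0
  co <- simulate_cohort(cfg)
  ph <- phase_cohort(co$mutations, co$annotation$genome)
  sp <- lesion_oriented_spectrum(ph$mutations)
  from_t <- grepl("^.T.>", names(sp))
  expect_gte(sum(sp[from_t]) / sum(sp), 0.95)
})

test_that("normalised spectra sum to 100", {
  sp <- lesion_oriented_spectrum(default_phased()$mutations)
  expect_equal(sum(normalize_spectrum(sp)), 100, tolerance = 1e-9)
  z <- normalize_spectrum(rep(0, 5))
  expect_true(attr(z, "degenerate"))
})

test_that("weighted mutation rate reproduces hand-computed toy values", {
  # two contexts, counts 4/100 bp and 1/100 bp, weights 0.75/0.25
  ctx <- contexts64()
  counts <- stats::setNames(rep(0, 64), ctx)
  comp <- stats::setNames(rep(0, 64), ctx)
  counts[c("ACA", "TGT")] <- c(4, 1)
  comp[c("ACA", "TGT")] <- c(100, 100)
  w <- stats::setNames(rep(0, 64), ctx)
  w[c("ACA", "TGT")] <- c(0.75, 0.25)
  expect_equal(weighted_mutation_rate(counts, comp, w), 0.0325)
  # zero mutations -> zero rate
  expect_equal(weighted_mutation_rate(counts * 0, comp, w), 0)
  # uniform rate with matching weights returns that rate
  counts2 <- comp * 0.02
  expect_equal(weighted_mutation_rate(counts2, comp, comp / sum(comp)), 0.02)
  # inconsistent inputs are rejected
  comp0 <- comp; comp0["ACA"] <- 0
  expect_error(weighted_mutation_rate(counts, comp0, w), "zero composition")
})

test_that("mutation rate is invariant to duplicating region and mutations", {
  co <- default_cohort()
  ph <- default_phased()
  g <- co$annotation$genome
  segs <- ph$segments[tumour_id == co$tumours$tumour_id[1] &
                        lesion_class == "F"]
  mut <- ph$mutations[tumour_id == co$tumours$tumour_id[1] &
                        lesion_strand == "F" & kind == "sub"]
  comp <- trinuc_composition(g, segs[, .(chrom, start, end)])
  w <- genome_weights(g)
  sp <- lesion_oriented_spectrum(mut)
  r1 <- weighted_mutation_rate(sp, comp, w)
  r2 <- weighted_mutation_rate(sp * 2, comp * 2, w)
  expect_equal(r2, r1)
})

test_that("multiallelic rate has the right bounds and trivial values", {
  m_bi <- mk_mut(rep("C", 10), rep("T", 10), rep("ACA", 10), rep("F", 10))
  expect_equal(multiallelic_rate(m_bi), 0)
  m_tri <- data.table::copy(m_bi)[, ad_alt2 := 5L]
  expect_equal(multiallelic_rate(m_tri), 1)
  # below-support sites are excluded from the denominator
  m_half <- rbind(m_bi[1:5], m_tri[6:10])
  m_half[1:5, ad_alt := 1L]
  expect_equal(multiallelic_rate(m_half), 1)
})

test_that("higher lesion persistence increases the multiallelic rate", {
  base <- list(seed = 19, n_chrom = 1L, chrom_length = 3e6,
               include_x = FALSE, n_tumours = 2L, n_genes = 60L,
               n_motifs = 20L)
  lo <- do.call(sim_config, c(base, p_persist = 0.05))
  hi <- do.call(sim_config, c(base, p_persist = 0.5))
  rate_of <- function(cfg) {
    co <- simulate_cohort(cfg)
    multiallelic_rate(co$mutations)
  }
  expect_gt(rate_of(hi), rate_of(lo))
})

test_that("subtracted spectra rescale residuals to |area| 100", {
  expect_equal(subtracted_spectrum(c(5, 5), c(5, 5)), c(0, 0),
               ignore_attr = TRUE)
  expect_true(attr(subtracted_spectrum(c(5, 5), c(5, 5)), "degenerate"))
  expect_equal(subtracted_spectrum(c(4, 0), c(1, 1)), c(75, -25))
})

test_that("residual spectrum of collateral mutations is G>T dominated", {
  co <- default_cohort()
  ph <- default_phased()
  lab <- merge(ph$mutations[kind == "sub"], co$truth,
               by = c("tumour_id", "chrom", "pos"))
  coll <- lesion_oriented_spectrum(lab[mech == "collateral"])
  direct <- lesion_oriented_spectrum(lab[mech == "direct"])
  expected <- normalize_spectrum(direct) * sum(coll) / 100
  resid <- subtracted_spectrum(coll, expected)
  gt <- grepl("^.G.>T$", names(resid))
  # the single largest positive residual is a G>T category, and G>T as a
  # class carries more positive residual mass than any other class
  expect_equal(names(which.max(resid)), names(which.max(resid[gt])))
  cls <- sub("^.(.).>(.)$", "\\1>\\2", names(resid))
  cls_mass <- tapply(pmax(resid, 0), cls, sum)
  expect_equal(names(which.max(cls_mass)), "G>T")
})

test_that("cosine similarity matches direct evaluation", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 2)), 0)
  set.seed(8)
  a <- runif(192); b <- runif(192)
  expect_equal(cosine_similarity(a, b),
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  expect_true(is.na(cosine_similarity(rep(0, 3), c(1, 2, 3))))
})

test_that("bootstrap CI over intervals contains the point estimate", {
  co <- default_cohort()
  ph <- default_phased()
  g <- co$annotation$genome
  id <- co$tumours$tumour_id[1]
  segs <- ph$segments[tumour_id == id & lesion_class == "F"]
  mut <- ph$mutations[tumour_id == id & lesion_strand == "F" & kind == "sub"]
  w <- genome_weights(g)
  rate_for <- function(idx) {
    sp <- lesion_oriented_spectrum(
      data.table::rbindlist(lapply(idx, function(i)
        mut[chrom == segs$chrom[i] & pos >= segs$start[i] &
              pos < segs$end[i]])))
    comp <- trinuc_composition(g, segs[idx, .(chrom, start, end)])
    weighted_mutation_rate(sp, comp, w)
  }
  point <- rate_for(seq_len(nrow(segs)))
  set.seed(5)
  ci <- boot_ci(rate_for, nrow(segs), n_boot = 60L)
  expect_gte(point, ci[["lower"]])
  expect_lte(point, ci[["upper"]])
})
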