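# small cohort with a planted single-position damage hotspot in motifs,
# shared across the profile tests
hotspot_fixture <- function() {
  if (is.null(.fix$hot)) {
    cfg <- sim_config(seed = 27, n_chrom = 2L, chrom_length = 4e6,
                      include_x = FALSE, n_tumours = 6L, n_genes = 120L,
                      n_motifs = 200L, motif_hotspot_factor = 60,
                      trim_rate = 0)
    co <- simulate_cohort(cfg)
    ph <- phase_cohort(co$mutations, co$annotation$genome)
    .fix$hot <- list(cfg = cfg, co = co, ph = ph,
                     rates = class_rates(ph, co$annotation$genome))
  }
  .fix$hot
}

test_that("excess and enrichment metrics follow their definitions", {
  pp <- list(profile = data.table::data.table(
    rel_pos = 0:2, observed = c(2, 5, 0), expected = c(1, 5, 0),
    count = c(1000, 1000, 0)),
    obs_mat = matrix(0, 1, 3), exp_mat = matrix(0, 1, 3))
  class(pp) <- "positional_profile"
  m <- excess_and_enrichment(pp)
  expect_equal(m$excess_mb[1], 1000)
  expect_equal(m$enrichment[1], 1 / 3)
  expect_equal(m$enrichment[2], 0)
  expect_true(is.na(m$enrichment[3]))
  # rolling mean of a constant profile is unchanged
  expect_equal(roll_mean(rep(0.4, 21), 5L), rep(0.4, 21))
})

test_that("expected profiles are flat and calibrated without positional effects", {
  # a simulation with no planted positional structure: no motif protection
  # or hotspot, no nucleosome periodicity
  cfg <- sim_config(seed = 28, n_chrom = 2L, chrom_length = 4e6,
                    include_x = FALSE, n_tumours = 6L, n_genes = 120L,
                    n_motifs = 20L, motif_protect_factor = 1,
                    nucleosome_repair_amp = 0, trim_rate = 0)
  co <- simulate_cohort(cfg)
  ph <- phase_cohort(co$mutations, co$annotation$genome)
  ann <- co$annotation
  set.seed(30)
  # random non-overlapping regions
  n <- 10000L
  slot <- sample.int(cfg$chrom_length %/% 80L - 2L, n)
  feats <- data.table::data.table(
    chrom = sample(names(ann$genome$seq), n, replace = TRUE),
    start = slot * 80L)
  feats <- unique(feats, by = c("chrom", "start"))
  feats[, `:=`(end = start + 61L, strand = "+")]
  pp <- positional_profile(ph, ann$genome, feats)
  m <- excess_and_enrichment(pp)
  # aggregate calibration: total observed within ~10% of total expected
  expect_lt(abs(sum(m$observed) / sum(m$expected) - 1), 0.1)
  expect_lt(abs(mean(m$enrichment, na.rm = TRUE)), 0.05)
  # conservation: profile totals equal mutations falling in the regions
  mut <- ph$mutations[kind == "sub" & lesion_strand %in% c("F", "R")]
  hits <- match_interval(mut$chrom, mut$pos,
                         feats[, .(chrom, start, end, id = .I)])
  expect_equal(sum(m$observed), sum(!is.na(hits)))
})

test_that("a planted motif damage hotspot shows mutation enrichment without multiallelic excess", {
  hf <- hotspot_fixture()
  ann <- hf$co$annotation
  cfg <- hf$cfg
  pp <- motif_profile(hf$ph, ann$genome, ann$motifs, flank = 20L,
                      rates = hf$rates)
  m <- excess_and_enrichment(pp, n_boot = 50L, seed = 2L)
  hot_i <- 20L + cfg$motif_hotspot_offset + 1L  # rel_pos is 0-based
  expect_gt(m$enrichment[hot_i], 0.5)
  expect_gt(m$enr_lo[hot_i], 0)
  # protected high-information core: negative enrichment away from the
  # hotspot
  ic <- attr(ann$motifs, "ic")
  core_pos <- 20L + which(ic >= 1)
  core_pos <- setdiff(core_pos, hot_i)
  expect_lt(mean(m$enrichment[core_pos], na.rm = TRUE), -0.1)
  # multiallelism per mutation shows no corresponding elevation at the
  # damage hotspot
  ppm <- motif_profile(hf$ph, ann$genome, ann$motifs, flank = 20L,
                       rates = hf$rates, value = "multiallelic")
  mm <- excess_and_enrichment(ppm, n_boot = 50L, seed = 3L)
  expect_true(is.na(mm$enrichment[hot_i]) || mm$enr_lo[hot_i] <= 0)
})

test_that("damage/repair classification recovers planted hotspot and protection", {
  hf <- hotspot_fixture()
  ann <- hf$co$annotation
  cfg <- hf$cfg
  pp <- motif_profile(hf$ph, ann$genome, ann$motifs, flank = 20L,
                      rates = hf$rates)
  m <- excess_and_enrichment(pp, n_boot = 50L, seed = 2L)
  ppm <- motif_profile(hf$ph, ann$genome, ann$motifs, flank = 20L,
                       rates = hf$rates, value = "multiallelic")
  mm <- excess_and_enrichment(ppm, n_boot = 50L, seed = 3L)
  cls <- classify_damage_vs_repair(m, mm)
  hot_i <- 20L + cfg$motif_hotspot_offset + 1L
  expect_equal(cls[hot_i], "excess_damage")
  # rule table on constructed inputs
  mk <- function(lo, hi) data.table::data.table(enr_lo = lo, enr_hi = hi)
  expect_equal(classify_damage_vs_repair(mk(0.1, 0.5), mk(0.1, 0.5)),
               "slow_repair")
  expect_equal(classify_damage_vs_repair(mk(0.1, 0.5), mk(-0.1, 0.1)),
               "excess_damage")
  expect_equal(classify_damage_vs_repair(mk(-0.5, -0.1), mk(-0.1, 0.1)),
               "protected")
  expect_equal(classify_damage_vs_repair(mk(-0.5, -0.1), mk(-0.5, -0.1)),
               "neutral")
  expect_equal(classify_damage_vs_repair(mk(NA_real_, NA_real_), mk(0.1, 0.5)),
               "neutral")
})

test_that("major groove annotation is periodic and symmetric about the dyad", {
  expect_equal(major_groove_annotation(0), "inward")
  expect_equal(major_groove_annotation(10), "inward")
  expect_equal(major_groove_annotation(-10), "inward")
  expect_equal(major_groove_annotation(5), "outward")
  offs <- -73:73
  lab <- major_groove_annotation(offs)
  expect_equal(lab, rev(lab))
})

test_that("nucleosome repair periodicity appears in the mutation profile", {
  hf <- hotspot_fixture()
  ann <- hf$co$annotation
  dy <- ann$dyads[pos > 100 & pos < ann$cfg$chrom_length - 100]
  set.seed(31)
  dy <- dy[sample.int(nrow(dy), 8000L)]
  feats <- data.table::data.table(chrom = dy$chrom, start = dy$pos - 73L,
                                  end = dy$pos + 74L, strand = "+")
  pp <- positional_profile(hf$ph, ann$genome, feats, rates = hf$rates)
  m <- excess_and_enrichment(pp)
  # Fourier component at the helical period dominates neighbouring periods
  x <- m$enrichment - mean(m$enrichment, na.rm = TRUE)
  x[is.na(x)] <- 0
  pow <- function(period) {
    t <- seq_along(x)
    Mod(sum(x * exp(-2i * pi * t / period)))
  }
  p_heli <- pow(10.3)
  expect_gt(p_heli, pow(6))
  expect_gt(p_heli, pow(20))
})
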