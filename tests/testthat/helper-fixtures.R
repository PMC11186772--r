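# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

# a small deterministic genome for unit tests
toy_genome <- function() {
  if (is.null(.fix$toy_genome)) {
    set.seed(11)
    mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    .fix$toy_genome <- genome_ref(c(chr1 = mk(5000), chr2 = mk(5000),
                                    chrX = mk(3000)))
  }
  .fix$toy_genome
}

# default-conditions cohort (used for recovery and conservation checks)
default_cohort <- function() {
  if (is.null(.fix$cohort)) {
    cfg <- sim_config(seed = 42, n_tumours = 8)
    .fix$cohort <- simulate_cohort(cfg)
  }
  .fix$cohort
}

default_phased <- function() {
  if (is.null(.fix$phased)) {
    co <- default_cohort()
    .fix$phased <- phase_cohort(co$mutations, co$annotation$genome)
  }
  .fix$phased
}

# cohort with symmetric tumours and both TCR and TRIM active, for the
# transcription/trim recovery checks
trim_cohort <- function() {
  if (is.null(.fix$trim_cohort)) {
    cfg <- sim_config(seed = 7, n_tumours = 12, symmetric_fraction = 0.25)
    .fix$trim_cohort <- simulate_cohort(cfg)
  }
  .fix$trim_cohort
}

trim_phased <- function() {
  if (is.null(.fix$trim_phased)) {
    co <- trim_cohort()
    .fix$trim_phased <- phase_cohort(co$mutations, co$annotation$genome)
  }
  .fix$trim_phased
}

# per-base truth accuracy of a phased cohort against simulator truth
phasing_accuracy <- function(phased, truth_segments) {
  segs <- phased$segments[lesion_class %in% c("F", "R")]
  tot <- 0; ok <- 0
  for (i in seq_len(nrow(segs))) {
    s <- segs[i]
    tr <- truth_segments[tumour_id == s$tumour_id & chrom == s$chrom &
                           start < s$end & end > s$start]
    o <- pmin(tr$end, s$end) - pmax(tr$start, s$start)
    tot <- tot + sum(o)
    ok <- ok + sum(o[tr$class == s$lesion_class])
  }
  ok / tot
}
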