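## Positional expected/excess/enrichment profiles of mutation and
## multiallelic rates around genomic features, and damage-vs-repair
## classification.

#' Genome-wide per-context mutation rates per tumour and lesion class
#'
#' For each tumour and each lesion-strand class (F/R), the rate is the
#' count of substitutions in that class's phased space per occurrence of
#' the (lesion-oriented) trinucleotide context, with composition reverse
#' complemented for R segments. The multiallelic fraction of each
#' tumour-class mutation set is attached.
#'
#' @param cohort Phased cohort ([phase_cohort()]).
#' @param genome A `genome_ref`.
#' @return Nested list `rates[[tumour_id]][[class]]` = list(rate = named
#'   64-vector, ma_frac = scalar).
#' @export
class_rates <- function(cohort, genome) {
  ctx <- contexts64()
  ids <- unique(cohort$segments$tumour_id)
  out <- lapply(stats::setNames(ids, ids), function(id) {
    segs <- cohort$segments[tumour_id == id]
    mut <- cohort$mutations[tumour_id == id & kind == "sub"]
    lapply(stats::setNames(c("F", "R"), c("F", "R")), function(cl) {
      sp <- segs[lesion_class == cl, .(chrom, start, end)]
      if (!nrow(sp)) return(NULL)
      comp <- trinuc_composition(genome, sp,
                                 orient = if (cl == "R") "revcomp" else "forward")
      m <- mut[lesion_strand == cl]
      o <- orient_to_lesion(m)
      counts <- table(factor(o$ctx_l, levels = ctx))
      rate <- ifelse(comp[ctx] > 0, as.numeric(counts) / comp[ctx], 0)
      support <- cbind(m$ad_ref, m$ad_alt, m$ad_alt2, m$ad_alt3) >= 2L
      n_all <- rowSums(support)
      usable <- n_all >= 2L
      ma <- if (any(usable)) mean(n_all[usable] >= 3L) else 0
      list(rate = stats::setNames(rate, ctx), ma_frac = ma)
    })
  })
  out
}

#' Positional mutation / multiallelism profile around features
#'
#' Observed and expected mutation counts per relative position across a set
#' of equal-width (optionally strand-oriented) feature regions. The
#' expectation at a position is the sum over tumours of the genome-wide
#' per-trinucleotide rate matching that tumour's lesion-strand class at the
#' region, orientation-matched; tumours for which a region is unresolved
#' contribute nothing there. `count` is the number of regions with a non-N
#' context at the position.
#'
#' @param cohort Phased cohort.
#' @param genome A `genome_ref`.
#' @param features data.table(chrom, start, end, strand) of equal width.
#' @param rates Optional precomputed [class_rates()].
#' @param from_base Restrict to mutations from this base on the lesion
#'   strand (e.g. `"A"`), or NULL for all substitutions.
#' @param value `"mutation"` counts, or `"multiallelic"` site counts whose
#'   expectation is the observed mutation profile scaled by the overall
#'   multiallelic fraction (multiallelism per mutation), so that pure
#'   damage effects cancel and only repair-kinetic deviations remain.
#' @return List of class `positional_profile`: `profile`
#'   data.table(rel_pos, observed, expected, count), and per-region
#'   matrices `obs_mat`, `exp_mat` for bootstrapping.
#' @export
positional_profile <- function(cohort, genome, features, rates = NULL,
                               from_base = NULL,
                               value = c("mutation", "multiallelic")) {
  value <- match.arg(value)
  if (is.null(rates)) rates <- class_rates(cohort, genome)
  fe <- data.table::as.data.table(features)
  if (!"strand" %in% names(fe)) fe[, strand := "."]
  w <- unique(fe$end - fe$start)
  stopifnot(length(w) == 1L)
  n_reg <- nrow(fe)
  ctx <- contexts64()

  ## integer-coded forward contexts per region x position (0 = missing)
  ctx_mat <- matrix(0L, n_reg, w)
  for (i in seq_len(n_reg)) {
    p <- fe$start[i]:(fe$end[i] - 1L)
    cx <- trinuc_context(genome, fe$chrom[i], p)
    if (fe$strand[i] == "-") cx <- rev(cx)
    code <- match(cx, ctx)
    code[is.na(code)] <- 0L
    ctx_mat[i, ] <- code
  }
  count_i <- colSums(ctx_mat > 0L)

  ## per-tumour region class
  segs <- cohort$segments[lesion_class %in% c("F", "R"),
                          .(tumour_id, chrom, start, end, lesion_class)]
  data.table::setkey(segs, chrom, start, end)
  fq <- data.table::data.table(chrom = fe$chrom, start = fe$start,
                               end = fe$end, reg = seq_len(n_reg))
  hits <- data.table::foverlaps(fq, segs, by.x = c("chrom", "start", "end"),
                                type = "within", nomatch = NULL)
  region_ploidy <- genome$ploidy[fe$chrom]

  ## expected mutation matrix, vectorised per (tumour, class):
  ## rate[64 + 1] lookup with code 0 mapping to 0, reverse complement
  ## orientation for R-class regions, ploidy-scaled
  exp_mat <- matrix(0, n_reg, w)
  rc_code <- c(0L, match(revcomp(ctx), ctx))
  for (grp in split(seq_len(nrow(hits)),
                    paste(hits$tumour_id, hits$lesion_class))) {
    id <- hits$tumour_id[grp[1]]; cl <- hits$lesion_class[grp[1]]
    rr <- rates[[id]][[cl]]
    if (is.null(rr)) next
    regs <- hits$reg[grp]
    codes <- ctx_mat[regs, , drop = FALSE]
    if (cl == "R") codes <- matrix(rc_code[codes + 1L], nrow(codes))
    rvec <- rr$rate
    if (!is.null(from_base))
      rvec[substring(ctx, 2L, 2L) != from_base] <- 0
    lut <- c(0, unname(rvec))
    exp_mat[regs, ] <- exp_mat[regs, ] +
      matrix(lut[codes + 1L], nrow(codes)) * region_ploidy[regs]
  }

  ## observed matrices from phased mutations
  mut <- cohort$mutations[kind == "sub" & lesion_strand %in% c("F", "R")]
  if (!is.null(from_base)) {
    origin <- ifelse(mut$lesion_strand == "R", comp_base(mut$ref), mut$ref)
    mut <- mut[origin == from_base]
  }
  count_mat <- function(m) {
    om <- matrix(0, n_reg, w)
    if (!nrow(m)) return(om)
    reg_hit <- match_interval(m$chrom, m$pos, fq[, .(chrom, start, end, reg)])
    for (k in which(!is.na(reg_hit))) {
      i <- reg_hit[k]
      rel <- if (fe$strand[i] == "-") fe$end[i] - 1L - m$pos[k]
             else m$pos[k] - fe$start[i]
      om[i, rel + 1L] <- om[i, rel + 1L] + 1
    }
    om
  }
  obs_mut <- count_mat(mut)
  if (value == "multiallelic") {
    support <- cbind(mut$ad_ref, mut$ad_alt, mut$ad_alt2, mut$ad_alt3) >= 2L
    obs_ma <- count_mat(mut[rowSums(support) >= 3L])
    ma_frac <- if (sum(obs_mut) > 0) sum(obs_ma) / sum(obs_mut) else 0
    obs_mat <- obs_ma
    exp_mat <- obs_mut * ma_frac
  } else {
    obs_mat <- obs_mut
  }

  prof <- data.table::data.table(rel_pos = seq_len(w) - 1L,
                                 observed = colSums(obs_mat),
                                 expected = colSums(exp_mat),
                                 count = count_i)
  structure(list(profile = prof, obs_mat = obs_mat, exp_mat = exp_mat),
            class = "positional_profile")
}

#' Excess and enrichment metrics for a positional profile
#'
#' Excess mutations per Mb: `(obs - exp) * 1e6 / count`; enrichment:
#' `(obs - exp)/(obs + exp)`. Optionally smoothed with a centred
#' truncated rolling mean and given percentile bootstrap CIs over regions.
#'
#' @param pp A `positional_profile`.
#' @param roll_k Odd rolling-mean window (e.g. 51 nucleosome-centred, 21
#'   motif-centred); NULL for none.
#' @param n_boot Bootstrap replicates over regions (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return data.table with excess_mb, enrichment (possibly smoothed) and
#'   CI columns `enr_lo`, `enr_hi` when bootstrapped.
#' @export
excess_and_enrichment <- function(pp, roll_k = NULL, n_boot = 0L, seed = 1L) {
  prof <- data.table::copy(pp$profile)
  metric <- function(obs, expd, count) {
    list(excess = ifelse(count > 0, (obs - expd) * 1e6 / count, NA_real_),
         enr = rel_diff(obs, expd))
  }
  m <- metric(prof$observed, prof$expected, prof$count)
  prof[, excess_mb := m$excess]
  prof[, enrichment := m$enr]
  if (!is.null(roll_k)) {
    prof[, excess_mb := roll_mean(excess_mb, roll_k)]
    prof[, enrichment := roll_mean(enrichment, roll_k)]
  }
  if (n_boot > 0L) {
    set.seed(seed)
    n_reg <- nrow(pp$obs_mat)
    reps <- replicate(n_boot, {
      idx <- sample.int(n_reg, n_reg, replace = TRUE)
      e <- rel_diff(colSums(pp$obs_mat[idx, , drop = FALSE]),
                    colSums(pp$exp_mat[idx, , drop = FALSE]))
      if (!is.null(roll_k)) e <- roll_mean(e, roll_k)
      e
    })
    prof[, enr_lo := apply(reps, 1L, stats::quantile, 0.025, na.rm = TRUE)]
    prof[, enr_hi := apply(reps, 1L, stats::quantile, 0.975, na.rm = TRUE)]
  }
  prof[]
}

#' Major-groove orientation of positions around a nucleosome dyad
#'
#' The centre of the inward-facing major groove sits at the dyad and
#' repeats every 10.3 bp, each span covering 5.15 bp; the outward-facing
#' groove is offset by half a period.
#'
#' @param offsets Integer offsets from the dyad.
#' @param period Helical repeat (bp).
#' @param span Groove span (bp).
#' @return Character vector: `"inward"`, `"outward"` or `"neither"`.
#' @export
major_groove_annotation <- function(offsets, period = 10.3, span = 5.15) {
  d_in <- abs(offsets - period * round(offsets / period))
  ko <- round(offsets / period - 0.5) + 0.5
  d_out <- abs(offsets - period * ko)
  ifelse(d_in <= span / 2, "inward",
         ifelse(d_out <= span / 2, "outward", "neither"))
}

#' Profile mutations around binding motifs
#'
#' Regions are the motifs extended by `flank` on both sides and oriented to
#' the motif strand. Within the motif, only mutations whose reference base
#' matches the motif consensus are retained; in the flanks all reference
#' bases are used.
#'
#' @param cohort Phased cohort.
#' @param genome A `genome_ref`.
#' @param motifs data.table(chrom, start, end, strand, consensus).
#' @param flank Flank width (bp).
#' @param ... Passed to [positional_profile()] (`from_base`, `value`,
#'   `rates`).
#' @return A `positional_profile` over width `motif + 2 * flank`.
#' @export
motif_profile <- function(cohort, genome, motifs, flank = 20L, ...) {
  mo <- data.table::as.data.table(motifs)
  regions <- mo[, .(chrom, start = start - flank, end = end + flank, strand)]
  ok <- regions$start >= 0 &
    regions$end <= genome$lengths[regions$chrom]
  regions <- regions[ok]; mo <- mo[ok]
  ## consensus filter: drop in-motif mutations not matching the consensus
  cohort2 <- cohort
  mut <- cohort$mutations
  miv <- mo[, .(chrom, start, end, row = .I)]
  hit <- match_interval(mut$chrom, mut$pos, miv)
  inmot <- which(!is.na(hit))
  drop <- rep(FALSE, nrow(mut))
  for (k in inmot) {
    i <- hit[k]
    off <- mut$pos[k] - mo$start[i]
    cons <- substring(mo$consensus[i], off + 1L, off + 1L)
    if (nchar(cons) == 1L && cons != mut$ref[k]) drop[k] <- TRUE
  }
  cohort2$mutations <- mut[!drop]
  positional_profile(cohort2, genome, regions, ...)
}

#' Classify positions as slow repair, excess damage, protected or neutral
#'
#' Based on bootstrap CIs of mutation and multiallelic (per-mutation)
#' enrichment. Multiallelism proxies lesion persistence, so repair-driven
#' mutation changes move both metrics in the same direction: elevated
#' mutation with elevated multiallelism indicates slow repair; elevated
#' mutation without a matching multiallelism increase indicates excess
#' damage; reduced mutation without a matching multiallelism decrease
#' indicates protection from damage; anything else (or missing CIs) is
#' neutral.
#'
#' @param mut_prof,ma_prof Profiles from [excess_and_enrichment()] with CI
#'   columns.
#' @return Character vector per position.
#' @export
classify_damage_vs_repair <- function(mut_prof, ma_prof) {
  stopifnot(nrow(mut_prof) == nrow(ma_prof),
            all(c("enr_lo", "enr_hi") %in% names(mut_prof)),
            all(c("enr_lo", "enr_hi") %in% names(ma_prof)))
  state <- function(lo, hi) {
    data.table::fcase(is.na(lo) | is.na(hi), "missing",
                      lo > 0, "up", hi < 0, "down", default = "flat")
  }
  sm <- state(mut_prof$enr_lo, mut_prof$enr_hi)
  sa <- state(ma_prof$enr_lo, ma_prof$enr_hi)
  data.table::fcase(
    sm == "missing" | sa == "missing", "neutral",
    sm == "up" & sa == "up", "slow_repair",
    sm == "up" & sa != "up", "excess_damage",
    sm == "down" & sa != "down", "protected",
    default = "neutral")
}
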