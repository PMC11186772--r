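## NER-TRIM analyses: strand-discordant per-base rate curves across
## expression strata, VAF quantile binning, and the symmetric-tumour
## high-VAF enrichment test.

#' Per-origin-base relative mutation-rate differences across expression
#'
#' For template-strand-lesion genes, the per-base mutation rate (mutations
#' from each lesion-strand base divided by occurrences of that base) is
#' computed per expression stratum and compared with the non-expressed
#' (stratum 1) rate as `(obs - exp)/(obs + exp)`. TRIM manifests as a
#' rising A-origin curve mirroring the falling T-origin curve. 95% CIs come
#' from gene-level bootstraps.
#'
#' @param cohort Phased cohort.
#' @param genes Gene table with `stratum`.
#' @param genome A `genome_ref`.
#' @param n_boot Gene-level bootstrap replicates.
#' @param seed RNG seed.
#' @return data.table(stratum, base, obs_rate, rel_diff, lo, hi).
#' @export
per_base_relative_difference <- function(cohort, genes, genome,
                                         n_boot = 100L, seed = 1L) {
  g <- data.table::as.data.table(genes)
  stopifnot("stratum" %in% names(g))
  segs <- cohort$segments[lesion_class %in% c("F", "R"),
                          .(tumour_id, chrom, start, end, lesion_class)]
  data.table::setkey(segs, chrom, start, end)
  gq <- g[, .(gene_id, chrom, start, end, strand, stratum)]
  hits <- data.table::foverlaps(gq, segs, by.x = c("chrom", "start", "end"),
                                type = "within", nomatch = NULL)
  hits[, orientation := tcr_orientation(strand, lesion_class)]
  hits <- hits[orientation == "template"]
  if (!nrow(hits)) stop("no template-lesion genes in classified segments")

  ## per-gene base composition on the lesion strand: for class R the
  ## lesion-strand base counts are the complement of the forward counts
  base_counts <- function(gene_row) {
    s <- Biostrings::DNAString(seq_at(genome, gene_row$chrom,
                                      gene_row$i.start, gene_row$i.end))
    f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
    stats::setNames(as.numeric(f), c("A", "C", "G", "T"))
  }
  mut <- cohort$mutations[kind == "sub" & lesion_strand %in% c("F", "R")]
  giv <- gq[, .(chrom, start, end, gene_id)]
  mut <- data.table::copy(mut)
  mut[, gene_id := giv$gene_id[match_interval(chrom, pos, giv)]]

  bases <- c("A", "C", "G", "T")
  ## per (hit = gene x tumour): counts of mutations from each base and the
  ## base composition, both on the lesion strand
  per_hit <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i]
    bc <- base_counts(h)
    if (h$lesion_class == "R")
      bc <- stats::setNames(bc[c("T", "G", "C", "A")], bases)
    mm <- mut[tumour_id == h$tumour_id & gene_id == h$gene_id]
    origin <- if (nrow(mm))
      ifelse(mm$lesion_strand == "R", comp_base(mm$ref), mm$ref)
    else character(0)
    cnt <- table(factor(origin, levels = bases))
    list(stratum = h$stratum, counts = as.numeric(cnt), comp = bc)
  })
  strata <- vapply(per_hit, `[[`, 0L, "stratum")
  cnt_mat <- t(vapply(per_hit, `[[`, numeric(4), "counts"))
  comp_mat <- t(vapply(per_hit, `[[`, numeric(4), "comp"))

  rates_for <- function(idx) {
    st <- strata[idx]
    out <- lapply(sort(unique(st)), function(s) {
      sel <- idx[st == s]
      r <- colSums(cnt_mat[sel, , drop = FALSE]) /
        pmax(colSums(comp_mat[sel, , drop = FALSE]), 1)
      data.table::data.table(stratum = s, base = bases, obs_rate = r)
    })
    dt <- data.table::rbindlist(out)
    base1 <- dt[stratum == min(dt$stratum)]
    dt[, rel := rel_diff(obs_rate,
                         base1$obs_rate[match(base, base1$base)])]
    dt
  }
  point <- rates_for(seq_len(nrow(hits)))
  set.seed(seed)
  reps <- replicate(n_boot, {
    idx <- sample.int(nrow(hits), nrow(hits), replace = TRUE)
    r <- rates_for(idx)
    r$rel[match(paste(point$stratum, point$base),
                paste(r$stratum, r$base))]
  })
  point[, lo := apply(reps, 1L, stats::quantile, 0.025, na.rm = TRUE)]
  point[, hi := apply(reps, 1L, stats::quantile, 0.975, na.rm = TRUE)]
  data.table::setnames(point, "rel", "rel_diff")
  point[]
}

#' VAF quantile positions and 0.005-width bins per tumour
#'
#' Each autosomal point mutation's VAF quantile is its empirical CDF
#' position among the tumour's point mutations (ties share the maximum
#' rank); quantiles are grouped into 200 consecutive bins of 0.005 span,
#' bin 200 being the top 0.5% of VAFs. Each mutation is flagged for overlap
#' with the supplied top-expression (stratum 6) gene spans.
#'
#' @param mut Mutation table.
#' @param s6_spans data.table(chrom, start, end) of stratum-6 gene spans.
#' @param min_mut Minimum autosomal point mutations per tumour.
#' @return data.table(tumour_id, chrom, pos, vaf, quantile, bin, in_s6);
#'   tumours below `min_mut` are skipped with a warning.
#' @export
vaf_quantile_bins <- function(mut, s6_spans, min_mut = 200L) {
  m <- data.table::as.data.table(mut)[kind == "sub" &
                                        !chrom %in% c("X", "chrX")]
  keep_ids <- m[, .N, by = tumour_id][N >= min_mut, tumour_id]
  dropped <- setdiff(unique(m$tumour_id), keep_ids)
  if (length(dropped))
    warning("skipping tumours with fewer than ", min_mut,
            " autosomal point mutations: ", paste(dropped, collapse = ", "))
  m <- m[tumour_id %in% keep_ids]
  m[, quantile := {
    r <- rank(vaf, ties.method = "max")
    r / .N
  }, by = tumour_id]
  m[, bin := pmin(as.integer(ceiling(quantile / 0.005)), 200L)]
  s6 <- data.table::as.data.table(s6_spans)[, .(chrom, start, end)]
  if (nrow(s6)) {
    m[, in_s6 := !is.na(match_interval(chrom, pos, s6))]
  } else m[, in_s6 := FALSE]
  m[, .(tumour_id, chrom, pos, vaf, quantile, bin, in_s6)]
}

#' Per-bin enrichment of top-expression overlap: focal vs background
#'
#' For each VAF quantile bin, a 2x2 table of (in stratum-6 span vs not) x
#' (focal vs background tumours) gives an odds ratio (Haldane-Anscombe
#' corrected when a cell is zero, flagged) and a two-tailed Fisher P.
#'
#' @param bins Output of [vaf_quantile_bins()] for all tumours.
#' @param focal_ids Focal tumour ids (e.g. the symmetric tumours).
#' @param background_ids Background ids; defaults to all others.
#' @return data.table(bin, or, p, corrected, a, b, c, d).
#' @export
bin_enrichment_test <- function(bins, focal_ids, background_ids = NULL) {
  b <- data.table::as.data.table(bins)
  if (is.null(background_ids))
    background_ids <- setdiff(unique(b$tumour_id), focal_ids)
  fo <- b[tumour_id %in% focal_ids]
  bg <- b[tumour_id %in% background_ids]
  data.table::rbindlist(lapply(1:200, function(bi) {
    a <- fo[bin == bi & in_s6 == TRUE, .N]
    bb <- fo[bin == bi & in_s6 == FALSE, .N]
    cc <- bg[bin == bi & in_s6 == TRUE, .N]
    dd <- bg[bin == bi & in_s6 == FALSE, .N]
    or <- odds_ratio(a, bb, cc, dd)
    p <- if ((a + bb) > 0 && (cc + dd) > 0)
      stats::fisher.test(matrix(c(a, bb, cc, dd), 2L))$p.value
    else NA_real_
    data.table::data.table(bin = bi, or = as.numeric(or), p = p,
                           corrected = attr(or, "corrected"),
                           a = a, b = bb, c = cc, d = dd)
  }))
}

#' Aggregate top-bin enrichment with a bootstrap CI
#'
#' Convenience wrapper reporting the odds ratio, Fisher P and a
#' tumour-level bootstrap CI for one bin (default the top 0.5% VAF bin).
#'
#' @param bins Output of [vaf_quantile_bins()].
#' @param focal_ids,background_ids Tumour id sets.
#' @param bin_i Bin to test (default 200).
#' @param n_boot Bootstrap replicates over focal tumours.
#' @param seed RNG seed.
#' @return List: `or`, `p`, `ci`.
#' @export
top_bin_enrichment <- function(bins, focal_ids, background_ids = NULL,
                               bin_i = 200L, n_boot = 100L, seed = 1L) {
  b <- data.table::as.data.table(bins)
  if (is.null(background_ids))
    background_ids <- setdiff(unique(b$tumour_id), focal_ids)
  bg <- b[tumour_id %in% background_ids & bin == bin_i]
  cc <- sum(bg$in_s6); dd <- sum(!bg$in_s6)
  cell <- function(ids) {
    fo <- b[tumour_id %in% ids & bin == bin_i]
    c(sum(fo$in_s6), sum(!fo$in_s6))
  }
  ab <- cell(focal_ids)
  or <- odds_ratio(ab[1], ab[2], cc, dd)
  p <- stats::fisher.test(matrix(c(ab[1], ab[2], cc, dd), 2L))$p.value
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    ids <- sample(focal_ids, length(focal_ids), replace = TRUE)
    ab2 <- Reduce(`+`, lapply(ids, cell))
    as.numeric(odds_ratio(ab2[1], ab2[2], cc, dd))
  }, 0)
  list(or = as.numeric(or), p = p,
       ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE))
}

#' Rank-sum test of labelled-mutation VAF quantile bias
#'
#' Two-tailed Wilcoxon rank-sum test of labelled vs unlabelled VAF
#' quantiles per tumour group, Bonferroni corrected over groups; groups
#' with fewer than `min_labelled` labelled mutations are skipped.
#'
#' @param bins Output of [vaf_quantile_bins()].
#' @param labels Logical vector parallel to `bins` rows (e.g. driver-like
#'   flags).
#' @param groups Group label per row (e.g. symmetric vs asymmetric).
#' @param min_labelled Minimum labelled mutations per group.
#' @return data.table(group, n_labelled, p_raw, p_bonferroni, shift).
#' @export
labelled_vaf_bias_test <- function(bins, labels, groups,
                                   min_labelled = 3L) {
  b <- data.table::as.data.table(bins)
  stopifnot(nrow(b) == length(labels), nrow(b) == length(groups))
  gs <- unique(groups)
  out <- data.table::rbindlist(lapply(gs, function(g) {
    sel <- groups == g
    q <- b$quantile[sel]; l <- labels[sel]
    if (sum(l) < min_labelled)
      return(data.table::data.table(group = g, n_labelled = sum(l),
                                    p_raw = NA_real_, shift = NA_real_))
    wt <- suppressWarnings(stats::wilcox.test(q[l], q[!l]))
    data.table::data.table(group = g, n_labelled = sum(l),
                           p_raw = wt$p.value,
                           shift = stats::median(q[l]) - stats::median(q[!l]))
  }))
  n_tested <- sum(!is.na(out$p_raw))
  out[, p_bonferroni := pmin(1, p_raw * n_tested)]
  out[]
}
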