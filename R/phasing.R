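#' Mutational asymmetry score
#'
#' Relative difference `S = (F - R)/(F + R)` between the rate (or count) of
#' mutations from T on the forward strand and from T on the reverse strand
#' (mutations from A on the forward strand). Antisymmetric under swapping
#' its arguments; `NA` when both are zero.
#'
#' @param f,r Non-negative rates or counts.
#' @return S in `[-1, 1]`.
#' @export
asymmetry_score <- function(f, r) {
  stopifnot(all(f >= 0, na.rm = TRUE), all(r >= 0, na.rm = TRUE))
  rel_diff(f, r)
}

## Bernoulli binary segmentation: recursively split a 0/1 sequence where the
## log-likelihood gain of a split exceeds `penalty`, respecting a minimum
## segment size. Returns sorted cut indices (cut after position k).
.bern_ll <- function(n1, n) {
  n0 <- n - n1
  p <- n1 / n
  out <- numeric(length(n))
  pos1 <- n1 > 0
  pos0 <- n0 > 0
  out[pos1] <- n1[pos1] * log(p[pos1])
  out[pos0] <- out[pos0] + n0[pos0] * log(1 - p[pos0])
  out
}

.binseg <- function(x, min_seg, penalty) {
  n <- length(x)
  if (n < 2L * min_seg) return(integer(0))
  cs <- cumsum(x)
  ks <- seq.int(min_seg, n - min_seg)
  ll_all <- .bern_ll(cs[n], n)
  gain <- .bern_ll(cs[ks], ks) + .bern_ll(cs[n] - cs[ks], n - ks) - ll_all
  k <- ks[which.max(gain)]
  if (max(gain) <= penalty) return(integer(0))
  c(.binseg(x[seq_len(k)], min_seg, penalty), k,
    k + .binseg(x[(k + 1L):n], min_seg, penalty))
}

.count_ta <- function(genome, chrom, start, end) {
  s <- Biostrings::DNAString(seq_at(genome, chrom, start, end))
  f <- Biostrings::letterFrequency(s, c("T", "A"))
  c(t = unname(f[["T"]]), a = unname(f[["A"]]))
}

#' Segment a tumour's genome by mutational asymmetry and classify the
#' lesion-containing strand
#'
#' Only substitutions from T (on either strand: reference T or A) with VAF
#' above `vaf_min` inform the segmentation, a binary change-point search on
#' the Bernoulli sequence of strand-of-origin labels with a BIC-style
#' penalty. Per segment, S is computed from composition-normalised rates and
#' the segment classified F (`S > s_threshold`), R (`S < -s_threshold`) or
#' unresolved; ties at the threshold are unresolved. Chromosomes with fewer
#' informative mutations than `min_informative` are left unresolved whole.
#' All mutations (including indels) are labelled by their containing
#' segment; segments tile each chromosome exactly.
#'
#' @param mutations Mutation table of a single tumour.
#' @param genome A `genome_ref`.
#' @param min_informative Minimum informative mutations per segment.
#' @param vaf_min VAF threshold for counting strand-specific mutations.
#' @param s_threshold Classification threshold on |S|.
#' @return List of class `phased_tumour`: `segments`
#'   (chrom/start/end/n_T_forward/n_T_reverse/S/lesion_class), `mutations`
#'   (input plus `lesion_strand`, `segment_id`), and `symmetric` (see
#'   [detect_symmetric()]).
#' @export
segment_and_classify <- function(mutations, genome, min_informative = 50L,
                                 vaf_min = 0.1, s_threshold = 0.33) {
  mut <- data.table::as.data.table(mutations)
  stopifnot(length(unique(mut$tumour_id)) <= 1L)
  segs <- data.table::rbindlist(lapply(names(genome$seq), function(ch) {
    len <- genome$lengths[[ch]]
    m <- mut[chrom == ch & kind == "sub" & ref %in% c("T", "A") & vaf > vaf_min]
    data.table::setorder(m, pos)
    x <- as.integer(m$ref == "T")
    if (length(x) < min_informative) {
      return(data.table::data.table(chrom = ch, start = 0L, end = len,
                                    n_T_forward = sum(x),
                                    n_T_reverse = sum(1L - x),
                                    S = NA_real_,
                                    lesion_class = "unresolved"))
    }
    cuts <- .binseg(x, min_seg = min_informative,
                    penalty = 2 * log(length(x)))
    bounds <- c(0L, as.integer((m$pos[cuts] + m$pos[cuts + 1L]) %/% 2), len)
    data.table::rbindlist(lapply(seq_len(length(bounds) - 1L), function(i) {
      s0 <- bounds[i]; e0 <- bounds[i + 1L]
      in_seg <- m$pos >= s0 & m$pos < e0
      nf <- sum(x[in_seg]); nr <- sum(in_seg) - nf
      ta <- .count_ta(genome, ch, s0, e0)
      S <- if (ta[["t"]] > 0 && ta[["a"]] > 0)
        asymmetry_score(nf / ta[["t"]], nr / ta[["a"]]) else NA_real_
      cls <- if (is.na(S)) "unresolved"
             else if (S > s_threshold) "F"
             else if (S < -s_threshold) "R" else "unresolved"
      data.table::data.table(chrom = ch, start = s0, end = e0,
                             n_T_forward = nf, n_T_reverse = nr, S = S,
                             lesion_class = cls)
    }))
  }))
  segs[, segment_id := .I]
  data.table::setkey(segs, chrom, start, end)
  mut[, segment_id := match_interval(chrom, pos, segs)]
  mut[, lesion_strand := segs$lesion_class[segment_id]]
  out <- list(segments = segs[], mutations = mut[], tumour_id = mut$tumour_id[1])
  out$symmetric <- detect_symmetric(out)
  class(out) <- "phased_tumour"
  out
}

#' Flag mutationally symmetric tumours
#'
#' A tumour is symmetric when more than 99% of its autosomal mutations lie
#' in segments with `|S| < 0.2`.
#'
#' @param phased A `phased_tumour` (or list with `segments` and `mutations`).
#' @param s_sym Symmetry threshold on |S|.
#' @param frac Required fraction of autosomal mutations.
#' @return Logical flag (`NA` when there are no autosomal mutations).
#' @export
detect_symmetric <- function(phased, s_sym = 0.2, frac = 0.99) {
  mut <- phased$mutations[!chrom %in% c("X", "chrX") & !is.na(segment_id)]
  if (nrow(mut) == 0L) return(NA)
  seg_s <- phased$segments$S[mut$segment_id]
  in_sym <- !is.na(seg_s) & abs(seg_s) < s_sym
  mean(in_sym) > frac
}

#' Phase every tumour of a cohort
#'
#' @param mutations Mutation table with a `tumour_id` column.
#' @param genome A `genome_ref`.
#' @param ... Passed to [segment_and_classify()].
#' @return List: `mutations` (labelled, all tumours), `segments` (with
#'   `tumour_id`), `tumours` (id, symmetric flag), `phased` (per-tumour
#'   `phased_tumour` objects, named).
#' @export
phase_cohort <- function(mutations, genome, ...) {
  mut <- data.table::as.data.table(mutations)
  ids <- unique(mut$tumour_id)
  phased <- lapply(stats::setNames(ids, ids), function(id)
    segment_and_classify(mut[tumour_id == id], genome, ...))
  list(
    mutations = data.table::rbindlist(lapply(phased, `[[`, "mutations")),
    segments = data.table::rbindlist(lapply(ids, function(id)
      data.table::data.table(tumour_id = id, phased[[id]]$segments))),
    tumours = data.table::data.table(
      tumour_id = ids,
      symmetric = vapply(phased, function(p) isTRUE(p$symmetric), TRUE)),
    phased = phased)
}
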