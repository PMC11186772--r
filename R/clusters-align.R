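## Enumeration of equally optimal alignments for sequence pairs differing by
## a single indel and a single substitution, with fractional weighting of
## the solutions, and the upstream/downstream bias permutation test.

#' Enumerate equally optimal one-gap-one-substitution alignments
#'
#' For an ancestral and a derived sequence differing by exactly one indel
#' and one substitution, every contiguous single-gap placement is tried;
#' placements implying exactly one mismatch are the equally optimal
#' solutions, each weighted `1 / n_solutions`. Sequences are expected to be
#' oriented so that the forward direction is new-strand synthesis over the
#' lesion-containing template.
#'
#' The gap sits between derived-sequence positions `gap_pos` and
#' `gap_pos + 1` (1-based); `offset` is the signed distance of the
#' substitution from the gap (+1 immediately downstream/right, -1
#' immediately upstream/left; never 0).
#'
#' @param ancestral,derived Nucleotide strings (A/C/G/T).
#' @return data.table(gap_pos, offset, anc_base, der_base, indel_seq,
#'   weight); zero rows when no placement yields exactly one mismatch
#'   (pair rejected).
#' @export
enumerate_optimal_alignments <- function(ancestral, derived) {
  stopifnot(is.character(ancestral), is.character(derived),
            length(ancestral) == 1L, length(derived) == 1L)
  n_a <- nchar(ancestral); n_d <- nchar(derived)
  if (n_a == n_d) stop("sequences must differ by an indel")
  is_del <- n_a > n_d
  long <- if (is_del) ancestral else derived
  short <- if (is_del) derived else ancestral
  L <- abs(n_a - n_d)
  nl <- nchar(long); ns <- nchar(short)
  lv <- strsplit(long, "")[[1]]
  sv <- strsplit(short, "")[[1]]
  sols <- list()
  for (g in seq_len(nl - L + 1L)) {
    ## delete block [g, g+L-1] from the long sequence
    keep <- c(seq_len(g - 1L), if (g + L <= nl) seq.int(g + L, nl))
    mism <- which(lv[keep] != sv)
    if (length(mism) != 1L) next
    mm <- mism[1L]
    ## gap lies after short-sequence position g - 1
    offset <- if (mm >= g) mm - g + 1L else mm - g
    sols[[length(sols) + 1L]] <- data.table::data.table(
      gap_pos = g - 1L, offset = offset,
      anc_base = if (is_del) lv[keep][mm] else sv[mm],
      der_base = if (is_del) sv[mm] else lv[keep][mm],
      indel_seq = paste(lv[seq.int(g, g + L - 1L)], collapse = ""))
  }
  out <- data.table::rbindlist(sols)
  if (is.null(out) || nrow(out) == 0L)
    return(data.table::data.table(gap_pos = integer(), offset = integer(),
                                  anc_base = character(),
                                  der_base = character(),
                                  indel_seq = character(),
                                  weight = numeric()))
  out[, weight := 1 / .N]
  out[]
}

#' Build oriented ancestral/derived sequences for an indel-substitution pair
#'
#' Edits the two mutations into the reference and orients the pair so that
#' the forward strand is the strand newly synthesized over the
#' lesion-containing template (reverse complemented when the lesion strand
#' is the reference forward strand).
#'
#' @param genome A `genome_ref`.
#' @param indel One-row mutation record (anchored ref/alt representation).
#' @param sub One-row substitution record in the same tumour.
#' @param lesion_strand `"F"` or `"R"`.
#' @param flank Flank length around the pair.
#' @return List with `ancestral`, `derived` strings.
#' @export
build_pair_sequences <- function(genome, indel, sub, lesion_strand,
                                 flank = 100L) {
  stopifnot(indel$chrom == sub$chrom, lesion_strand %in% c("F", "R"))
  ch <- indel$chrom
  lo <- max(0L, min(indel$pos, sub$pos) - flank)
  hi <- min(genome$lengths[[ch]],
            max(indel$pos + nchar(indel$ref), sub$pos + 1L) + flank)
  refseq <- seq_at(genome, ch, lo, hi)
  edit <- function(s, pos0, ref, alt) {
    i <- pos0 - lo + 1L
    stopifnot(substring(s, i, i + nchar(ref) - 1L) == ref)
    paste0(substring(s, 1L, i - 1L), alt,
           substring(s, i + nchar(ref), nchar(s)))
  }
  ancestral <- refseq
  ## apply the rightmost edit first so coordinates stay valid
  edits <- list(list(indel$pos, indel$ref, indel$alt),
                list(sub$pos, sub$ref, sub$alt))
  ord <- order(-c(indel$pos, sub$pos))
  derived <- refseq
  for (e in edits[ord]) derived <- edit(derived, e[[1]], e[[2]], e[[3]])
  if (lesion_strand == "F") {
    ancestral <- revcomp(ancestral)
    derived <- revcomp(derived)
  }
  list(ancestral = ancestral, derived = derived)
}

#' Upstream/downstream substitution bias with permutation P value
#'
#' For indel-substitution pairs whose equally optimal solutions all place
#' the substitution on one side of the indel (a definitive side), the bias
#' is `(down - up)/(down + up)`. The null randomly relabels the lesion
#' strand of each pair (flipping its side), and the empirical two-sided P
#' value is `(b + 1)/(n + 1)`.
#'
#' @param side Integer vector per definitive pair: +1 downstream, -1
#'   upstream.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List: `bias`, `p`, `n_pairs`, `null` (permuted biases).
#' @export
updown_bias <- function(side, n_perm = 10000L, seed = 1L) {
  side <- side[!is.na(side)]
  if (!length(side)) return(list(bias = NA_real_, p = NA_real_, n_pairs = 0L))
  stopifnot(all(side %in% c(-1L, 1L)))
  n <- length(side)
  bias <- rel_diff(sum(side == 1L), sum(side == -1L))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    s <- side * sample(c(-1L, 1L), n, replace = TRUE)
    rel_diff(sum(s == 1L), sum(s == -1L))
  }, 0)
  list(bias = bias, p = perm_pvalue(bias, null), n_pairs = n, null = null)
}

#' Definitive substitution side for a pair's alignment solutions
#' @param solutions Output of [enumerate_optimal_alignments()].
#' @return +1 (all downstream), -1 (all upstream) or NA (mixed/none).
#' @export
definitive_side <- function(solutions) {
  if (nrow(solutions) == 0L) return(NA_integer_)
  s <- unique(sign(solutions$offset))
  if (length(s) == 1L) as.integer(s) else NA_integer_
}
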