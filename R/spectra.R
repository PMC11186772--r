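## Strand-resolved mutation spectra over 192 categories (4 ref bases x 3
## alternates x 16 flanking contexts), oriented to the lesion-containing
## strand, plus composition-weighted mutation and multiallelic rates.

.BASES <- c("A", "C", "G", "T")

#' The 64 trinucleotide contexts, alphabetical
#' @return Character vector of 64 3-mers (AAA..TTT).
#' @export
contexts64 <- function() {
  g <- expand.grid(d = .BASES, m = .BASES, u = .BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$u, g$m, g$d))
}

#' The 192 substitution categories
#'
#' Ordered context-major (contexts alphabetical), with the three alternate
#' alleles sorted within each context; names look like `"ACG>T"` (context
#' ACG, middle base C mutated to T).
#' @return Character vector of 192 category names.
#' @export
spectrum_categories <- function() {
  ctx <- contexts64()
  unlist(lapply(ctx, function(cc) {
    m <- substring(cc, 2, 2)
    paste0(cc, ">", sort(setdiff(.BASES, m)))
  }))
}

#' Orient mutation calls to the lesion-containing strand
#'
#' Mutations in reverse-lesion (R) segments have ref, alt and context
#' reverse complemented so that "from X" afterwards means X on the
#' lesion-containing strand. Unresolved mutations are dropped (count kept in
#' `attr(, "n_unresolved")`).
#'
#' @param mut Mutation table with `lesion_strand` in `{"F","R"}` (others
#'   dropped).
#' @return data.table with `ref_l`, `alt_l`, `ctx_l` columns added.
#' @export
orient_to_lesion <- function(mut) {
  mut <- data.table::as.data.table(mut)
  n_un <- sum(!mut$lesion_strand %in% c("F", "R"))
  out <- mut[lesion_strand %in% c("F", "R")]
  flip <- out$lesion_strand == "R"
  out[, ref_l := ifelse(flip, comp_base(ref), ref)]
  out[, alt_l := ifelse(flip, comp_base(alt), alt)]
  ctx <- out$context
  ok <- !is.na(ctx) & flip
  ctx[ok] <- revcomp(ctx[ok])
  out[, ctx_l := ctx]
  data.table::setattr(out, "n_unresolved", n_un)
  out
}

#' Lesion-strand-oriented 192-category spectrum
#'
#' @param mut Mutation table (substitutions with `lesion_strand` labels and
#'   trinucleotide `context`).
#' @return Named numeric vector of 192 counts; `attr(, "n_skipped")` counts
#'   unresolved or context-less calls.
#' @export
lesion_oriented_spectrum <- function(mut) {
  mut <- data.table::as.data.table(mut)[kind == "sub"]
  o <- orient_to_lesion(mut)
  skipped <- attr(o, "n_unresolved") + sum(is.na(o$context))
  o <- o[!is.na(ctx_l)]
  cats <- spectrum_categories()
  key <- paste0(o$ctx_l, ">", o$alt_l)
  counts <- table(factor(key, levels = cats))
  out <- stats::setNames(as.numeric(counts), cats)
  attr(out, "n_skipped") <- skipped
  out
}

#' Normalise a spectrum so it sums to 100
#' @param x Numeric spectrum (counts or rates).
#' @return Rescaled vector summing to 100 (all-zero input returned as is
#'   with `attr(, "degenerate") = TRUE`).
#' @export
normalize_spectrum <- function(x) {
  s <- sum(x)
  if (s == 0) return(structure(x, degenerate = TRUE))
  x / s * 100
}

#' Trinucleotide composition of an interval set
#'
#' Counts the 64 trinucleotides in the given intervals (interior 3-mers;
#' windows containing N are excluded), optionally reverse-complement
#' oriented and ploidy-weighted (autosomes x2, X x1).
#'
#' @param genome A `genome_ref`.
#' @param intervals data.frame(chrom, start, end); defaults to whole
#'   chromosomes.
#' @param orient `"forward"` or `"revcomp"`.
#' @param ploidy_weight Multiply counts by chromosome ploidy.
#' @return Named numeric vector of 64 counts.
#' @export
trinuc_composition <- function(genome, intervals = NULL,
                               orient = c("forward", "revcomp"),
                               ploidy_weight = TRUE) {
  orient <- match.arg(orient)
  if (is.null(intervals))
    intervals <- data.table::data.table(chrom = names(genome$seq), start = 0L,
                                        end = unname(genome$lengths))
  iv <- data.table::as.data.table(intervals)
  ctx <- contexts64()
  out <- stats::setNames(numeric(64), ctx)
  for (i in seq_len(nrow(iv))) {
    s <- seq_at(genome, iv$chrom[i], iv$start[i], iv$end[i])
    f <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(s))
    w <- if (ploidy_weight) genome$ploidy[[iv$chrom[i]]] else 1
    out <- out + as.numeric(f[ctx]) * w
  }
  if (orient == "revcomp") out <- stats::setNames(out[revcomp(ctx)], ctx)
  out
}

#' Whole-genome trinucleotide weights
#' @param genome A `genome_ref`.
#' @return Fractions of each trinucleotide (sums to 1), ploidy-weighted.
#' @export
genome_weights <- function(genome) {
  comp <- trinuc_composition(genome)
  comp / sum(comp)
}

#' Composition-weighted mutation rate
#'
#' Per-context rates (count / context occurrences) are computed over the 64
#' trinucleotide contexts (a 192-category vector is collapsed by summing its
#' three substitution rates per context) and averaged with the supplied
#' reference-composition weights.
#'
#' @param spec_counts Named 192- or 64-vector of mutation counts.
#' @param composition Named 64-vector of context occurrence counts for the
#'   analysed space (same orientation as the counts).
#' @param weights Named 64-vector of reference trinucleotide fractions;
#'   defaults to the composition itself (normalised).
#' @return Mutation rate per bp.
#' @export
weighted_mutation_rate <- function(spec_counts, composition, weights = NULL) {
  ctx <- contexts64()
  if (length(spec_counts) == 192L) {
    grp <- substring(names(spec_counts), 1L, 3L)
    spec_counts <- tapply(spec_counts, factor(grp, levels = ctx), sum)
  }
  spec_counts <- spec_counts[ctx]
  spec_counts[is.na(spec_counts)] <- 0
  composition <- composition[ctx]
  bad <- spec_counts > 0 & (is.na(composition) | composition == 0)
  if (any(bad))
    stop("contexts with mutations but zero composition: ",
         paste(ctx[bad], collapse = ", "))
  rate <- ifelse(composition > 0, spec_counts / composition, 0)
  if (is.null(weights)) weights <- composition / sum(composition)
  weights <- weights[ctx]
  weights[is.na(weights)] <- 0
  sum(weights * rate) / sum(weights)
}

#' Composition-weighted multiallelic rate
#'
#' A site is biallelic when exactly two alleles are supported by at least
#' `min_reads` reads, multiallelic when three or four are; sites with fewer
#' than two supported alleles are excluded. Per-context multiallelic
#' fractions are averaged with weights renormalised over the occupied
#' contexts.
#'
#' @param mut Mutation table with allele-depth columns; contexts oriented to
#'   the lesion strand when `lesion_strand` labels are present.
#' @param weights Named 64-vector of reference trinucleotide fractions.
#' @param min_reads Reads required to support an allele.
#' @return Multiallelic rate in `[0, 1]` (`NA` when no usable site).
#' @export
multiallelic_rate <- function(mut, weights = NULL, min_reads = 2L) {
  mut <- data.table::as.data.table(mut)[kind == "sub"]
  if (nrow(mut) && any(mut$lesion_strand %in% c("F", "R"))) {
    o <- orient_to_lesion(mut)
    ctx <- o$ctx_l
  } else {
    o <- mut
    ctx <- o$context
  }
  support <- cbind(o$ad_ref, o$ad_alt, o$ad_alt2, o$ad_alt3) >= min_reads
  n_alleles <- rowSums(support)
  use <- n_alleles >= 2L & !is.na(ctx)
  if (!any(use)) return(NA_real_)
  ctx <- factor(ctx[use], levels = contexts64())
  multi <- n_alleles[use] >= 3L
  n_tot <- tapply(rep(1, sum(use)), ctx, sum)
  n_multi <- tapply(as.numeric(multi), ctx, sum)
  occupied <- !is.na(n_tot) & n_tot > 0
  frac <- n_multi[occupied] / n_tot[occupied]
  if (is.null(weights)) w <- n_tot[occupied]
  else w <- weights[contexts64()][occupied]
  sum(w * frac) / sum(w)
}

#' Subtracted (residual) spectrum
#'
#' `obs - exp`, rescaled so the absolute values sum to 100.
#'
#' @param observed,expected Same-length spectra.
#' @return Residual spectrum; all-zero residual returned as zeros with
#'   `attr(, "degenerate") = TRUE`.
#' @export
subtracted_spectrum <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  r <- observed - expected
  s <- sum(abs(r))
  if (s == 0) return(structure(r, degenerate = TRUE))
  r / s * 100
}

#' Cosine similarity of two non-negative spectra
#' @param a,b Same-length numeric vectors.
#' @return Value in `[0, 1]`; `NA` if either vector is all zero.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
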