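## Nascent expression quantification, expression strata, and strand-resolved
## transcription-coupled repair (TCR) rate curves.

#' Nascent TPM from intronic read counts
#'
#' Per library: reads per kilobase of analysed intron, then normalised to
#' transcripts per million; the final estimate per gene is the mean over
#' libraries. Genes without intron bp are excluded (`NA`).
#'
#' @param counts Matrix of intronic read counts, genes x libraries.
#' @param intron_bp Intron length per gene (bp).
#' @return Numeric vector of mean nascent TPM per gene.
#' @export
nascent_tpm <- function(counts, intron_bp) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(intron_bp))
  usable <- !is.na(intron_bp) & intron_bp > 0
  rpk <- counts[usable, , drop = FALSE] / (intron_bp[usable] / 1e3)
  tpm <- sweep(rpk, 2L, colSums(rpk), "/") * 1e6
  out <- rep(NA_real_, length(intron_bp))
  out[usable] <- rowMeans(tpm)
  out
}

#' Hierarchically exclude overlapping genes
#'
#' Starting from the most expressed gene, any overlapping less-expressed
#' gene is excluded; the retained set is pairwise non-overlapping.
#' Expression ties are broken by genomic order.
#'
#' @param genes data.table with chrom/start/end and an expression column.
#' @param expr_col Name of the expression column.
#' @return The retained subset (original order).
#' @export
dedupe_overlapping_genes <- function(genes, expr_col = "nascent_tpm") {
  g <- data.table::as.data.table(genes)
  g[, .row := .I]
  ord <- order(-g[[expr_col]], g$chrom, g$start)
  keep <- logical(nrow(g))
  kept <- list()
  for (i in ord) {
    ch <- g$chrom[i]
    ivs <- kept[[ch]]
    if (is.null(ivs) ||
        !any(g$start[i] < ivs[, 2L] & g$end[i] > ivs[, 1L])) {
      keep[i] <- TRUE
      kept[[ch]] <- rbind(ivs, c(g$start[i], g$end[i]))
    }
  }
  g[keep][, .row := NULL][]
}

#' Assign expression strata from the rate-expression relationship
#'
#' Fits a flat-sloped-flat piecewise model of per-gene mutation rate against
#' log nascent TPM by grid search over two breakpoints (50 log-spaced
#' candidates each), then assigns strata: 1 below the lower breakpoint
#' (low/no detected expression), 6 above the upper (saturated TCR), and 2-5
#' as quantile quartiles of the intermediate genes.
#'
#' @param genes data.table with `nascent_tpm`.
#' @param rate Per-gene mutation rate (same order as `genes`).
#' @param n_grid Breakpoint candidates per side.
#' @return List: `breakpoints` (low, high TPM), `stratum` (integer 1-6 per
#'   gene), `sse` of the best fit.
#' @export
strata_assign <- function(genes, rate, n_grid = 50L) {
  g <- data.table::as.data.table(genes)
  stopifnot(nrow(g) == length(rate))
  tpm <- g$nascent_tpm
  pos_min <- if (any(tpm > 0, na.rm = TRUE)) min(tpm[tpm > 0], na.rm = TRUE) else 1
  ltpm <- log10(pmax(tpm, pos_min / 10))
  ok <- !is.na(rate) & !is.na(ltpm)
  if (length(unique(ltpm[ok])) < 4L) {
    warning("degenerate expression distribution; single stratum")
    return(list(breakpoints = c(low = NA_real_, high = NA_real_),
                stratum = rep(1L, nrow(g)), sse = NA_real_))
  }
  qs <- stats::quantile(ltpm[ok], c(0.05, 0.95))
  cand <- seq(qs[1], qs[2], length.out = n_grid)
  best <- list(sse = Inf)
  x <- ltpm[ok]; y <- rate[ok]
  for (b1 in cand) for (b2 in cand) {
    if (b2 <= b1) next
    lo <- x < b1; hi <- x > b2; mid <- !lo & !hi
    if (sum(lo) < 3L || sum(hi) < 3L || sum(mid) < 3L) next
    sse <- sum((y[lo] - mean(y[lo]))^2) + sum((y[hi] - mean(y[hi]))^2)
    xm <- x[mid]; ym <- y[mid]
    fit <- stats::lm.fit(cbind(1, xm), ym)
    sse <- sse + sum(fit$residuals^2)
    if (sse < best$sse) best <- list(sse = sse, b1 = b1, b2 = b2)
  }
  low <- 10^best$b1; high <- 10^best$b2
  stratum <- rep(NA_integer_, nrow(g))
  stratum[tpm < low] <- 1L
  stratum[tpm > high] <- 6L
  mid_i <- which(is.na(stratum))
  if (length(mid_i)) {
    r <- rank(tpm[mid_i], ties.method = "first")
    stratum[mid_i] <- 1L + as.integer(ceiling(r * 4 / length(mid_i)))
  }
  list(breakpoints = c(low = low, high = high), stratum = stratum,
       sse = best$sse)
}

#' Assign expression strata from fixed TPM breakpoints
#'
#' Convenience companion to [strata_assign()] when the breakpoints are
#' supplied rather than fitted; the defaults are the study-style cut-offs
#' (below 0.287 TPM: no detectable TCR, stratum 1; above 3.73 TPM:
#' saturated TCR, stratum 6), with the intermediate genes quantile-split
#' into strata 2-5.
#'
#' @param tpm Nascent TPM per gene.
#' @param low,high Breakpoints in TPM.
#' @return Integer strata 1-6.
#' @export
assign_strata_by_tpm <- function(tpm, low = 0.287, high = 3.73) {
  stratum <- rep(NA_integer_, length(tpm))
  stratum[tpm < low] <- 1L
  stratum[tpm > high] <- 6L
  mid <- which(is.na(stratum))
  if (length(mid)) {
    r <- rank(tpm[mid], ties.method = "first")
    stratum[mid] <- 1L + as.integer(ceiling(r * 4 / length(mid)))
  }
  stratum
}

#' Template / non-template orientation of a gene given the lesion strand
#'
#' A plus-strand gene is transcribed off the reverse strand, so it carries
#' template-strand lesions in an R segment; a minus-strand gene does so in
#' an F segment.
#'
#' @param gene_strand `"+"` or `"-"`.
#' @param lesion_class `"F"` or `"R"`.
#' @return `"template"` or `"nontemplate"`.
#' @export
tcr_orientation <- function(gene_strand, lesion_class) {
  stopifnot(all(gene_strand %in% c("+", "-")),
            all(lesion_class %in% c("F", "R")))
  ifelse((gene_strand == "+") == (lesion_class == "R"),
         "template", "nontemplate")
}

#' Strand-resolved TCR rate curves by expression stratum
#'
#' For each tumour, genes wholly inside classified asymmetry segments are
#' split into template-lesion and non-template-lesion orientation; mutation
#' and multiallelic rates are computed per stratum and orientation with
#' composition weighting, and repair efficiency reported as
#' `(observed/expected) x 100` against the stratum-1 rate averaged over the
#' two orientations.
#'
#' @param cohort Phased cohort ([phase_cohort()]).
#' @param genes Gene table with `stratum` assigned.
#' @param genome A `genome_ref`.
#' @param weights Reference trinucleotide fractions (default whole genome).
#' @return data.table(stratum, orientation, n_mut, bp, rate, multiallelic,
#'   repair_efficiency).
#' @export
tcr_rates <- function(cohort, genes, genome, weights = NULL) {
  if (is.null(weights)) weights <- genome_weights(genome)
  g <- data.table::as.data.table(genes)
  stopifnot("stratum" %in% names(g))
  segs <- data.table::as.data.table(cohort$segments)
  ys <- segs[lesion_class %in% c("F", "R"),
             .(tumour_id, chrom, start, end, lesion_class)]
  data.table::setkey(ys, chrom, start, end)
  gq <- g[, .(gene_id, chrom, start, end, strand, stratum)]
  hits <- data.table::foverlaps(gq, ys, by.x = c("chrom", "start", "end"),
                                type = "within", nomatch = NULL)
  hits[, orientation := tcr_orientation(strand, lesion_class)]

  ## per-gene composition (forward orientation), cached once
  comp_fwd <- lapply(seq_len(nrow(g)), function(i)
    trinuc_composition(genome,
                       g[i, .(chrom, start, end)], ploidy_weight = TRUE))
  names(comp_fwd) <- g$gene_id
  ctx <- contexts64()
  rc_perm <- match(revcomp(ctx), ctx)

  mut <- data.table::copy(
    cohort$mutations[kind == "sub" & lesion_strand %in% c("F", "R")])
  giv <- gq[, .(chrom, start, end, gene_id)]
  mut[, gene_id := giv$gene_id[match_interval(chrom, pos, giv)]]
  out <- data.table::rbindlist(lapply(sort(unique(hits$stratum)), function(st) {
    data.table::rbindlist(lapply(c("template", "nontemplate"), function(orn) {
      h <- hits[stratum == st & orientation == orn]
      if (!nrow(h)) return(NULL)
      comp <- Reduce(`+`, lapply(seq_len(nrow(h)), function(i) {
        cc <- comp_fwd[[h$gene_id[i]]]
        ## orient composition to the lesion strand
        if (h$lesion_class[i] == "R") stats::setNames(cc[rc_perm], ctx) else cc
      }))
      mm <- merge(mut, h[, .(tumour_id, gene_id)],
                  by = c("tumour_id", "gene_id"))
      spec <- lesion_oriented_spectrum(mm)
      rate <- weighted_mutation_rate(spec, comp, weights)
      ma <- multiallelic_rate(mm, weights)
      data.table::data.table(stratum = st, orientation = orn,
                             n_mut = as.integer(sum(spec)),
                             bp = sum(comp), rate = rate, multiallelic = ma)
    }))
  }))
  base <- out[stratum == min(out$stratum), mean(rate)]
  out[, repair_efficiency := rate / base * 100]
  out[]
}
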