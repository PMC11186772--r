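#' Genome reference container
#'
#' Holds chromosome sequences (in memory, as character strings) together with
#' per-chromosome ploidy. Autosomes are treated as diploid; a chromosome named
#' `"X"` (or `"chrX"`) is haploid, matching a male mouse genome. All
#' coordinates throughout the package are 0-based, half-open.
#'
#' @param seqs Named character vector of chromosome sequences (A/C/G/T/N), or
#'   a `Biostrings::DNAStringSet`.
#' @param ploidy Optional named integer vector (1 or 2 per chromosome). By
#'   default 2 everywhere except chromosomes named `X`/`chrX`, which get 1.
#' @return An object of class `genome_ref`.
#' @export
genome_ref <- function(seqs, ploidy = NULL) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("chromosome sequences must have unique names")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN character in chromosome(s): ",
                     paste(names(seqs)[bad], collapse = ", "))
  lens <- nchar(seqs)
  if (is.null(ploidy)) {
    ploidy <- ifelse(names(seqs) %in% c("X", "chrX"), 1L, 2L)
    names(ploidy) <- names(seqs)
  }
  stopifnot(all(names(seqs) %in% names(ploidy)), all(ploidy %in% 1:2))
  structure(list(seq = seqs, lengths = stats::setNames(lens, names(seqs)),
                 ploidy = ploidy[names(seqs)]),
            class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("genome_ref:", length(x$seq), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A `genome_ref`.
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) genome$lengths

#' Extract genome sequence
#'
#' @param genome A `genome_ref`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Character string of length `end - start`.
#' @export
seq_at <- function(genome, chrom, start, end) {
  stopifnot(chrom %in% names(genome$seq))
  len <- genome$lengths[[chrom]]
  if (any(start < 0L) || any(end > len) || any(start >= end))
    stop("interval out of bounds for ", chrom)
  substring(genome$seq[[chrom]], start + 1L, end)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised; an empty string maps to itself and the operation is an
#' involution.
#'
#' @param seq Character vector over the alphabet A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(is.na(seq)) || any(grepl("[^ACGTN]", seq)))
    stop("revcomp: sequences must be over {A,C,G,T,N}")
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

#' Complement single bases (vectorised, no reversal)
#' @param base Character vector of single bases.
#' @return Complemented bases.
#' @export
comp_base <- function(base) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[base])
}

#' Forward-strand trinucleotide context
#'
#' Returns the 3-mer centred on `pos` on the reference forward strand.
#' Chromosome-edge positions, and contexts containing `N`, are returned as
#' `NA` and are excluded from spectra downstream.
#'
#' @param genome A `genome_ref`.
#' @param chrom Chromosome name (scalar) or vector parallel to `pos`.
#' @param pos 0-based position vector.
#' @return Character vector of 3-mers (or `NA`).
#' @export
trinuc_context <- function(genome, chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    len <- genome$lengths[[ch]]
    ok <- pos[i] >= 1L & pos[i] <= len - 2L
    ctx <- rep(NA_character_, length(i))
    if (any(ok))
      ctx[ok] <- substring(genome$seq[[ch]], pos[i][ok], pos[i][ok] + 2L)
    ctx[!is.na(ctx) & grepl("N", ctx)] <- NA_character_
    out[i] <- ctx
  }
  out
}

## ---- interval algebra (0-based half-open) ------------------------------

.as_iranges_by_chrom <- function(x) {
  x <- data.table::as.data.table(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start >= x$end)) stop("intervals must have start < end")
  split(IRanges::IRanges(start = x$start + 1L, end = x$end), x$chrom)
}

.iranges_to_dt <- function(lst) {
  out <- data.table::rbindlist(lapply(names(lst), function(ch) {
    ir <- lst[[ch]]
    if (length(ir) == 0L) return(NULL)
    data.table::data.table(chrom = ch, start = IRanges::start(ir) - 1L,
                           end = IRanges::end(ir))
  }))
  if (is.null(out) || nrow(out) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  data.table::setkey(out, chrom, start, end)
  out[]
}

#' Merge, subtract or intersect interval sets
#'
#' Half-open interval algebra. `merge` returns the disjoint sorted cover of
#' `a` (ignoring `b`); `subtract` removes `b` from `a`; `intersect` keeps the
#' overlap. Unsorted input is accepted and sorted internally.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end` (0-based
#'   half-open). `b` is ignored for `mode = "merge"`.
#' @param mode One of `"merge"`, `"subtract"`, `"intersect"`.
#' @return data.table of disjoint sorted intervals.
#' @export
merge_subtract <- function(a, b = NULL, mode = c("merge", "subtract", "intersect")) {
  mode <- match.arg(mode)
  ia <- .as_iranges_by_chrom(a)
  ia <- lapply(ia, IRanges::reduce)
  if (mode == "merge") return(.iranges_to_dt(ia))
  stopifnot(!is.null(b))
  ib <- .as_iranges_by_chrom(b)
  ib <- lapply(ib, IRanges::reduce)
  chroms <- union(names(ia), names(ib))
  out <- lapply(stats::setNames(chroms, chroms), function(ch) {
    ra <- if (ch %in% names(ia)) ia[[ch]] else IRanges::IRanges()
    rb <- if (ch %in% names(ib)) ib[[ch]] else IRanges::IRanges()
    if (mode == "subtract") IRanges::setdiff(ra, rb) else IRanges::intersect(ra, rb)
  })
  .iranges_to_dt(out)
}

#' Total bp covered by an interval set
#' @param x data.frame with `start`, `end` columns (half-open).
#' @return Numeric total of `end - start` after merging overlaps.
#' @export
interval_bp <- function(x) {
  m <- merge_subtract(x, mode = "merge")
  sum(as.numeric(m$end - m$start))
}

#' Fixed-step genomic windows over a genome
#' @param genome A `genome_ref`.
#' @param step Window size in bp.
#' @return data.table(chrom, start, end) of consecutive windows (last partial
#'   window dropped).
#' @export
genome_windows <- function(genome, step) {
  data.table::rbindlist(lapply(names(genome$seq), function(ch) {
    n <- genome$lengths[[ch]] %/% step
    if (n == 0L) return(NULL)
    data.table::data.table(chrom = ch, start = (seq_len(n) - 1L) * step,
                           end = seq_len(n) * step)
  }))
}

#' Assign points to covering intervals
#'
#' @param chrom,pos Vectors of point coordinates (0-based).
#' @param intervals data.table of disjoint intervals keyed by chrom,start,end;
#'   an `id` column (integer row index) is used for the return value.
#' @return Integer vector: row index of the covering interval in `intervals`
#'   or `NA`.
#' @export
match_interval <- function(chrom, pos, intervals) {
  iv <- data.table::as.data.table(intervals)
  iv[, `:=`(.row = .I)]
  pts <- data.table::data.table(chrom = chrom, start = pos, end = pos + 1L,
                                .ord = seq_along(pos))
  data.table::setkey(iv, chrom, start, end)
  hit <- data.table::foverlaps(pts, iv, type = "within", mult = "first",
                               nomatch = NA)
  hit[order(hit$.ord)]$.row
}
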