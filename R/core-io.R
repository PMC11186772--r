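## Readers and writers for the plain-text interchange formats used by the
## pipeline. Mutation tables are 1-based on disk (VCF convention) and 0-based
## in memory; the conversion happens only here.

#' Read a mutation table
#'
#' TSV with header columns `tumour_id, chrom, pos_1based, ref, alt, vaf,
#' ad_ref, ad_alt` and optional `ad_alt2, ad_alt3`. Positions are converted
#' to 0-based; substitution/insertion/deletion kind is derived from allele
#' lengths; the trinucleotide context is annotated when a genome is supplied.
#'
#' @param path File path.
#' @param genome Optional `genome_ref` for context annotation.
#' @return data.table of mutation calls.
#' @export
read_mutations <- function(path, genome = NULL) {
  x <- data.table::fread(path, sep = "\t")
  req <- c("tumour_id", "chrom", "pos_1based", "ref", "alt", "vaf",
           "ad_ref", "ad_alt")
  if (!all(req %in% names(x)))
    stop("mutation table missing columns: ",
         paste(setdiff(req, names(x)), collapse = ", "))
  x[, pos := as.integer(pos_1based - 1L)][, pos_1based := NULL]
  for (col in c("ad_alt2", "ad_alt3"))
    if (!col %in% names(x)) x[, (col) := 0L]
  if (!"lesion_strand" %in% names(x)) x[, lesion_strand := NA_character_]
  x[, kind := mutation_kind(ref, alt)]
  if (!is.null(genome) && !"context" %in% names(x))
    x[, context := trinuc_context(genome, chrom, pos), by = chrom]
  validate_mutations(x)
  data.table::setcolorder(
    x, intersect(c("tumour_id", "chrom", "pos", "ref", "alt", "kind", "vaf",
                   "ad_ref", "ad_alt", "ad_alt2", "ad_alt3", "context",
                   "lesion_strand"), names(x)))
  x[]
}

#' Classify mutations as substitution, insertion or deletion
#' @param ref,alt Allele strings.
#' @return Character vector in `{"sub","ins","del"}`.
#' @export
mutation_kind <- function(ref, alt) {
  data.table::fcase(nchar(ref) == nchar(alt), "sub",
                    nchar(ref) < nchar(alt), "ins",
                    default = "del")
}

#' Validate a mutation table's internal consistency
#' @param x Mutation data.table.
#' @return Invisibly `x`; stops on violation.
#' @export
validate_mutations <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$ref == x$alt)) stop("ref == alt in mutation table")
  if (any(x$vaf < 0 | x$vaf > 1)) stop("vaf outside [0,1]")
  if ("context" %in% names(x)) {
    sub <- x[kind == "sub" & !is.na(context)]
    if (nrow(sub) && any(substring(sub$context, 2L, 2L) != substring(sub$ref, 1L, 1L)))
      stop("context middle base does not match ref")
  }
  invisible(x)
}

#' Write a mutation table (1-based on disk)
#' @param x Mutation data.table.
#' @param path Output path.
#' @export
write_mutations <- function(x, path) {
  out <- data.table::copy(data.table::as.data.table(x))
  out[, pos_1based := pos + 1L][, pos := NULL]
  lead <- c("tumour_id", "chrom", "pos_1based", "ref", "alt", "vaf",
            "ad_ref", "ad_alt", "ad_alt2", "ad_alt3")
  data.table::setcolorder(out, intersect(c(lead, names(out)), names(out)))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read / write BED6 intervals
#'
#' BED is 0-based half-open on disk, matching internal coordinates.
#' @param path File path.
#' @return data.table(chrom, start, end, name, score, strand).
#' @export
read_bed <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(x, cols[seq_len(ncol(x))])
  x[]
}

#' @rdname read_bed
#' @param x data.table with at least chrom/start/end.
#' @export
write_bed <- function(x, path) {
  x <- data.table::as.data.table(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  data.table::fwrite(x[, ..cols], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write bedGraph window tracks
#' @param path File path.
#' @return data.table(chrom, start, end, value).
#' @export
read_bedgraph <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"))
  x[]
}

#' @rdname read_bedgraph
#' @param x data.table(chrom, start, end, value).
#' @export
write_bedgraph <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x)[, .(chrom, start, end, value)],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write genome FASTA
#' @param path File path.
#' @param ploidy Passed to [genome_ref()].
#' @return A `genome_ref`.
#' @export
read_fasta <- function(path, ploidy = NULL) {
  genome_ref(Biostrings::readDNAStringSet(path), ploidy = ploidy)
}

#' @rdname read_fasta
#' @param genome A `genome_ref`.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

#' Read / write a gene annotation table
#'
#' TSV with columns `gene_id, chrom, start, end, strand, intron_bp,
#' nascent_tpm, steady_tpm` (0-based half-open span of the primary
#' transcript).
#' @param path File path.
#' @return data.table of gene records.
#' @export
read_genes <- function(path) data.table::fread(path, sep = "\t")[]

#' @rdname read_genes
#' @param x Gene data.table.
#' @export
write_genes <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}
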