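## Synthetic genome and annotation generator. Everything is produced from
## cfg$seed through R's RNG, so identical configs give byte-identical
## output.

.random_dna <- function(n) {
  codes <- charToRaw("ACGT")
  rawToChar(codes[sample.int(4L, n, replace = TRUE)])
}

.sim_chrom_names <- function(cfg) {
  ch <- paste0("chr", seq_len(cfg$n_chrom))
  if (cfg$include_x) ch <- c(ch, "chrX")
  ch
}

#' Generate the synthetic genome and shared annotation
#'
#' Produces a random genome with mask, non-overlapping genes with log-normal
#' nascent expression and fork-co-oriented strands, smooth replication-time
#' and fork-directionality window tracks (with simulated early/late and
#' Okazaki read counts), an accessibility landscape peaked at planted motif
#' instances, regularly spaced nucleosome dyads, and the per-base damage and
#' repair modifier machinery used by [simulate_tumour()].
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_annotation` with elements `genome`, `mask`,
#'   `genes`, `windows` (replication tracks), `motifs` (with per-position
#'   information content in `attr(, "ic")`), `dyads`, and internal lookup
#'   tables.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- .sim_chrom_names(cfg)
  seqs <- vapply(chroms, function(ch) .random_dna(cfg$chrom_length), "")
  genome <- genome_ref(seqs)

  ## mask: random 50 kb tiles until the requested fraction is covered
  mask <- data.table::rbindlist(lapply(chroms, function(ch) {
    len <- cfg$chrom_length
    tile <- 5e4
    n_tiles <- len %/% tile
    n_pick <- round(cfg$mask_fraction * n_tiles)
    if (n_pick == 0L) return(NULL)
    starts <- sort(sample.int(n_tiles, n_pick) - 1L) * tile
    data.table::data.table(chrom = ch, start = starts, end = starts + tile)
  }))
  if (nrow(mask)) mask <- merge_subtract(mask, mode = "merge")

  ## replication-time field: smooth sinusoid with a per-chromosome phase;
  ## fork directionality is its (rescaled) spatial derivative
  phase <- stats::setNames(runif(length(chroms), 0, 2 * pi), chroms)
  rt_fun <- function(ch, pos) 0.85 * sin(2 * pi * pos / cfg$rt_wavelength_bp + phase[ch])
  rfd_fun <- function(ch, pos) 0.85 * cos(2 * pi * pos / cfg$rt_wavelength_bp + phase[ch])

  windows <- genome_windows(genome, cfg$window_bp)
  windows[, mid := (start + end) / 2]
  windows[, rt_true := rt_fun(chrom, mid)]
  windows[, rfd_true := rfd_fun(chrom, mid)]
  depth <- 200
  windows[, early_count := rpois(.N, depth * (1 + rt_true) / 2)]
  windows[, late_count := rpois(.N, depth * (1 - rt_true) / 2)]
  ## Okazaki convention: RFD = (R - F)/(R + F)
  windows[, ok_rev := rpois(.N, depth * (1 + rfd_true) / 2)]
  windows[, ok_fwd := rpois(.N, depth * (1 - rfd_true) / 2)]

  ## genes: non-overlapping spans, strand co-oriented with fork movement
  ## with probability cfg$co_orientation
  genes <- data.table::rbindlist(lapply(chroms, function(ch) {
    n_here <- max(1L, round(cfg$n_genes / length(chroms)))
    len <- pmin(pmax(round(rlnorm(n_here, cfg$gene_length_meanlog,
                                  cfg$gene_length_sdlog)), 5e3), 6e4)
    free <- cfg$chrom_length - 2e4 - sum(len)
    if (free < n_here * 500)
      stop("genome too small to place the requested genes")
    ## split the free space into random gaps; cumulative placement keeps
    ## spans strictly non-overlapping
    g <- runif(n_here + 1L)
    gaps <- round(free * g / sum(g))
    starts <- 1e4 + cumsum(gaps)[seq_len(n_here)] +
      c(0, cumsum(len)[-n_here])
    data.table::data.table(chrom = ch, start = as.integer(starts),
                           end = as.integer(starts + len))
  }))
  genes[, gene_id := sprintf("g%04d", .I)]
  genes[, rfd_local := rfd_fun(chrom, (start + end) / 2)]
  co <- runif(nrow(genes)) < cfg$co_orientation
  genes[, strand := ifelse(xor(rfd_local > 0, co), "-", "+")]
  genes[, rfd_local := NULL]
  genes[, nascent_tpm := rlnorm(.N, cfg$tpm_meanlog, cfg$tpm_sdlog)]
  genes[, steady_tpm := nascent_tpm * rlnorm(.N, 0, 0.4)]
  genes[, intron_bp := round(cfg$intron_fraction * (end - start))]
  data.table::setcolorder(genes, c("gene_id", "chrom", "start", "end",
                                   "strand", "intron_bp", "nascent_tpm",
                                   "steady_tpm"))

  ## motifs: genome-matching instances (consensus = reference sequence), so
  ## every in-motif reference base matches the consensus; an information
  ## content profile marks the protected core
  ic <- rep(0.3, cfg$motif_width)
  core <- seq(4L, cfg$motif_width - 3L)
  ic[core] <- 1.6 + 0.4 * sin(seq_along(core))
  motifs <- data.table::rbindlist(lapply(chroms, function(ch) {
    n_here <- max(1L, round(cfg$n_motifs / length(chroms)))
    starts <- sort(sample.int(cfg$chrom_length - 2000L, n_here)) + 1000L
    data.table::data.table(chrom = ch, start = starts,
                           end = starts + cfg$motif_width,
                           strand = sample(c("+", "-"), n_here, replace = TRUE))
  }))
  motifs[, name := sprintf("m%04d", .I)]
  motifs[, consensus := seq_at(genome, chrom, start, end), by = chrom]
  data.table::setattr(motifs, "ic", ic)

  ## nucleosome dyads: regular spacing with a per-chromosome phase offset
  dyads <- data.table::rbindlist(lapply(chroms, function(ch) {
    off <- sample.int(cfg$dyad_spacing_bp, 1L)
    p <- seq(off, cfg$chrom_length - 200L, by = cfg$dyad_spacing_bp)
    data.table::data.table(chrom = ch, pos = p, score = runif(length(p)))
  }))

  ## per-base positions of each nucleotide (forward strand), for Poisson
  ## lesion placement
  base_pos <- lapply(seqs, function(s) {
    r <- charToRaw(s)
    lapply(c(T = "T", C = "C", G = "G", A = "A"),
           function(b) which(r == charToRaw(b)) - 1L)
  })

  ann <- list(cfg = cfg, genome = genome, mask = mask, genes = genes,
              windows = windows[], motifs = motifs, dyads = dyads,
              base_pos = base_pos,
              dyad_offset = stats::setNames(
                vapply(chroms, function(ch) as.numeric(dyads[chrom == ch, pos][1L]), 0),
                chroms))
  class(ann) <- "sim_annotation"
  ann
}

#' @export
print.sim_annotation <- function(x, ...) {
  cat("sim_annotation:", length(x$genome$seq), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$motifs), "motifs\n")
  invisible(x)
}

## accessibility at arbitrary positions: baseline plus Gaussian peaks at
## motif centres (sigma 200 bp)
.accessibility_at <- function(ann, chrom, pos) {
  out <- rep(0.2, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    centres <- ann$motifs[chrom == ch, (start + end) %/% 2]
    if (!length(centres)) next
    centres <- sort(centres)
    j <- findInterval(pos[i], centres)
    d1 <- abs(pos[i] - centres[pmax(j, 1L)])
    d2 <- abs(pos[i] - centres[pmin(j + 1L, length(centres))])
    d <- pmin(d1, d2)
    out[i] <- out[i] + 0.7 * exp(-d^2 / (2 * 200^2))
  }
  out
}

## nucleosome repair modifier: within +-73 bp of a dyad, repair is reduced
## overall and oscillates with the 10.3 bp helical period (inward-facing
## major groove least repaired); linker DNA repairs at full efficiency
.nucleosome_modifier <- function(ann, chrom, pos) {
  cfg <- ann$cfg
  off <- ann$dyad_offset[chrom]
  sp <- cfg$dyad_spacing_bp
  d <- pos - (round((pos - off) / sp) * sp + off)
  inside <- abs(d) <= 73
  m <- rep(1, length(pos))
  m[inside] <- 0.7 * (1 - cfg$nucleosome_repair_amp *
                        cos(2 * pi * d[inside] / 10.3))
  m
}
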