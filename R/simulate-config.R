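#' Simulation configuration
#'
#' Parameters of the synthetic lesion-segregation tumour generator. The
#' defaults describe a desk-scale analogue of a single-dose alkylating
#' mutagenesis experiment in mouse liver: per-strand base lesions strongly
#' biased to T, chromosome-block-scale strand segregation, multi-generation
#' lesion persistence (multiallelism), transcription-coupled repair of the
#' template strand saturating at ~10 nascent TPM, accessibility-scaled global
#' repair with nucleosome periodicity, translesion collateral clusters,
#' strand-biased T skip-deletions, resynthesis-induced opposite-strand
#' mutations (TRIM) within a ~26 nt excision span, and a small fraction of
#' mutationally symmetric two-daughter tumours.
#'
#' @param seed Integer seed fixing every output byte.
#' @param n_chrom Number of autosomes.
#' @param chrom_length Autosome length in bp.
#' @param include_x Whether to add a haploid X chromosome of the same length.
#' @param mask_fraction Fraction of each chromosome masked from analysis.
#' @param segment_block_bp Lesion-strand choice is made once per block of
#'   this size, emulating chromosome-scale asymmetry segments.
#' @param n_tumours Number of tumours in a cohort.
#' @param symmetric_fraction Fraction of tumours retaining both daughters.
#' @param lesion_rate Named per-bp per-strand lesion rates for bases T,C,G,A.
#' @param miscoding Per-lesion-base alternate-allele probability vectors.
#' @param p_miscode Probability a lesion miscodes at one replication.
#' @param p_persist Per-cell-cycle lesion survival probability (before
#'   repair), generating multiallelism.
#' @param n_generations Number of cell generations simulated.
#' @param tcr_strength Maximal per-generation removal probability of
#'   template-strand lesions by transcription-coupled repair.
#' @param tcr_low_tpm Nascent TPM below which TCR is undetectable; the
#'   removal probability rises log-linearly from here to saturation.
#' @param tcr_saturation_tpm Nascent TPM at which TCR saturates.
#' @param tcr_invisible Fraction of template-strand lesions invisible to
#'   TCR (sets the rate floor / plateau in highly expressed genes).
#' @param repair_base Baseline global repair probability per generation.
#' @param repair_accessibility Additional repair probability per unit of
#'   accessibility.
#' @param nucleosome_repair_amp Amplitude of the 10.3 bp periodic repair
#'   modulation within nucleosome-wrapped DNA.
#' @param p_cluster Probability a bypass substitution adds a collateral
#'   mutation 1-10 nt downstream.
#' @param cluster_gt_bias Probability a collateral mutation at a G (lesion
#'   strand) is G to T.
#' @param p_skip_del Probability a surviving T lesion is bypassed by base
#'   skipping, yielding a 1 bp deletion.
#' @param p_skip_sub Probability a skip-deletion gains a downstream
#'   substitution (A to C or G to T on the lesion strand).
#' @param p_insertion Probability a substitution gains a 1 bp insertion
#'   upstream.
#' @param background_indel_rate Per-bp rate of strand-unbiased background
#'   1 bp indels.
#' @param trim_rate Probability a repaired lesion with an opposite-strand
#'   lesion within `trim_span_nt` yields a resynthesis mutation.
#' @param trim_span_nt Excision span for TRIM (single-stranded segment).
#' @param coverage Mean sequencing depth for allele counts.
#' @param vaf_concentration Beta concentration of VAF noise.
#' @param n_genes,gene_length_meanlog,gene_length_sdlog Gene placement.
#' @param intron_fraction Fraction of a gene span that is intronic.
#' @param tpm_meanlog,tpm_sdlog Log-normal nascent expression.
#' @param co_orientation Probability a gene is co-oriented with local
#'   replication fork movement.
#' @param window_bp Width of replication-track windows.
#' @param rt_wavelength_bp Wavelength of the smooth replication-time field.
#' @param n_motifs,motif_width Planted binding-motif instances.
#' @param motif_protect_factor Damage multiplier at high-information motif
#'   positions (< 1 protects).
#' @param motif_hotspot_offset,motif_hotspot_factor Optional single-position
#'   damage hotspot within the motif (factor 1 disables).
#' @param dyad_spacing_bp Nucleosome dyad spacing.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 6e6,
                       include_x = TRUE,
                       mask_fraction = 0.127,
                       segment_block_bp = 1.5e6,
                       n_tumours = 12L,
                       symmetric_fraction = 0.027,
                       lesion_rate = c(T = 1.5e-3, C = 2.0e-4,
                                       G = 7.0e-5, A = 1.5e-5),
                       miscoding = list(
                         T = c(A = 0.45, C = 0.35, G = 0.20),
                         C = c(T = 0.55, A = 0.30, G = 0.15),
                         G = c(A = 0.50, T = 0.35, C = 0.15),
                         A = c(G = 0.50, T = 0.25, C = 0.25)),
                       p_miscode = 0.6,
                       p_persist = 0.2,
                       n_generations = 4L,
                       tcr_strength = 0.8,
                       tcr_low_tpm = 0.287,
                       tcr_saturation_tpm = 10,
                       tcr_invisible = 0.2,
                       repair_base = 0.25,
                       repair_accessibility = 0.30,
                       nucleosome_repair_amp = 0.6,
                       p_cluster = 0.01,
                       cluster_gt_bias = 0.7,
                       p_skip_del = 0.01,
                       p_skip_sub = 0.6,
                       p_insertion = 0.004,
                       background_indel_rate = 3e-6,
                       trim_rate = 0.9,
                       trim_span_nt = 26L,
                       coverage = 50,
                       vaf_concentration = 60,
                       n_genes = 300L,
                       gene_length_meanlog = log(3e4),
                       gene_length_sdlog = 0.5,
                       intron_fraction = 0.8,
                       tpm_meanlog = 0,
                       tpm_sdlog = 1.8,
                       co_orientation = 0.7,
                       window_bp = 1e4,
                       rt_wavelength_bp = 3e6,
                       n_motifs = 120L,
                       motif_width = 19L,
                       motif_protect_factor = 0.4,
                       motif_hotspot_offset = 9L,
                       motif_hotspot_factor = 1,
                       dyad_spacing_bp = 200L) {
  cfg <- as.list(environment())
  probs <- c(cfg$symmetric_fraction, cfg$p_miscode, cfg$p_persist,
             cfg$tcr_strength, cfg$repair_base, cfg$p_cluster,
             cfg$p_skip_del, cfg$p_skip_sub, cfg$p_insertion, cfg$trim_rate,
             cfg$mask_fraction, unlist(cfg$miscoding))
  stopifnot(all(probs >= 0 & probs <= 1),
            all(c("T", "C", "G", "A") %in% names(cfg$lesion_rate)),
            all(cfg$lesion_rate >= 0),
            cfg$chrom_length >= cfg$segment_block_bp)
  for (b in names(cfg$miscoding))
    stopifnot(abs(sum(cfg$miscoding[[b]]) - 1) < 1e-9,
              !(b %in% names(cfg$miscoding[[b]])))
  class(cfg) <- "sim_config"
  cfg
}
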