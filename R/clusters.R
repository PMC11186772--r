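## Substitution mutation clusters, permutation nulls, lesion-strand
## orientation of cluster members, read phasing, leading/lagging cluster
## comparison with power analysis, and indel-substitution clustering.

#' Find mutation clusters by chained spacing
#'
#' Maximal chains of same-tumour substitutions in which consecutive
#' mutations are spaced strictly less than `x_nt` apart (transitively, so a
#' cluster's total span can exceed `x_nt`).
#'
#' @param mut Mutation table (substitutions are selected internally).
#' @param x_nt Spacing threshold (typical choices: 11, 101 or 201).
#' @return data.table of cluster members (tumour_id, chrom, pos,
#'   cluster_id) for clusters of size >= 2; `attr(, "sizes")` tabulates
#'   cluster sizes.
#' @export
find_clusters <- function(mut, x_nt = 101L) {
  m <- data.table::as.data.table(mut)
  if ("kind" %in% names(m)) m <- m[kind == "sub"]
  data.table::setorder(m, tumour_id, chrom, pos)
  m[, grp := cumsum(c(1L, as.integer(diff(pos) >= x_nt))),
    by = .(tumour_id, chrom)]
  m[, size := .N, by = .(tumour_id, chrom, grp)]
  out <- m[size >= 2L]
  out[, cluster_id := .GRP, by = .(tumour_id, chrom, grp)]
  out[, c("grp", "size") := NULL]
  sizes <- if (nrow(out)) table(table(out$cluster_id)) else table(integer(0))
  data.table::setattr(out, "sizes", sizes)
  out[]
}

#' Between-tumour permutation of mutation positions
#'
#' For each tumour, an identically sized proxy mutation set is drawn
#' without replacement from the positions called in the other tumours.
#'
#' @param mut Mutation table (>= 2 tumours).
#' @param n_perm Number of permuted datasets.
#' @param seed RNG seed.
#' @return List of `n_perm` proxy mutation tables (tumour_id, chrom, pos,
#'   kind).
#' @export
permute_between_tumours <- function(mut, n_perm = 1L, seed = 1L) {
  m <- data.table::as.data.table(mut)
  ids <- unique(m$tumour_id)
  if (length(ids) < 2L) stop("need at least two tumours to permute")
  set.seed(seed)
  lapply(seq_len(n_perm), function(p) {
    out <- data.table::rbindlist(lapply(ids, function(id) {
      donors <- m[tumour_id != id]
      n_t <- sum(m$tumour_id == id)
      if (nrow(donors) < n_t)
        stop("insufficient donor positions for tumour ", id)
      pick <- donors[sample.int(nrow(donors), n_t)]
      pick[, tumour_id := id]
      pick
    }))
    out
  })
}

## count mutations whose nearest same-tumour neighbour is within `x_nt - 1`
.n_clustered <- function(m, x_nt) {
  cl <- find_clusters(m, x_nt)
  nrow(cl)
}

#' Cluster enrichment against the between-tumour permutation null
#'
#' Two-sided Fisher's exact test of (clustered vs unclustered mutations) in
#' the observed data against the mean over permuted proxy datasets.
#'
#' @param mut Mutation table.
#' @param x_nt Spacing threshold.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List: `or`, `p`, `observed` (clustered count), `expected`
#'   (mean permuted clustered count), `n` (total substitutions).
#' @export
cluster_enrichment <- function(mut, x_nt = 11L, n_perm = 10L, seed = 1L) {
  m <- data.table::as.data.table(mut)[kind == "sub"]
  n <- nrow(m)
  obs <- .n_clustered(m, x_nt)
  perms <- permute_between_tumours(m[, .(tumour_id, chrom, pos, kind)],
                                   n_perm, seed)
  exp_cl <- mean(vapply(perms, .n_clustered, 0, x_nt = x_nt))
  tab <- matrix(round(c(obs, n - obs, exp_cl, n - exp_cl)), 2L)
  ft <- stats::fisher.test(tab)
  list(or = as.numeric(odds_ratio(obs, n - obs, exp_cl, n - exp_cl)),
       p = ft$p.value, observed = obs, expected = exp_cl, n = n)
}

#' Orient cluster members relative to lesion-strand synthesis
#'
#' DNA synthesis over the lesion-containing template extends 5'-3' on the
#' new strand: in an R-lesion segment the leftmost mutation site is
#' replicated over first (upstream), in an F segment the rightmost.
#' Downstream offsets are in nt along the synthesis direction from the
#' upstream site.
#'
#' @param members data.table of one cluster's members (sorted by pos).
#' @param lesion_class `"F"`, `"R"` or `"unresolved"`.
#' @return Input with `role` (`upstream`/`downstream`, NA when unresolved)
#'   and `offset_nt` columns.
#' @export
orient_cluster <- function(members, lesion_class) {
  m <- data.table::as.data.table(members)
  data.table::setorder(m, pos)
  if (!lesion_class %in% c("F", "R")) {
    m[, `:=`(role = NA_character_, offset_nt = NA_integer_)]
    return(m[])
  }
  up_pos <- if (lesion_class == "R") min(m$pos) else max(m$pos)
  m[, role := ifelse(pos == up_pos, "upstream", "downstream")]
  m[, offset_nt := abs(pos - up_pos)]
  m[]
}

#' Read-level phasing of close mutation pairs
#'
#' A pair separated by 75 nt or fewer is phased to the same chromosome when
#' at least one qualifying read supports the called mutant allele at both
#' positions.
#'
#' @param pairs data.table(tumour_id, chrom, pos1, alt1, pos2, alt2).
#' @param reads Read co-occurrence table (tumour_id, read_id, chrom, pos,
#'   allele, qual_ok).
#' @param max_nt Maximum pair separation for phasing.
#' @return Logical vector per pair (`NA` beyond `max_nt`).
#' @export
phase_pairs <- function(pairs, reads, max_nt = 75L) {
  p <- data.table::as.data.table(pairs)
  r <- data.table::as.data.table(reads)[qual_ok == TRUE]
  vapply(seq_len(nrow(p)), function(i) {
    if (abs(p$pos2[i] - p$pos1[i]) > max_nt) return(NA)
    r1 <- r[tumour_id == p$tumour_id[i] & chrom == p$chrom[i] &
              pos == p$pos1[i] & allele == p$alt1[i], read_id]
    r2 <- r[tumour_id == p$tumour_id[i] & chrom == p$chrom[i] &
              pos == p$pos2[i] & allele == p$alt2[i], read_id]
    length(intersect(r1, r2)) > 0L
  }, NA)
}

#' Compare leading- vs lagging-strand cluster length distributions
#'
#' Two-sample two-sided Kolmogorov-Smirnov test, plus a resampling power
#' analysis: the lagging lengths are partitioned at `split_at` into short
#' and long bins; for each distortion `d` a sample of the leading-arm size
#' is drawn in which a fraction `d` of would-be short draws come from the
#' long bin instead, and power is the fraction of `n_boot` replicates whose
#' KS test against the undistorted lengths reaches P < 0.05.
#'
#' @param len_leading,len_lagging Cluster span vectors (nt).
#' @param d_grid Distortion values (default 0 to 0.1 step 0.0005).
#' @param n_boot Bootstraps per distortion value.
#' @param split_at Short/long partition threshold.
#' @param seed RNG seed.
#' @param min_n Minimum clusters per arm for the KS test.
#' @return List: `ks` (htest or NULL with a warning), `power`
#'   data.table(d, power).
#' @export
compare_lead_lag_clusters <- function(len_leading, len_lagging,
                                      d_grid = seq(0, 0.1, by = 0.0005),
                                      n_boot = 100L, split_at = 10,
                                      seed = 1L, min_n = 20L) {
  ks <- NULL
  if (length(len_leading) >= min_n && length(len_lagging) >= min_n) {
    ks <- suppressWarnings(stats::ks.test(len_leading, len_lagging))
  } else warning("fewer than ", min_n, " clusters in an arm; KS skipped")
  set.seed(seed)
  short <- len_lagging[len_lagging <= split_at]
  long <- len_lagging[len_lagging > split_at]
  n_draw <- length(len_leading)
  p_short <- length(short) / length(len_lagging)
  power <- vapply(d_grid, function(d) {
    hits <- vapply(seq_len(n_boot), function(b) {
      from_short <- runif(n_draw) < p_short
      ## distortion: a fraction d of short draws comes from the long bin
      flip <- from_short & runif(n_draw) < d
      from_short <- from_short & !flip
      samp <- numeric(n_draw)
      n_s <- sum(from_short)
      if (n_s) samp[from_short] <- sample(short, n_s, replace = TRUE)
      if (n_draw - n_s)
        samp[!from_short] <- sample(long, n_draw - n_s, replace = TRUE)
      suppressWarnings(stats::ks.test(samp, len_lagging)$p.value) < 0.05
    }, NA)
    mean(hits)
  }, 0)
  list(ks = ks, power = data.table::data.table(d = d_grid, power = power))
}

#' Indel-substitution clustering and deletion strand bias
#'
#' For each quality-filtered indel in lesion-strand-resolved autosomal
#' space, the closest same-tumour substitution is found. Clustering is
#' tested as a two-sided Fisher's exact test of (indel with/without a
#' substitution within `window_nt`) against the mean of permuted proxy
#' substitution sets. The strand bias of 1 bp deletions (T vs A removed
#' from the lesion strand) is compared between in-cluster deletions
#' (substitution within 10 nt) and all deletions genome wide.
#'
#' @param mut Phased mutation table (lesion_strand labels required).
#' @param window_nt Clustering window.
#' @param n_perm Permutations for the null.
#' @param seed RNG seed.
#' @param min_indel_reads Minimum reads supporting the indel call.
#' @return List: `pairs` (per-indel nearest substitution), `or_cluster`,
#'   `p_cluster`, `or_tdel`, `p_tdel`, counts.
#' @export
indel_sub_clusters <- function(mut, window_nt = 100L, n_perm = 100L,
                               seed = 1L, min_indel_reads = 3L) {
  m <- data.table::as.data.table(mut)
  m <- m[!chrom %in% c("X", "chrX") & lesion_strand %in% c("F", "R")]
  indels <- m[kind != "sub" & ad_alt >= min_indel_reads]
  subs <- m[kind == "sub"]
  if (nrow(indels) == 0L)
    return(list(pairs = data.table::data.table(), or_cluster = NA_real_,
                p_cluster = NA_real_, or_tdel = NA_real_, p_tdel = NA_real_))

  nearest_dist <- function(ind, sub) {
    out <- rep(NA_real_, nrow(ind))
    for (grp in split(seq_len(nrow(ind)),
                      paste(ind$tumour_id, ind$chrom))) {
      id <- ind$tumour_id[grp[1]]; ch <- ind$chrom[grp[1]]
      sp <- sort(sub[tumour_id == id & chrom == ch, pos])
      if (!length(sp)) next
      j <- findInterval(ind$pos[grp], sp)
      d1 <- abs(ind$pos[grp] - sp[pmax(j, 1L)])
      d2 <- abs(sp[pmin(j + 1L, length(sp))] - ind$pos[grp])
      out[grp] <- pmin(d1, d2)
    }
    out
  }
  d_obs <- nearest_dist(indels, subs)
  obs_in <- sum(d_obs <= window_nt, na.rm = TRUE)
  obs_out <- nrow(indels) - obs_in

  perms <- permute_between_tumours(subs[, .(tumour_id, chrom, pos, kind)],
                                   n_perm, seed)
  perm_in <- vapply(perms, function(p)
    sum(nearest_dist(indels, p) <= window_nt, na.rm = TRUE), 0)
  exp_in <- mean(perm_in)
  exp_out <- nrow(indels) - exp_in
  ft <- stats::fisher.test(matrix(round(c(obs_in, obs_out, exp_in, exp_out)), 2L))

  ## T vs A deletion from the lesion strand, in cluster vs genome wide
  is_del1 <- indels$kind == "del" & nchar(indels$ref) == 2L
  dels <- indels[is_del1]
  del_fwd <- substring(dels$ref, 2L, 2L)
  del_lesion <- ifelse(dels$lesion_strand == "R", comp_base(del_fwd), del_fwd)
  in_cl <- d_obs[is_del1] <= 10
  ta <- del_lesion %in% c("T", "A")
  tab_t <- c(sum(del_lesion == "T" & in_cl & ta, na.rm = TRUE),
             sum(del_lesion == "A" & in_cl & ta, na.rm = TRUE),
             sum(del_lesion == "T" & ta, na.rm = TRUE),
             sum(del_lesion == "A" & ta, na.rm = TRUE))
  or_tdel <- p_tdel <- NA_real_
  if (all(!is.na(tab_t)) && sum(tab_t[1:2]) > 0) {
    ft_t <- stats::fisher.test(matrix(tab_t, 2L))
    or_tdel <- as.numeric(odds_ratio(tab_t[1], tab_t[2], tab_t[3], tab_t[4]))
    p_tdel <- ft_t$p.value
  }
  pairs <- data.table::data.table(indels[, .(tumour_id, chrom, pos, ref,
                                             alt, kind, lesion_strand)],
                                  dist_nearest_sub = d_obs)
  list(pairs = pairs,
       or_cluster = as.numeric(odds_ratio(obs_in, obs_out, exp_in, exp_out)),
       p_cluster = ft$p.value, or_tdel = or_tdel, p_tdel = p_tdel,
       observed_in = obs_in, expected_in = exp_in, n_indels = nrow(indels))
}
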