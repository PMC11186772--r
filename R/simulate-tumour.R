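## Generative model for one tumour: per-strand lesions, gen-1 repair (global
## accessibility-scaled + TCR) with TRIM side-effects, strand segregation per
## block, multi-generation persistence producing multiallelism, translesion
## collateral clusters, skip-deletions, insertions, background indels, and a
## beta-binomial VAF/read-depth model.

.draw_miscode <- function(base, miscoding) {
  out <- character(length(base))
  for (b in unique(base)) {
    i <- which(base == b)
    p <- miscoding[[b]]
    out[i] <- sample(names(p), length(i), replace = TRUE, prob = p)
  }
  out
}

.block_class <- function(cfg, class_map, chrom, pos) {
  idx <- as.integer(pos %/% cfg$segment_block_bp) + 1L
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[i] <- class_map[[ch]][idx[i]]
  }
  out
}

## forward-strand ref/alt from lesion-strand base/alt
.to_forward <- function(base, alt, strand) {
  flip <- strand == "R"
  list(ref = ifelse(flip, comp_base(base), base),
       alt = ifelse(flip, comp_base(alt), alt))
}

#' Simulate one tumour
#'
#' @param ann A `sim_annotation` from [simulate_annotation()].
#' @param tumour_id Tumour identifier string.
#' @param symmetric If `TRUE` both post-mutagenesis daughter lineages are
#'   retained (a mutationally symmetric tumour); clonal VAF is halved and
#'   TRIM mutations, shared by both daughters, keep full clonal VAF.
#' @return List with `mutations` (call table), `truth` (per-mutation
#'   mechanism, generation, true lesion strand, shared flag), `segments`
#'   (true lesion-strand block map) and `reads` (read-level co-occurrence
#'   table for close mutation pairs).
#' @export
simulate_tumour <- function(ann, tumour_id = "t1", symmetric = FALSE) {
  cfg <- ann$cfg
  chroms <- names(ann$genome$seq)

  ## true lesion-strand map, one choice per block
  class_map <- lapply(stats::setNames(chroms, chroms), function(ch) {
    n_blocks <- ceiling(ann$genome$lengths[[ch]] / cfg$segment_block_bp)
    sample(c("F", "R"), n_blocks, replace = TRUE)
  })
  segments_truth <- data.table::rbindlist(lapply(chroms, function(ch) {
    n_blocks <- length(class_map[[ch]])
    len <- ann$genome$lengths[[ch]]
    data.table::data.table(
      chrom = ch,
      start = (seq_len(n_blocks) - 1L) * as.integer(cfg$segment_block_bp),
      end = pmin(seq_len(n_blocks) * as.integer(cfg$segment_block_bp), len),
      class = class_map[[ch]])
  }))

  ## ---- lesion placement on both strands --------------------------------
  bases <- c("T", "C", "G", "A")
  lesions <- data.table::rbindlist(lapply(chroms, function(ch) {
    pl <- ann$genome$ploidy[[ch]]
    data.table::rbindlist(lapply(c("F", "R"), function(s) {
      data.table::rbindlist(lapply(bases, function(b) {
        pool <- ann$base_pos[[ch]][[if (s == "F") b else comp_base(b)]]
        n <- min(rpois(1L, pl * cfg$lesion_rate[[b]] * length(pool)),
                 length(pool))
        if (n == 0L) return(NULL)
        data.table::data.table(chrom = ch,
                               pos = pool[sample.int(length(pool), n)],
                               strand = s, base = b)
      }))
    }))
  }))
  if (is.null(lesions) || nrow(lesions) == 0L)
    lesions <- data.table::data.table(chrom = character(), pos = integer(),
                                      strand = character(), base = character())

  ## motif protection: thin lesions at high-information motif positions
  ic <- attr(ann$motifs, "ic")
  if (nrow(lesions) && cfg$motif_protect_factor < 1 && any(ic >= 1)) {
    core_off <- which(ic >= 1) - 1L
    prot <- ann$motifs[, .(chrom = rep(chrom, each = length(core_off)),
                           pos = as.vector(vapply(start, function(s) s + core_off,
                                                  integer(length(core_off)))))]
    lesions[, .protected := FALSE]
    lesions[prot, .protected := TRUE, on = c("chrom", "pos")]
    drop <- lesions$.protected & runif(nrow(lesions)) > cfg$motif_protect_factor
    lesions <- lesions[!drop][, .protected := NULL]
  }

  ## optional single-offset damage hotspot within motifs (strand-oriented)
  if (cfg$motif_hotspot_factor > 1 && nrow(ann$motifs)) {
    hs <- ann$motifs[, .(chrom,
                         pos = ifelse(strand == "+",
                                      start + cfg$motif_hotspot_offset,
                                      end - 1L - cfg$motif_hotspot_offset))]
    hs[, fwd_base := substring(ann$genome$seq[chrom], pos + 1L, pos + 1L),
       by = chrom]
    extra <- data.table::rbindlist(lapply(c("F", "R"), function(s) {
      b <- if (s == "F") hs$fwd_base else comp_base(hs$fwd_base)
      lam <- ann$genome$ploidy[hs$chrom] * cfg$lesion_rate[b] *
        (cfg$motif_hotspot_factor - 1)
      n <- rpois(nrow(hs), lam)
      i <- rep(seq_len(nrow(hs)), n)
      if (!length(i)) return(NULL)
      data.table::data.table(chrom = hs$chrom[i], pos = hs$pos[i],
                             strand = s, base = b[i])
    }))
    if (!is.null(extra) && nrow(extra)) lesions <- rbind(lesions, extra)
  }
  data.table::setkey(lesions, chrom, pos)

  ## ---- per-lesion repair probability -----------------------------------
  acc <- .accessibility_at(ann, lesions$chrom, lesions$pos)
  nmod <- .nucleosome_modifier(ann, lesions$chrom, lesions$pos)
  p_glob <- (cfg$repair_base + cfg$repair_accessibility * acc) * nmod
  ## TCR for lesions on the transcription template strand: + gene -> R
  ## template, - gene -> F template
  gseg <- ann$genes[, .(chrom, start, end, strand, nascent_tpm)]
  data.table::setkey(gseg, chrom, start, end)
  q <- data.table::data.table(chrom = lesions$chrom, start = lesions$pos,
                              end = lesions$pos + 1L)
  hit <- data.table::foverlaps(q, gseg, type = "within", mult = "first",
                               nomatch = NA)
  template <- ifelse(hit$strand == "+", "R", "F")
  ## log-linear TCR response between the detection floor and saturation,
  ## applied only to the TCR-visible lesion fraction
  tcr_resp <- pmin(1, pmax(0, log(hit$nascent_tpm / cfg$tcr_low_tpm) /
                                log(cfg$tcr_saturation_tpm / cfg$tcr_low_tpm)))
  visible <- runif(nrow(lesions)) >= cfg$tcr_invisible
  p_tcr <- ifelse(!is.na(template) & template == lesions$strand & visible,
                  cfg$tcr_strength * tcr_resp, 0)
  p_tcr[is.na(p_tcr)] <- 0
  p_rep <- pmin(0.98, p_glob + p_tcr)
  repaired1 <- runif(nrow(lesions)) < p_rep

  ## ---- TRIM: repair of one lesion resynthesises over a close opposite-
  ## strand lesion (both strands duplexed only in generation 1) ------------
  trim_records <- NULL
  if (cfg$trim_rate > 0 && any(repaired1)) {
    rep_les <- lesions[repaired1]
    opp <- lesions[!repaired1]
    trims <- data.table::rbindlist(lapply(unique(rep_les$chrom), function(ch) {
      a <- rep_les[chrom == ch]
      out <- lapply(c("F", "R"), function(s) {
        ra <- a[strand == s]
        ob <- opp[chrom == ch & strand != s]
        if (!nrow(ra) || !nrow(ob)) return(NULL)
        j <- findInterval(ra$pos, ob$pos)
        d_lo <- ra$pos - ob$pos[pmax(j, 1L)]
        d_hi <- ob$pos[pmin(j + 1L, nrow(ob))] - ra$pos
        d_lo[j < 1L] <- NA
        d_hi[j >= nrow(ob)] <- NA
        use_lo <- !is.na(d_lo) & (is.na(d_hi) | d_lo <= d_hi)
        k <- ifelse(use_lo, pmax(j, 1L), pmin(j + 1L, nrow(ob)))
        d <- ifelse(use_lo, d_lo, d_hi)
        ok <- !is.na(d) & d <= cfg$trim_span_nt
        if (!any(ok)) return(NULL)
        ob[k[ok]]
      })
      data.table::rbindlist(out)
    }))
    if (!is.null(trims) && nrow(trims)) {
      trims <- unique(trims, by = c("chrom", "pos", "strand"))
      keep <- runif(nrow(trims)) < cfg$trim_rate
      trims <- trims[keep]
      if (nrow(trims)) {
        alt_ls <- .draw_miscode(trims$base, cfg$miscoding)
        fa <- .to_forward(trims$base, alt_ls, trims$strand)
        trim_records <- data.table::data.table(
          chrom = trims$chrom, pos = trims$pos, ref = fa$ref, alt = fa$alt,
          mech = "trim", generation = 1L, true_strand = trims$strand,
          shared = TRUE, lineage = "both", vaf_mean = 0.5,
          alt2 = NA_character_, vaf2_mean = NA_real_,
          alt3 = NA_character_, vaf3_mean = NA_real_,
          pair_id = NA_integer_)
      }
    }
  }

  ## ---- retained lineages ----------------------------------------------
  flip_map <- lapply(class_map, function(v) ifelse(v == "F", "R", "F"))
  lineages <- if (symmetric) list(A = class_map, B = flip_map)
              else list(A = class_map)
  lin_w <- if (symmetric) 0.5 else 1

  pair_counter <- 0L
  lineage_records <- lapply(names(lineages), function(ln) {
    cm <- lineages[[ln]]
    cls <- .block_class(cfg, cm, lesions$chrom, lesions$pos)
    keep <- lesions$strand == cls & !repaired1
    les <- lesions[keep]
    if (!nrow(les)) return(NULL)
    prep <- p_rep[keep]
    n <- nrow(les)

    ## skip-deletion bypass of T lesions
    is_skip <- les$base == "T" & runif(n) < cfg$p_skip_del & les$pos >= 1L

    ## substitution path: per-generation survival and miscoding
    surv <- rep(TRUE, n)
    alleles <- matrix(NA_character_, n, cfg$n_generations)
    for (g in seq_len(cfg$n_generations)) {
      if (g > 1L) surv <- surv & (runif(n) < cfg$p_persist * (1 - prep))
      mis <- surv & (runif(n) < cfg$p_miscode)
      if (any(mis))
        alleles[mis, g] <- .draw_miscode(les$base[mis], cfg$miscoding)
    }
    recs <- NULL
    sub_i <- which(!is_skip)
    if (length(sub_i)) {
      al <- alleles[sub_i, , drop = FALSE]
      first_g <- apply(!is.na(al), 1L, function(z) if (any(z)) which(z)[1] else NA_integer_)
      has <- !is.na(first_g)
      sub_i <- sub_i[has]; al <- al[has, , drop = FALSE]; first_g <- first_g[has]
      if (length(sub_i)) {
        primary <- al[cbind(seq_along(sub_i), first_g)]
        ## distinct later alleles become subclonal extra alleles
        alt2 <- alt3 <- rep(NA_character_, length(sub_i))
        v2 <- v3 <- rep(NA_real_, length(sub_i))
        multi <- which(rowSums(!is.na(al)) > 1L)
        for (ii in multi) {
          gg <- which(!is.na(al[ii, ]))
          extra <- gg[gg > first_g[ii]]
          seen <- primary[ii]
          for (g in extra) {
            a <- al[ii, g]
            if (a %in% seen) next
            if (is.na(alt2[ii])) { alt2[ii] <- a; v2[ii] <- lin_w * 0.5^g }
            else if (is.na(alt3[ii])) { alt3[ii] <- a; v3[ii] <- lin_w * 0.5^g }
            seen <- c(seen, a)
          }
        }
        fa <- .to_forward(les$base[sub_i], primary, les$strand[sub_i])
        f2 <- ifelse(les$strand[sub_i] == "R", comp_base(alt2), alt2)
        f3 <- ifelse(les$strand[sub_i] == "R", comp_base(alt3), alt3)
        recs <- data.table::data.table(
          chrom = les$chrom[sub_i], pos = les$pos[sub_i],
          ref = fa$ref, alt = fa$alt, mech = "direct",
          generation = first_g, true_strand = les$strand[sub_i],
          shared = FALSE, lineage = ln,
          vaf_mean = lin_w * 0.5^first_g,
          alt2 = f2, vaf2_mean = v2, alt3 = f3, vaf3_mean = v3,
          pair_id = NA_integer_)

        ## collateral mutations downstream of clonal substitutions; the
        ## extending TLS polymerase errs at non-A template bases with a
        ## G -> T preference
        cl_i <- which(first_g == 1L & runif(length(sub_i)) < cfg$p_cluster)
        if (length(cl_i)) {
          src <- recs[cl_i]
          dir <- ifelse(src$true_strand == "R", 1L, -1L)
          pick <- vapply(seq_len(nrow(src)), function(i) {
            cand <- src$pos[i] + dir[i] * (1:10)
            len <- ann$genome$lengths[[src$chrom[i]]]
            cand <- cand[cand >= 1L & cand <= len - 2L]
            if (!length(cand)) return(NA_integer_)
            fb <- substring(ann$genome$seq[[src$chrom[i]]], cand + 1L, cand + 1L)
            bl <- if (src$true_strand[i] == "R") comp_base(fb) else fb
            gs <- cand[bl == "G"]
            nonA <- cand[bl != "A"]
            if (length(gs) && runif(1) < cfg$cluster_gt_bias)
              gs[sample.int(length(gs), 1L)]
            else if (length(nonA)) nonA[sample.int(length(nonA), 1L)]
            else NA_integer_
          }, 0L)
          ok <- !is.na(pick)
          src <- src[ok]; p2 <- pick[ok]
          if (nrow(src)) {
            fwd_b <- substring(ann$genome$seq[src$chrom], p2 + 1L, p2 + 1L)
            b2 <- ifelse(src$true_strand == "R", comp_base(fwd_b), fwd_b)
            a2 <- vapply(seq_along(b2), function(i) {
              if (b2[i] == "G" && runif(1) < cfg$cluster_gt_bias) "T"
              else sample(setdiff(c("C", "G", "T"), b2[i]), 1L)
            }, "")
            fa2 <- .to_forward(b2, a2, src$true_strand)
            ids <- pair_counter + seq_len(nrow(src))
            pair_counter <<- pair_counter + nrow(src)
            recs$pair_id[cl_i[ok]] <- ids
            coll <- data.table::data.table(
              chrom = src$chrom, pos = p2, ref = fa2$ref, alt = fa2$alt,
              mech = "collateral", generation = 1L,
              true_strand = src$true_strand, shared = FALSE, lineage = ln,
              vaf_mean = lin_w * 0.5, alt2 = NA_character_,
              vaf2_mean = NA_real_, alt3 = NA_character_,
              vaf3_mean = NA_real_, pair_id = ids)
            recs <- rbind(recs, coll)
          }
        }

        ## 1 bp insertions downstream of clonal substitutions
        in_i <- which(first_g == 1L & runif(length(sub_i)) < cfg$p_insertion)
        if (length(in_i)) {
          src <- recs[in_i]
          off <- sample(10L, length(in_i), replace = TRUE)
          dir <- ifelse(src$true_strand == "R", 1L, -1L)
          p3 <- src$pos + dir * off
          lens <- ann$genome$lengths[src$chrom]
          ok <- p3 >= 1L & p3 <= lens - 2L
          src <- src[ok]; p3 <- p3[ok]
          if (nrow(src)) {
            anchor <- substring(ann$genome$seq[src$chrom], p3 + 1L, p3 + 1L)
            insb <- sample(c("A", "C", "G", "T"), nrow(src), replace = TRUE)
            ids <- pair_counter + seq_len(nrow(src))
            pair_counter <<- pair_counter + nrow(src)
            recs$pair_id[in_i[ok]] <- ids
            ins <- data.table::data.table(
              chrom = src$chrom, pos = p3, ref = anchor,
              alt = paste0(anchor, insb), mech = "insertion",
              generation = 1L, true_strand = src$true_strand, shared = FALSE,
              lineage = ln, vaf_mean = lin_w * 0.5, alt2 = NA_character_,
              vaf2_mean = NA_real_, alt3 = NA_character_,
              vaf3_mean = NA_real_, pair_id = ids)
            recs <- rbind(recs, ins)
          }
        }
      }
    }

    ## skip-deletions: remove the T from the lesion strand, with an optional
    ## downstream A->C / G->T substitution
    sk_i <- which(is_skip)
    if (length(sk_i)) {
      sk <- les[sk_i]
      anchor <- substring(ann$genome$seq[sk$chrom], sk$pos, sk$pos)
      delb <- substring(ann$genome$seq[sk$chrom], sk$pos + 1L, sk$pos + 1L)
      ids <- pair_counter + seq_len(nrow(sk))
      pair_counter <<- pair_counter + nrow(sk)
      dels <- data.table::data.table(
        chrom = sk$chrom, pos = sk$pos - 1L, ref = paste0(anchor, delb),
        alt = anchor, mech = "skip_del", generation = 1L,
        true_strand = sk$strand, shared = FALSE, lineage = ln,
        vaf_mean = lin_w * 0.5, alt2 = NA_character_, vaf2_mean = NA_real_,
        alt3 = NA_character_, vaf3_mean = NA_real_, pair_id = ids)
      with_sub <- runif(nrow(sk)) < cfg$p_skip_sub
      if (any(with_sub)) {
        ss <- sk[with_sub]
        off <- sample(10L, nrow(ss), replace = TRUE)
        dir <- ifelse(ss$strand == "R", 1L, -1L)
        p2 <- ss$pos + dir * off
        lens <- ann$genome$lengths[ss$chrom]
        ok <- p2 >= 1L & p2 <= lens - 2L
        ss <- ss[ok]; p2 <- p2[ok]
        if (nrow(ss)) {
          fwd_b <- substring(ann$genome$seq[ss$chrom], p2 + 1L, p2 + 1L)
          b2 <- ifelse(ss$strand == "R", comp_base(fwd_b), fwd_b)
          a2 <- ifelse(b2 == "A", "C", ifelse(b2 == "G", "T", NA))
          rand <- is.na(a2)
          if (any(rand))
            a2[rand] <- vapply(b2[rand], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
          fa2 <- .to_forward(b2, a2, ss$strand)
          subs <- data.table::data.table(
            chrom = ss$chrom, pos = p2, ref = fa2$ref, alt = fa2$alt,
            mech = "collateral", generation = 1L, true_strand = ss$strand,
            shared = FALSE, lineage = ln, vaf_mean = lin_w * 0.5,
            alt2 = NA_character_, vaf2_mean = NA_real_,
            alt3 = NA_character_, vaf3_mean = NA_real_,
            pair_id = ids[with_sub][ok])
          dels <- rbind(dels, subs)
        }
      }
      recs <- rbind(recs, dels)
    }
    recs
  })

  ## background strand-unbiased 1 bp indels
  bg <- NULL
  if (cfg$background_indel_rate > 0) {
    bg <- data.table::rbindlist(lapply(chroms, function(ch) {
      len <- ann$genome$lengths[[ch]]
      n <- rpois(1L, ann$genome$ploidy[[ch]] * cfg$background_indel_rate * len)
      if (n == 0L) return(NULL)
      p <- sample.int(len - 3L, n) + 1L
      is_del <- runif(n) < 0.5
      anchor <- substring(ann$genome$seq[[ch]], p, p)
      nxt <- substring(ann$genome$seq[[ch]], p + 1L, p + 1L)
      data.table::data.table(
        chrom = ch, pos = p - 1L,
        ref = ifelse(is_del, paste0(anchor, nxt), anchor),
        alt = ifelse(is_del, anchor,
                     paste0(anchor, sample(c("A", "C", "G", "T"), n, TRUE))),
        mech = "none", generation = 1L, true_strand = NA_character_,
        shared = FALSE, lineage = "A", vaf_mean = lin_w * 0.5,
        alt2 = NA_character_, vaf2_mean = NA_real_, alt3 = NA_character_,
        vaf3_mean = NA_real_, pair_id = NA_integer_)
    }))
  }

  all_recs <- data.table::rbindlist(
    c(lineage_records, list(trim_records), list(bg)), use.names = TRUE)
  if (is.null(all_recs) || nrow(all_recs) == 0L) {
    empty <- data.table::data.table(
      tumour_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), kind = character(),
      vaf = numeric(), ad_ref = integer(), ad_alt = integer(),
      ad_alt2 = integer(), ad_alt3 = integer(), context = character(),
      lesion_strand = character())
    return(list(mutations = empty, truth = data.table::data.table(),
                segments = segments_truth, reads = NULL))
  }

  ## dedupe per site: TRIM wins over lineage records at the same position
  all_recs[, .prio := ifelse(mech == "trim", 0L, 1L)]
  data.table::setorder(all_recs, chrom, pos, .prio)
  all_recs <- unique(all_recs, by = c("chrom", "pos"))
  all_recs[, .prio := NULL]

  ## haploid X: clonal cell fraction maps to doubled VAF
  on_x <- all_recs$chrom %in% c("X", "chrX")
  for (col in c("vaf_mean", "vaf2_mean", "vaf3_mean"))
    data.table::set(all_recs, which(on_x), col,
                    pmin(all_recs[[col]][on_x] * 2, 0.98))

  ## ---- observed VAF and allele depths ----------------------------------
  k <- cfg$vaf_concentration
  n <- nrow(all_recs)
  vaf_obs <- rbeta(n, all_recs$vaf_mean * k, (1 - all_recs$vaf_mean) * k)
  depth <- rpois(n, cfg$coverage)
  ad_alt <- rbinom(n, depth, vaf_obs)
  draw_sub <- function(vm) {
    out <- integer(n)
    has <- !is.na(vm)
    if (any(has)) {
      v <- rbeta(sum(has), vm[has] * k, (1 - vm[has]) * k)
      out[has] <- rbinom(sum(has), depth[has], v)
    }
    out
  }
  ad2 <- draw_sub(all_recs$vaf2_mean)
  ad3 <- draw_sub(all_recs$vaf3_mean)
  ad2 <- pmin(ad2, pmax(depth - ad_alt, 0L))
  ad3 <- pmin(ad3, pmax(depth - ad_alt - ad2, 0L))
  ad_ref <- pmax(depth - ad_alt - ad2 - ad3, 0L)

  all_recs[, `:=`(tumour_id = tumour_id, vaf = ifelse(depth > 0, ad_alt / depth, 0),
                  ad_ref = ad_ref, ad_alt = ad_alt, ad_alt2 = ad2,
                  ad_alt3 = ad3)]
  all_recs <- all_recs[ad_alt >= 2L]
  all_recs[, kind := mutation_kind(ref, alt)]
  all_recs[, context := trinuc_context(ann$genome, chrom, pos)]
  all_recs[, lesion_strand := NA_character_]

  mut_cols <- c("tumour_id", "chrom", "pos", "ref", "alt", "kind", "vaf",
                "ad_ref", "ad_alt", "ad_alt2", "ad_alt3", "context",
                "lesion_strand")
  mutations <- all_recs[, ..mut_cols]
  truth <- all_recs[, .(tumour_id, chrom, pos, mech, generation,
                        true_strand, shared, lineage, pair_id)]

  reads <- .simulate_pair_reads(all_recs, cfg)
  list(mutations = mutations[], truth = truth[], segments = segments_truth,
       reads = reads)
}

## read-level co-occurrence for mutation pairs generated on the same
## chromatid (collateral / skip / insertion pairs): reads spanning both
## sites carry both mutant alleles
.simulate_pair_reads <- function(recs, cfg) {
  paired <- recs[!is.na(pair_id)]
  if (nrow(paired) < 2L) return(NULL)
  grp <- split(seq_len(nrow(paired)), paired$pair_id)
  grp <- grp[lengths(grp) == 2L]
  if (!length(grp)) return(NULL)
  out <- lapply(names(grp), function(pid) {
    i <- grp[[pid]]
    a <- paired[i[1]]; b <- paired[i[2]]
    if (abs(a$pos - b$pos) > 75L) return(NULL)
    n_span <- rpois(1L, cfg$coverage * 0.3)
    if (n_span == 0L) return(NULL)
    both <- rbinom(1L, n_span, min(a$vaf, b$vaf))
    ids <- paste0("rd_", pid, "_", seq_len(n_span))
    data.table::rbindlist(list(
      data.table::data.table(read_id = rep(ids[seq_len(both)], 2L),
                             chrom = rep(c(a$chrom, b$chrom), each = both),
                             pos = rep(c(a$pos, b$pos), each = both),
                             allele = rep(c(a$alt, b$alt), each = both),
                             qual_ok = TRUE),
      if (n_span > both)
        data.table::data.table(read_id = rep(ids[(both + 1):n_span], 2L),
                               chrom = rep(c(a$chrom, b$chrom), each = n_span - both),
                               pos = rep(c(a$pos, b$pos), each = n_span - both),
                               allele = rep(c(a$ref, b$ref), each = n_span - both),
                               qual_ok = TRUE)))
  })
  data.table::rbindlist(out)
}

#' Simulate a cohort of tumours
#'
#' @param cfg A [sim_config()].
#' @param ann Optional pre-built annotation (rebuilt from `cfg` otherwise).
#' @return List with `annotation`, `mutations` (all tumours), `truth`,
#'   `segments` (per-tumour truth maps with a `tumour_id` column), `reads`,
#'   and `tumours` (id + symmetric flag).
#' @export
simulate_cohort <- function(cfg, ann = NULL) {
  if (is.null(ann)) ann <- simulate_annotation(cfg)
  set.seed(cfg$seed + 1L)
  n_sym <- round(cfg$symmetric_fraction * cfg$n_tumours)
  sym <- rep(FALSE, cfg$n_tumours)
  if (n_sym > 0) sym[sample.int(cfg$n_tumours, n_sym)] <- TRUE
  ids <- sprintf("T%03d", seq_len(cfg$n_tumours))
  sims <- lapply(seq_len(cfg$n_tumours), function(i)
    simulate_tumour(ann, ids[i], symmetric = sym[i]))
  segs <- data.table::rbindlist(lapply(seq_along(sims), function(i)
    data.table::data.table(tumour_id = ids[i], sims[[i]]$segments)))
  list(annotation = ann,
       mutations = data.table::rbindlist(lapply(sims, `[[`, "mutations")),
       truth = data.table::rbindlist(lapply(sims, `[[`, "truth")),
       segments = segs,
       reads = data.table::rbindlist(
         lapply(seq_along(sims), function(i) {
           r <- sims[[i]]$reads
           if (is.null(r)) NULL else data.table::data.table(tumour_id = ids[i], r)
         })),
       tumours = data.table::data.table(tumour_id = ids, symmetric = sym))
}
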