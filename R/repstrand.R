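## Replication timing, fork directionality, leading/lagging assignment over
## the lesion-containing strand, and the windowed multivariate mutation-rate
## regression.

#' Replication time from early/late windowed counts
#'
#' Counts are normalised to tags per million separately for the early and
#' late fractions, smoothed with a centred 5-window (50 kb over a 10 kb
#' grid) rolling mean per chromosome, and combined as the relative
#' enrichment `(E - L)/(E + L)`.
#'
#' @param windows data.table(chrom, start, end) of consecutive fixed-step
#'   windows with `early_count` and `late_count` columns.
#' @param k Smoothing span in windows (odd).
#' @return Input with an `rt` column added (`NA` where both counts are 0).
#' @export
replication_timing <- function(windows, k = 5L) {
  w <- data.table::as.data.table(windows)
  stopifnot(all(c("early_count", "late_count") %in% names(w)))
  norm <- function(x) if (sum(x) > 0) x / sum(x) * 1e6 else rep(0, length(x))
  e <- norm(w$early_count)
  l <- norm(w$late_count)
  w[, `:=`(e_tpm = e, l_tpm = l)]
  w[, `:=`(e_sm = roll_mean(e_tpm, k), l_sm = roll_mean(l_tpm, k)),
    by = chrom]
  w[, rt := rel_diff(e_sm, l_sm)]
  w[, c("e_tpm", "l_tpm", "e_sm", "l_sm") := NULL]
  w[]
}

#' Fork directionality as the derivative of replication time
#'
#' `rfd_i = (rt_{i+1} - rt_{i-1}) / 2`, the average of the upstream and
#' downstream differences; chromosome edges (and windows with missing
#' neighbours) are `NA`.
#'
#' @param windows data.table with an `rt` column, ordered per chromosome.
#' @return Input with an `rfd` column added.
#' @export
rfd_from_rt <- function(windows) {
  w <- data.table::as.data.table(windows)
  stopifnot("rt" %in% names(w))
  w[, rfd := (data.table::shift(rt, -1L) - data.table::shift(rt, 1L)) / 2,
    by = chrom]
  w[]
}

#' Fork directionality from Okazaki-fragment strand counts
#'
#' `RFD = (R - F)/(R + F)`: positive values indicate consensus rightward
#' fork progression.
#'
#' @param fwd,rev Forward and reverse read counts per window.
#' @return Numeric RFD (`NA` where both are zero).
#' @export
okseq_rfd <- function(fwd, rev) {
  stopifnot(all(fwd >= 0, na.rm = TRUE), all(rev >= 0, na.rm = TRUE))
  rel_diff(rev, fwd)
}

#' Quantile-bin two RFD tracks and flag concordant windows
#'
#' Both tracks are split into `n_bins` quantile bins (stable ties); a window
#' is concordant when the two bin labels differ by less than `max_bin_diff`
#' bins. Downstream replication-strand analyses use the Okazaki bins
#' restricted to concordant windows.
#'
#' @param rfd_ok,rfd_repli Numeric vectors on the same window grid.
#' @param n_bins Number of quantile bins.
#' @param max_bin_diff Strict concordance threshold in bins.
#' @return data.table(bin_ok, bin_repli, concordant).
#' @export
quantile_bin_and_concord <- function(rfd_ok, rfd_repli, n_bins = 21L,
                                     max_bin_diff = 4L) {
  stopifnot(length(rfd_ok) == length(rfd_repli))
  if (all(is.na(rfd_ok)) || all(is.na(rfd_repli)))
    stop("all-missing RFD track")
  b_ok <- quantile_bins(rfd_ok, n_bins)
  b_re <- quantile_bins(rfd_repli, n_bins)
  data.table::data.table(bin_ok = b_ok, bin_repli = b_re,
                         concordant = abs(b_ok - b_re) < max_bin_diff)
}

#' Leading/lagging assignment over the lesion-containing strand
#'
#' A rightward fork (RFD > 0) over forward-strand lesions is consensus
#' lagging-strand replication over the lesions; the full truth table is
#' (F, +) lagging, (R, -) lagging, (F, -) leading, (R, +) leading.
#'
#' @param s_class Lesion-strand class, `"F"` or `"R"`.
#' @param rfd Numeric fork directionality.
#' @return `"leading"`, `"lagging"`, or `NA` for `rfd == 0` / missing input.
#' @export
leading_lagging <- function(s_class, rfd) {
  stopifnot(all(s_class %in% c("F", "R") | is.na(s_class)))
  out <- rep(NA_character_, length(rfd))
  ok <- !is.na(s_class) & !is.na(rfd) & rfd != 0
  out[ok] <- ifelse((s_class[ok] == "F") == (rfd[ok] > 0),
                    "lagging", "leading")
  out
}

#' Rescale a relative enrichment to the unit interval
#'
#' `f = 1 - (1 - r)/2`; used so that bounded (-1, 1) predictors enter the
#' regression on the same (0, 1) scale as fractional predictors.
#'
#' @param r Relative enrichment in `[-1, 1]`.
#' @return Value in `[0, 1]`.
#' @export
rescale_re <- function(r) {
  if (any(r < -1 | r > 1, na.rm = TRUE))
    stop("relative enrichment outside [-1, 1]")
  1 - (1 - r) / 2
}

#' Windowed multivariate mutation-rate regression
#'
#' Ordinary least squares of per-window mutation rate on genomic
#' predictors (typically fraction expressed-template, fraction
#' expressed-non-template, residual-genic fraction, rescaled replication
#' time and rescaled replication strand bias). Rank-deficient designs are
#' rejected with the collinear columns named.
#'
#' @param data data.frame of windows.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @return data.table(term, estimate, se, t, p) plus the fitted `lm` in
#'   `attr(, "fit")`.
#' @export
window_regression <- function(data, outcome, predictors) {
  df <- as.data.frame(data)[, c(outcome, predictors)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  mm <- stats::model.matrix(
    stats::reformulate(predictors), data = df)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(stats::reformulate(predictors, response = outcome),
                   data = df)
  s <- summary(fit)$coefficients
  out <- data.table::data.table(term = rownames(s), estimate = s[, 1],
                                se = s[, 2], t = s[, 3], p = s[, 4])
  data.table::setattr(out, "fit", fit)
  out
}

#' Build the per-window regression table from a phased cohort
#'
#' Partitions the genome into fixed windows, computes per-bp mutation rates
#' aggregated across tumours (separately for F and R lesion
#' segments; windows with unresolved strand or containing strand
#' transitions in a tumour contribute nothing for that tumour), and
#' annotates expressed template/non-template fractions, residual genic
#' fraction, and rescaled replication time and strand bias.
#'
#' @param cohort A phased cohort ([phase_cohort()] output).
#' @param genome A `genome_ref`.
#' @param genes Gene table with `nascent_tpm`.
#' @param windows Replication window table with `rt` and `rfd` columns.
#' @param window_bp Analysis window size.
#' @param expressed_tpm TPM above which a gene counts as expressed.
#' @return data.table, one row per (window, lesion class) with columns
#'   `rate`, `f_template`, `f_nontemplate`, `f_residual_genic`, `rt_f`,
#'   `rsb_f`.
#' @export
regression_windows <- function(cohort, genome, genes, windows,
                               window_bp = 1e4, expressed_tpm = 1) {
  grid <- genome_windows(genome, window_bp)
  grid[, win_id := .I]
  data.table::setkey(grid, chrom, start, end)

  ## per-tumour per-window lesion class (windows wholly inside one segment)
  segs <- data.table::as.data.table(cohort$segments)
  ys <- segs[, .(tumour_id, chrom, start, end, lesion_class)]
  data.table::setkey(ys, chrom, start, end)
  cls <- data.table::foverlaps(grid, ys, by.x = c("chrom", "start", "end"),
                               type = "within", nomatch = NULL)
  cls <- cls[lesion_class %in% c("F", "R")]

  ## mutation counts per window per tumour (substitutions)
  mut <- cohort$mutations[kind == "sub" & lesion_strand %in% c("F", "R")]
  mut[, win_id := match_interval(chrom, pos, grid)]
  cnt <- mut[!is.na(win_id), .(n = .N), by = .(tumour_id, win_id)]
  cls <- merge(cls, cnt, by = c("tumour_id", "win_id"), all.x = TRUE)
  cls[is.na(n), n := 0L]
  ## aggregate across tumours: rate = total mutations / total covered bp
  agg <- cls[, .(n = sum(n), bp = .N * window_bp * 2), by = .(win_id)]
  agg[, rate := n / bp]

  ## annotation fractions per window
  g <- data.table::as.data.table(genes)
  g[, expressed := nascent_tpm > expressed_tpm]
  ov <- data.table::foverlaps(
    grid, data.table::setkey(g[, .(chrom, start, end, strand, expressed)],
                             chrom, start, end),
    by.x = c("chrom", "start", "end"), nomatch = NULL)
  ov[, bp := pmin(end, i.end) - pmax(start, i.start)]
  expr_bp <- ov[expressed == TRUE,
                .(bp_plus = sum(bp[strand == "+"]),
                  bp_minus = sum(bp[strand == "-"])), by = win_id]
  resid_bp <- ov[expressed == FALSE, .(bp_resid = sum(bp)), by = win_id]

  ## template fraction per window depends on the window's lesion class mix;
  ## use the majority class across tumours
  maj <- cls[, .(class = names(sort(table(lesion_class),
                                    decreasing = TRUE))[1]), by = win_id]

  out <- merge(agg, maj, by = "win_id")
  out <- merge(out, expr_bp, by = "win_id", all.x = TRUE)
  out <- merge(out, resid_bp, by = "win_id", all.x = TRUE)
  for (col in c("bp_plus", "bp_minus", "bp_resid"))
    out[is.na(get(col)), (col) := 0]
  ## + gene: template strand is R; so with class R, + genes are template
  out[, f_template := ifelse(class == "R", bp_plus, bp_minus) / window_bp]
  out[, f_nontemplate := ifelse(class == "R", bp_minus, bp_plus) / window_bp]
  out[, f_residual_genic := bp_resid / window_bp]

  ## replication annotation: consensus (largest-span) overlap value
  w <- data.table::as.data.table(windows)
  rep_ov <- data.table::foverlaps(
    grid, data.table::setkey(w[, .(chrom, start, end, rt, rfd)],
                             chrom, start, end),
    by.x = c("chrom", "start", "end"), nomatch = NULL)
  rep_ov[, bp := pmin(end, i.end) - pmax(start, i.start)]
  rep_val <- rep_ov[, .(rt = rt[which.max(bp)], rfd = rfd[which.max(bp)]),
                    by = win_id]
  out <- merge(out, rep_val, by = "win_id", all.x = TRUE)
  out[, rt_f := rescale_re(rt)]
  ## orient RSB so the lesion strand is the reverse strand: for F-class
  ## windows flip the fork direction sign
  out[, rsb := ifelse(class == "F", -rfd, rfd)]
  out[, rsb_f := rescale_re(rsb)]
  out[]
}
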