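#' Signed difference in derived allele frequency
#'
#' `delta = DAF(pop1) - DAF(pop2)`, one value per SNP, in `[-1, 1]`.
#' Swapping the pair flips the sign.
#'
#' @param snps a [snp_table()].
#' @param pop1,pop2 population names.
#' @return numeric vector with attribute `pair = c(pop1, pop2)`.
#' @export
delta <- function(snps, pop1, pop2) {
  d <- daf(snps, pop1) - daf(snps, pop2)
  attr(d, "pair") <- c(pop1, pop2)
  d
}

# The ten delta bins. Tail bins are identically wide: bin 1 = [-1, -0.8]
# (closed at both ends) and bin 10 = (0.79, 1]; the bin ending at 0.79 is
# narrower by 0.01. Interior bins are lower-open/upper-closed.
DELTA_EDGES <- c(-1, -0.8, -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.79, 1)

#' Bin delta values
#'
#' @param d numeric vector of delta values in `[-1, 1]`.
#' @return integer bin index 1..10 (bin 1 = `[-1, -0.8]`, bin 10 =
#'   `(0.79, 1]`).
#' @export
bin_delta <- function(d) {
  if (any(is.na(d)) || any(d < -1 | d > 1))
    stop("delta values must lie in [-1, 1]")
  b <- findInterval(d, DELTA_EDGES, left.open = TRUE)
  b[d <= -0.8] <- 1L  # bin 1 is closed at -0.8
  as.integer(b)
}

#' Genic enrichment spectrum
#'
#' Per-bin ratio of the genic SNP fraction to the global genic SNP fraction.
#' An enrichment of 1 means a bin looks like the genome; empty bins are
#' reported as `NA` (not zero).
#'
#' @param bin integer bin assignment per SNP (1..`n_bins`).
#' @param genic logical genic flag per SNP.
#' @param n_bins number of bins (default 10).
#' @return a `data.table` with columns `bin`, `genic_n`, `total_n`,
#'   `enrichment`; attribute `global_fraction`.
#' @export
genic_enrichment <- function(bin, genic, n_bins = 10L) {
  stopifnot(length(bin) == length(genic))
  g_all <- sum(genic)
  if (g_all == 0L) stop("no genic SNPs: enrichment undefined")
  frac0 <- g_all / length(genic)
  tot <- tabulate(bin, n_bins)
  gen <- tabulate(bin[genic], n_bins)
  e <- ifelse(tot > 0L, (gen / tot) / frac0, NA_real_)
  out <- data.table::data.table(bin = seq_len(n_bins), genic_n = gen,
                                total_n = tot, enrichment = e)
  data.table::setattr(out, "global_fraction", frac0)
  out
}

#' Weighted block jackknife (Busing delete-m_j)
#'
#' Leave-one-block-out resampling over genomic windows, weighting each block
#' by its SNP count, to obtain bias-corrected estimates and standard errors
#' for statistics computed on linked SNPs. With equal block sizes it reduces
#' exactly to the classical Tukey delete-1 jackknife.
#'
#' @param theta_hat full-data estimate.
#' @param theta_j numeric vector of leave-one-block-out estimates.
#' @param m_j block weights (SNPs per block), same length.
#' @param alpha two-sided confidence level (default 0.05 for a 95% CI).
#' @param na_drop drop blocks whose leave-out estimate is not finite
#'   (e.g. a bin emptied by the deletion) with a warning, rather than fail.
#' @return list with `estimate` (theta_hat), `bias_corrected`, `se`, `ci`
#'   (length-2), `pseudovalues` (the leave-one-out estimates used), `m_j`,
#'   `n`, `g`.
#' @export
busing_jackknife <- function(theta_hat, theta_j, m_j, alpha = 0.05,
                             na_drop = TRUE) {
  stopifnot(length(theta_j) == length(m_j))
  bad <- !is.finite(theta_j)
  if (any(bad)) {
    if (!na_drop) stop("non-finite leave-one-out estimates")
    warning(sum(bad), " block(s) dropped from jackknife (non-finite ",
            "leave-one-out estimate)")
    theta_j <- theta_j[!bad]
    m_j <- m_j[!bad]
  }
  g <- length(theta_j)
  if (g < 2L) stop("need >= 2 usable blocks")
  n <- sum(m_j)
  if (any(m_j >= n)) stop("a single block holds all SNPs; h_j undefined")
  h_j <- n / m_j
  theta_J <- g * theta_hat - sum((1 - m_j / n) * theta_j)
  tau_j <- h_j * theta_hat - (h_j - 1) * theta_j
  v <- sum((tau_j - theta_J)^2 / (h_j - 1)) / g
  se <- sqrt(v)
  z <- stats::qnorm(1 - alpha / 2)
  list(estimate = theta_hat, bias_corrected = theta_J, se = se,
       ci = c(theta_hat - z * se, theta_hat + z * se),
       pseudovalues = theta_j, m_j = m_j, n = n, g = g)
}

#' Block jackknife of an arbitrary statistic of a SNP table
#'
#' Generic (slow) interface: recomputes `statistic` once per block on the
#' table with that block removed. Block weights are total SNPs per block.
#' For the per-bin enrichment and tail log2-ratio statistics use the fast
#' specialized paths ([enrichment_spectrum()] and [tail_asymmetry()]).
#'
#' @param snps a [snp_table()] with a `block` column.
#' @param statistic function taking a SNP-table subset, returning a scalar.
#' @param alpha two-sided level for the CI.
#' @return a [busing_jackknife()] result.
#' @export
block_jackknife <- function(snps, statistic, alpha = 0.05) {
  if (!"block" %in% names(snps)) stop("no 'block' column; run assign_blocks")
  blocks <- unique(snps$block)
  if (length(blocks) < 2L) stop("need >= 2 non-empty blocks")
  theta_hat <- statistic(snps)
  theta_j <- vapply(blocks,
                    function(b) statistic(snp_subset(snps, snps$block != b)),
                    numeric(1))
  m_j <- as.numeric(table(snps$block)[blocks])
  busing_jackknife(theta_hat, theta_j, m_j, alpha = alpha)
}

# per-block per-bin genic/total counts used by all fast jackknife paths
block_bin_counts <- function(bin, genic, block, n_bins) {
  dt <- data.table::data.table(bin = bin, genic = genic, block = block)
  bc <- dt[, .(genic_n = sum(genic), total_n = .N), by = .(block, bin)]
  m <- dt[, .(m = .N), by = block]
  list(counts = bc, m = m)
}

# leave-one-block-out enrichment for one bin, vectorized over blocks:
# e_b = (gen_b/tot_b) / (gen_all/tot_all), all four totals adjusted by the
# deleted block's contribution.
loo_enrichment <- function(bb, which_bin) {
  m <- bb$m
  cnt <- bb$counts
  gen_all <- sum(cnt$genic_n); tot_all <- sum(cnt$total_n)
  inb <- cnt[cnt$bin == which_bin]
  gen_b <- sum(inb$genic_n); tot_b <- sum(inb$total_n)
  # per-block contributions (0 where block has no SNPs in the bin)
  bi <- merge(m, inb[, c("block", "genic_n", "total_n")],
              by = "block", all.x = TRUE)
  bi[is.na(genic_n), `:=`(genic_n = 0L, total_n = 0L)]
  gall <- cnt[, .(g = sum(genic_n), t = sum(total_n)), by = block]
  bi <- merge(bi, gall, by = "block", all.x = TRUE)
  num <- (gen_b - bi$genic_n) / (tot_b - bi$total_n)
  den <- (gen_all - bi$g) / (tot_all - bi$t)
  list(block = bi$block, m_j = bi$m, theta_j = num / den,
       theta_hat = (gen_b / tot_b) / (gen_all / tot_all))
}

#' Enrichment spectrum with weighted block-jackknife CIs
#'
#' Computes the binned genic enrichment of a per-SNP statistic (delta bins
#' by default) together with per-bin 95% confidence intervals from the 200 kb
#' weighted block jackknife.
#'
#' @param snps a [snp_table()] with `genic` and `block` columns.
#' @param bin integer bin assignment per SNP (e.g. `bin_delta(delta(...))`).
#' @param n_bins number of bins.
#' @param alpha two-sided CI level.
#' @return the [genic_enrichment()] table with extra columns `se`, `lo`, `hi`.
#' @export
enrichment_spectrum <- function(snps, bin, n_bins = 10L, alpha = 0.05) {
  if (!all(c("genic", "block") %in% names(snps)))
    stop("snps needs 'genic' and 'block' columns")
  spec <- genic_enrichment(bin, snps$genic, n_bins)
  bb <- block_bin_counts(bin, snps$genic, snps$block, n_bins)
  z <- stats::qnorm(1 - alpha / 2)
  spec[, `:=`(se = NA_real_, lo = NA_real_, hi = NA_real_)]
  for (b in seq_len(n_bins)) {
    if (spec$total_n[b] == 0L) next
    loo <- loo_enrichment(bb, b)
    jk <- suppressWarnings(
      busing_jackknife(spec$enrichment[b], loo$theta_j, loo$m_j,
                       alpha = alpha))
    spec[b, `:=`(se = jk$se, lo = jk$ci[1], hi = jk$ci[2])]
  }
  spec
}

#' Tail asymmetry of a delta enrichment spectrum
#'
#' The log2 ratio `L = log2(e_bin10 / e_bin1)` of the two tail-bin genic
#' enrichments, with a weighted block-jackknife CI and a two-sided z-test of
#' `L = 0`. Under symmetric drift the two tails are equally enriched and L
#' is centred on zero; population-specific selection inflates one tail.
#'
#' @param snps a [snp_table()] with `genic` and `block` columns.
#' @param pop1,pop2 the population pair (`delta = DAF(pop1) - DAF(pop2)`;
#'   bin 10 is the pop1-elevated tail).
#' @param alpha two-sided CI level.
#' @return list with `pair`, `L`, `se`, `ci`, `p`, `enrichment` (tails),
#'   `pseudovalues` (leave-one-block-out L values, for outlier comparisons),
#'   and the jackknife metadata.
#' @export
tail_asymmetry <- function(snps, pop1, pop2, alpha = 0.05) {
  bin <- bin_delta(delta(snps, pop1, pop2))
  tail_asymmetry_bins(snps, bin, pair = c(pop1, pop2), alpha = alpha,
                      hi_bin = 10L, lo_bin = 1L)
}

# shared tail log2-ratio jackknife on a precomputed binning
tail_asymmetry_bins <- function(snps, bin, pair, alpha = 0.05,
                                hi_bin = 10L, lo_bin = 1L) {
  n_bins <- max(hi_bin, lo_bin)
  spec <- genic_enrichment(bin, snps$genic, n_bins)
  e_hi <- spec$enrichment[hi_bin]
  e_lo <- spec$enrichment[lo_bin]
  if (!isTRUE(e_hi > 0) || !isTRUE(e_lo > 0))
    stop("tail enrichment zero or undefined (hi = ", e_hi, ", lo = ", e_lo,
         "); cannot form log2 ratio")
  bb <- block_bin_counts(bin, snps$genic, snps$block, n_bins)
  hi <- loo_enrichment(bb, hi_bin)
  lo <- loo_enrichment(bb, lo_bin)
  stopifnot(identical(hi$block, lo$block))
  L <- log2(e_hi / e_lo)
  theta_j <- log2(hi$theta_j / lo$theta_j)
  jk <- suppressWarnings(
    busing_jackknife(L, theta_j, hi$m_j, alpha = alpha))
  p <- 2 * stats::pnorm(-abs(L / jk$se))
  list(pair = pair, L = L, se = jk$se, ci = jk$ci, p = p,
       enrichment = c(hi = e_hi, lo = e_lo),
       pseudovalues = jk$pseudovalues, g = jk$g, n = jk$n)
}

#' Tail asymmetry across all population pairs, Bonferroni-corrected
#'
#' @param snps a [snp_table()] with `genic` and `block` columns.
#' @param alpha two-sided CI level.
#' @return a `data.table` with one row per unordered pair: `pop1`, `pop2`,
#'   `L`, `se`, `lo`, `hi`, `p`, `p_bonferroni`.
#' @export
delta_asymmetry_all_pairs <- function(snps, alpha = 0.05) {
  pops <- pops_of(snps)
  prs <- utils::combn(pops, 2)
  res <- lapply(seq_len(ncol(prs)), function(k) {
    a <- tail_asymmetry(snps, prs[1, k], prs[2, k], alpha = alpha)
    data.table::data.table(pop1 = prs[1, k], pop2 = prs[2, k], L = a$L,
                           se = a$se, lo = a$ci[1], hi = a$ci[2], p = a$p)
  })
  out <- data.table::rbindlist(res)
  out[, p_bonferroni := pmin(1, p * ncol(prs))]
  out
}

#' Two-sided Kolmogorov-Smirnov comparison of pseudovalue sets
#'
#' Compares two distributions of leave-one-block-out log2 tail-ratio values,
#' e.g. to ask whether one population pair's asymmetry is an outlier against
#' another's.
#'
#' @param a,b numeric vectors (jackknife pseudovalues).
#' @return the two-sided KS p-value.
#' @export
ks_outlier_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty pseudovalue set")
  if (length(a) < 2L || length(b) < 2L)
    warning("KS test on a single pseudovalue is degenerate")
  suppressWarnings(stats::ks.test(a, b)$p.value)
}
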