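#' Hudson's Fst estimator for two populations
#'
#' The unbiased two-population estimator based on allele counts,
#' `[(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] / [p1(1-p2) + p2(1-p1)]`,
#' which (unlike the classical Weir-Cockerham estimator) is not biased by
#' unequal sample sizes. Values can be negative; the denominator is zero
#' (estimate undefined, `NA`) when both populations are fixed for the same
#' allele.
#'
#' @param dac1,n1 derived allele count and called haploid count, population 1
#'   (vectors).
#' @param dac2,n2 same for population 2.
#' @return numeric vector of Fst estimates (`NA` where undefined).
#' @export
hudson_fst <- function(dac1, n1, dac2, n2) {
  if (any(n1 <= 1L) || any(n2 <= 1L))
    stop("called haploid counts must exceed 1")
  p1 <- dac1 / n1
  p2 <- dac2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, NA_real_, num / den)
}

#' Transform Fst to drift time
#'
#' `T = -ln(1 - Fst)`. Negative estimates are clamped to 0 first (a distance
#' cannot be negative); fixed differences (`Fst = 1`, where the transform
#' diverges) are replaced by the largest observed non-unit Fst for the same
#' population pair, supplied as `replacement`.
#'
#' @param fst numeric vector of Fst values for one population pair.
#' @param replacement the pair's largest observed Fst strictly below 1
#'   (see [pair_replacement()]).
#' @return drift-time distances `T >= 0`.
#' @export
drift_distance <- function(fst, replacement) {
  if (!is.finite(replacement) || replacement >= 1)
    stop("replacement value must be finite and < 1")
  f <- pmax(fst, 0)
  f[fst >= 1] <- replacement
  -log(1 - f)
}

#' Largest observed non-unit Fst per pair
#'
#' Two-pass contract for the fixed-difference substitution in
#' [drift_distance()].
#'
#' @param fst numeric vector of per-SNP Fst for one pair.
#' @return the largest finite value strictly below 1.
#' @export
pair_replacement <- function(fst) {
  f <- fst[is.finite(fst) & fst < 1]
  if (!length(f)) stop("no Fst value below 1 observed for this pair")
  max(f)
}

#' Classical three-population branch statistic
#'
#' `PBS_A = (T_AB + T_AC - T_BC) / 2`: the length of A's external branch on
#' the unique unrooted 3-taxon tree. Serves as the analytic oracle for the
#' neighbor-joining branch lengths at K = 3.
#'
#' @param t_ab,t_ac,t_bc pairwise drift-time distances.
#' @return `PBS_A` (may be negative before clamping).
#' @export
pbs_three <- function(t_ab, t_ac, t_bc) {
  (t_ab + t_ac - t_bc) / 2
}

#' Neighbor-joining external branch lengths
#'
#' Standard Saitou-Nei NJ on a K x K distance matrix, returning the terminal
#' (external) branch length of each taxon and, for K = 4, a topology code
#' (1: taxa 1+2 joined first against 3+4; 2: 1+3 | 2+4; 3: 1+4 | 2+3).
#' Join-selection ties break on the lowest taxon-index pair. For K = 3 the
#' result equals the three-point formula ([pbs_three()]); for additive
#' matrices the true external branches are recovered exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal and finite entries.
#' @return list with `branches` (named by rownames of `d` if present) and
#'   `topology`.
#' @export
nj_branch_lengths <- function(d) {
  d <- as.matrix(d)
  K <- nrow(d)
  if (K != ncol(d) || K < 3L) stop("d must be square with K >= 3")
  if (any(!is.finite(d))) stop("non-finite entry in distance matrix")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  flat <- d[lower.tri(d)]  # column-major lower triangle == combn pair order
  res <- .nj_batch_cpp(matrix(flat, nrow = 1), K)
  br <- drop(res$branches)
  names(br) <- rownames(d)
  list(branches = br, topology = res$topology[1])
}

#' Scale raw branch lengths to per-population 0-1 scores
#'
#' Negative branch lengths are clamped to 0, then each population's branches
#' are divided by that population's maximum clamped value, so scores are
#' comparable between populations with different drift histories.
#'
#' @param raw numeric matrix, SNPs x populations, of raw external branch
#'   lengths.
#' @param method `"max"` (default), `"minmax"`, or `"rank"` (fraction of the
#'   population's SNPs with a smaller value).
#' @return matrix of scores in `[0, 1]`.
#' @export
scale_scores <- function(raw, method = c("max", "minmax", "rank")) {
  method <- match.arg(method)
  x <- pmax(raw, 0)
  out <- x
  for (k in seq_len(ncol(x))) {
    v <- x[, k]
    if (method == "max") {
      mx <- max(v)
      if (mx == 0) {
        warning("all clamped branch lengths are 0 for population ", k)
        out[, k] <- 0
      } else out[, k] <- v / mx
    } else if (method == "minmax") {
      rng <- range(v)
      out[, k] <- if (diff(rng) == 0) 0 else (v - rng[1]) / diff(rng)
    } else {
      out[, k] <- (rank(v, ties.method = "average") - 1) / (length(v) - 1)
    }
  }
  out
}

#' Per-SNP multi-population branch statistic scan (PBSnj)
#'
#' For every SNP: pairwise Hudson Fst across all populations, transformed to
#' drift time `T = -ln(1 - Fst)` (fixed differences substituted per pair),
#' neighbor-joining on the distance matrix, and the external branch length
#' read off per population; finally per-population 0-1 scaling. Generalizes
#' the classical 3-population PBS to K >= 3 without fixing a tree topology.
#'
#' @param snps a [snp_table()]; monomorphic SNPs (Fst undefined for every
#'   pair) are dropped and counted. Pairs that are undefined at a SNP (both
#'   populations fixed for the same allele) contribute distance 0.
#' @param populations populations to scan (default: all panel populations;
#'   at least 3).
#' @param scale_method passed to [scale_scores()].
#' @return a `data.table` with the SNP coordinates (plus `genic`/`block`
#'   when present), `raw_<pop>` and `score_<pop>` columns, and a `topology`
#'   code; attributes `replacement` (per-pair substitution values),
#'   `n_dropped` (monomorphic SNPs removed), and `populations`.
#' @export
pbsnj_scan <- function(snps, populations = NULL,
                       scale_method = c("max", "minmax", "rank")) {
  pops <- pops_of(snps)
  if (is.null(populations)) populations <- pops
  if (!all(populations %in% pops))
    stop("unknown population(s): ",
         paste(setdiff(populations, pops), collapse = ", "))
  K <- length(populations)
  if (K < 3L) stop("PBSnj needs at least 3 populations")
  prs <- utils::combn(K, 2)
  npair <- ncol(prs)

  fst <- matrix(NA_real_, nrow(snps), npair)
  for (m in seq_len(npair)) {
    a <- populations[prs[1, m]]
    b <- populations[prs[2, m]]
    fst[, m] <- hudson_fst(snps[[paste0("dac_", a)]], snps[[paste0("n_", a)]],
                           snps[[paste0("dac_", b)]], snps[[paste0("n_", b)]])
  }
  # monomorphic across all scanned populations: undefined everywhere
  all_na <- rowSums(is.na(fst)) == npair
  n_drop <- sum(all_na)
  keep <- which(!all_na)
  fst <- fst[keep, , drop = FALSE]

  repl <- numeric(npair)
  dmat <- matrix(0, nrow(fst), npair)
  for (m in seq_len(npair)) {
    repl[m] <- pair_replacement(fst[, m])
    f <- fst[, m]
    f[is.na(f)] <- 0  # both fixed for the same allele: no differentiation
    dmat[, m] <- drift_distance(f, repl[m])
  }
  res <- .nj_batch_cpp(dmat, K)
  raw <- res$branches
  score <- scale_scores(raw, method = scale_method)

  keep_cols <- intersect(c("chrom", "pos", "anc", "der", "genic", "block",
                           "rate"), names(snps))
  out <- snps[keep, keep_cols, with = FALSE]
  for (k in seq_len(K)) {
    out[, (paste0("raw_", populations[k])) := raw[, k]]
    out[, (paste0("score_", populations[k])) := score[, k]]
  }
  out[, topology := res$topology]
  names(repl) <- apply(prs, 2, function(ij)
    paste(populations[ij], collapse = "-"))
  data.table::setattr(out, "replacement", repl)
  data.table::setattr(out, "n_dropped", n_drop)
  data.table::setattr(out, "populations", populations)
  out
}

# score bins of width 0.2 on [0,1]; bin 5 (scores >= 0.8) is the tail
pbsnj_bins <- function(score) {
  b <- findInterval(score, c(0, 0.2, 0.4, 0.6, 0.8), left.open = FALSE)
  as.integer(pmin(b, 5L))
}

#' Genic enrichment spectrum of PBSnj scores for one population
#'
#' Scores are binned in widths of 0.2 (the top bin, scores >= 0.8, is the
#' selection-candidate tail) and the genic enrichment per bin is computed
#' with weighted block-jackknife CIs.
#'
#' @param scores result of [pbsnj_scan()] (needs `genic` and `block`).
#' @param pop population name.
#' @param alpha two-sided CI level.
#' @return an [enrichment_spectrum()] table with 5 bins.
#' @export
pbsnj_enrichment <- function(scores, pop, alpha = 0.05) {
  sc <- scores[[paste0("score_", pop)]]
  if (is.null(sc)) stop("no scores for population ", pop)
  enrichment_spectrum(scores, pbsnj_bins(sc), n_bins = 5L, alpha = alpha)
}

#' Log2 ratio of two populations' PBSnj tail genic enrichments
#'
#' Tests whether one population's selection-candidate tail (scores >= 0.8)
#' is more genic than another's, with a weighted block-jackknife CI and
#' z-test (the multi-population analogue of the delta tail asymmetry).
#'
#' @param scores result of [pbsnj_scan()] (needs `genic` and `block`).
#' @param pop1,pop2 population names; `L = log2(e_tail(pop1) / e_tail(pop2))`.
#' @param alpha two-sided CI level.
#' @return list as in [tail_asymmetry()].
#' @export
pbsnj_tail_asymmetry <- function(scores, pop1, pop2, alpha = 0.05) {
  t1 <- scores[[paste0("score_", pop1)]] >= 0.8
  t2 <- scores[[paste0("score_", pop2)]] >= 0.8
  genic <- scores$genic
  block <- scores$block
  e_of <- function(tl, g, n_tot, g_tot) (sum(g & tl) / sum(tl)) /
    (g_tot / n_tot)
  g_tot <- sum(genic); n_tot <- length(genic)
  e1 <- e_of(t1, genic, n_tot, g_tot)
  e2 <- e_of(t2, genic, n_tot, g_tot)
  if (!isTRUE(e1 > 0) || !isTRUE(e2 > 0))
    stop("tail enrichment zero or undefined; cannot form log2 ratio")
  L <- log2(e1 / e2)
  # leave-one-block-out, vectorized on per-block counts
  dt <- data.table::data.table(block = block, genic = genic,
                               t1 = t1, t2 = t2)
  bc <- dt[, .(m = .N, g = sum(genic),
               t1n = sum(t1), t1g = sum(t1 & genic),
               t2n = sum(t2), t2g = sum(t2 & genic)), by = block]
  et1 <- ((sum(bc$t1g) - bc$t1g) / (sum(bc$t1n) - bc$t1n)) /
    ((g_tot - bc$g) / (n_tot - bc$m))
  et2 <- ((sum(bc$t2g) - bc$t2g) / (sum(bc$t2n) - bc$t2n)) /
    ((g_tot - bc$g) / (n_tot - bc$m))
  theta_j <- log2(et1 / et2)
  jk <- suppressWarnings(busing_jackknife(L, theta_j, bc$m, alpha = alpha))
  p <- 2 * stats::pnorm(-abs(L / jk$se))
  list(pair = c(pop1, pop2), L = L, se = jk$se, ci = jk$ci, p = p,
       enrichment = c(hi = e1, lo = e2), pseudovalues = jk$pseudovalues,
       g = jk$g, n = jk$n)
}
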