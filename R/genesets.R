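#' Resampling empirical p-value
#'
#' `p = (1 + #{resamples at least as extreme as observed}) / (1 + n)`.
#' Adding 1 to numerator and denominator keeps p strictly positive: a zero
#' would be a downward-biased estimate under finite resampling.
#'
#' @param observed observed statistic (scalar).
#' @param resampled numeric vector of resampled statistics.
#' @param direction `"ge"` (enrichment: resample >= observed is extreme) or
#'   `"le"` (depletion).
#' @return empirical p in `(0, 1]`.
#' @export
empirical_p <- function(observed, resampled, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (!length(resampled)) stop("need at least one resample")
  hits <- if (direction == "ge") sum(resampled >= observed)
          else sum(resampled <= observed)
  (1 + hits) / (1 + length(resampled))
}

#' Read gene sets (GMT or two-column TSV)
#'
#' @param path a `.gmt` file (set, description, genes...) or a two-column
#'   `set<TAB>gene` file.
#' @param min_size sets with fewer genes are dropped (default 3), with a
#'   message.
#' @return named list of character vectors (gene ids per set).
#' @export
read_gene_sets <- function(path, min_size = 3L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  if (all(lengths(fields) >= 3L) && tolower(tools::file_ext(path)) == "gmt") {
    sets <- lapply(fields, function(x) unique(x[-(1:2)]))
    names(sets) <- vapply(fields, `[[`, character(1), 1L)
  } else {
    dt <- data.table::data.table(set = vapply(fields, `[[`, character(1), 1),
                                 gene = vapply(fields, `[[`, character(1), 2))
    sets <- split(dt$gene, dt$set)
    sets <- lapply(sets, unique)
  }
  small <- lengths(sets) < min_size
  if (any(small))
    message(sum(small), " gene set(s) below the minimum size of ", min_size,
            " dropped")
  sets[!small]
}

#' Map SNPs to genes
#'
#' A SNP maps to every gene whose padded span contains it (a SNP inside
#' overlapping genes counts toward all of them).
#'
#' @param snps a [snp_table()] (or any table with `chrom`, `pos`).
#' @param genes gene annotation ([read_genes()]).
#' @param pad flank in bp added to each gene span (default 2000, matching
#'   the genic definition).
#' @return a `data.table` with `snp` (row index into `snps`) and `gene`.
#' @export
snp_gene_map <- function(snps, genes, pad = 2000L) {
  ggr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(1L, genes$start - pad),
                                  genes$end + pad))
  sgr <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(snps$pos, width = 1L))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(sgr, ggr))
  data.table::data.table(snp = S4Vectors::queryHits(ov),
                         gene = genes$gene[S4Vectors::subjectHits(ov)])
}

#' Category enrichment of a candidate SNP set by resampling
#'
#' For each categorical label (e.g. a regulatory-confidence class), compares
#' the label's proportion among candidate SNPs with its distribution in
#' size-matched random draws from the background. Both one-sided empirical
#' p-values are reported.
#'
#' @param candidate integer indices of candidate SNPs (subset of
#'   `background`).
#' @param background integer indices of background SNPs.
#' @param category character/factor label per SNP (indexed by the same ids;
#'   `NA` = unlabelled, ignored in proportions).
#' @param n_resamples number of random draws (default 1000).
#' @param seed RNG seed.
#' @return a `data.table` with `category`, `observed` (proportion),
#'   `expected` (mean resampled proportion), `p_greater`, `p_less`.
#' @export
snp_category_test <- function(candidate, background, category,
                              n_resamples = 1000L, seed = 1L) {
  if (!all(candidate %in% background))
    stop("candidate SNPs must be a subset of the background")
  if (length(candidate) > length(background))
    stop("candidate set larger than background")
  set.seed(seed)
  cats <- sort(unique(stats::na.omit(category[background])))
  prop <- function(idx) {
    lab <- category[idx]
    lab <- lab[!is.na(lab)]
    vapply(cats, function(cc) mean(lab == cc), numeric(1))
  }
  obs <- prop(candidate)
  draws <- matrix(0, n_resamples, length(cats))
  for (r in seq_len(n_resamples))
    draws[r, ] <- prop(sample(background, length(candidate)))
  data.table::data.table(
    category = cats,
    observed = obs,
    expected = colMeans(draws),
    p_greater = vapply(seq_along(cats), function(j)
      empirical_p(obs[j], draws[, j], "ge"), numeric(1)),
    p_less = vapply(seq_along(cats), function(j)
      empirical_p(obs[j], draws[, j], "le"), numeric(1)))
}

#' Gene-mode resampling enrichment (GOWINDA-style)
#'
#' Tests gene sets for enrichment among the genes hit by candidate SNPs,
#' correcting for gene length and gene clustering: each resample draws
#' background SNPs (without replacement) until the number of distinct genes
#' hit matches the candidate gene count, so long genes that soak up SNPs are
#' equally favoured in the null draws. The background universe is restricted
#' to SNPs inside genes that belong to at least one set.
#'
#' @param candidate integer indices of candidate SNPs.
#' @param background integer indices of background SNPs (candidates must be
#'   a subset).
#' @param gene_map SNP-to-gene map ([snp_gene_map()]) covering both sets.
#' @param sets named list of gene-id vectors ([read_gene_sets()]).
#' @param n_resamples number of resamples (default 1000).
#' @param seed RNG seed.
#' @return a `data.table` with per-set `observed` (genes hit), `expected`
#'   (mean resampled), `p` (empirical, enrichment direction) and `fdr`
#'   ([resampling_fdr()]); attribute `pseudo_p` (resamples x sets matrix).
#' @export
gene_mode_resample <- function(candidate, background, gene_map, sets,
                               n_resamples = 1000L, seed = 1L) {
  if (!all(candidate %in% background))
    stop("candidate SNPs must be a subset of the background")
  set.seed(seed)
  set_genes <- unique(unlist(sets, use.names = FALSE))
  gm <- gene_map[gene_map$gene %in% set_genes]
  # universe: background SNPs inside >= 1 set gene
  snp_genes <- split(gm$gene, gm$snp)
  universe <- intersect(background, as.integer(names(snp_genes)))
  cand <- intersect(candidate, universe)
  genes_of <- function(idx)
    unique(unlist(snp_genes[as.character(idx)], use.names = FALSE))
  cand_genes <- genes_of(cand)
  target_n <- length(cand_genes)
  if (target_n == 0L) stop("no candidate SNP hits any set gene")
  n_universe_genes <- length(unique(gm$gene[gm$snp %in% universe]))
  if (target_n > n_universe_genes)
    stop("candidate gene count unattainable from the background universe")

  count_hits <- function(genes)
    vapply(sets, function(s) sum(genes %in% s), integer(1))
  observed <- count_hits(cand_genes)

  draws <- matrix(0L, n_resamples, length(sets),
                  dimnames = list(NULL, names(sets)))
  for (r in seq_len(n_resamples)) {
    perm <- sample(universe)
    hit <- character(0)
    i <- 0L
    # draw SNPs without replacement until the distinct-gene count matches
    while (length(hit) < target_n && i < length(perm)) {
      i <- i + 1L
      hit <- union(hit, snp_genes[[as.character(perm[i])]])
    }
    draws[r, ] <- count_hits(hit)
  }
  p <- vapply(seq_along(sets), function(j)
    empirical_p(observed[j], draws[, j], "ge"), numeric(1))
  # pseudo p-values: each resample scored against the resample distribution
  pseudo <- apply(draws, 2, function(col) {
    (1 + (length(col) - rank(col, ties.method = "min") + 1)) /
      (1 + length(col))
  })
  fdr <- resampling_fdr(p, pseudo)
  out <- data.table::data.table(set = names(sets), observed = observed,
                                expected = colMeans(draws), p = p, fdr = fdr)
  data.table::setattr(out, "pseudo_p", pseudo)
  out
}

#' Resampling false discovery rate
#'
#' For each observed p-value `p`, `FDR(p) = R_exp(p) / R_obs(p)` where
#' `R_obs` is the number of observed p-values `<= p` and `R_exp` the mean
#' per-resample count of pseudo p-values `<= p`; capped at 1. (Expected
#' false positives over observed positives - the only orientation that
#' yields a rate in `[0, 1]`.)
#'
#' @param p_obs numeric vector of observed empirical p-values.
#' @param pseudo matrix of pseudo p-values, resamples x tests, computed by
#'   the same procedure as `p_obs`.
#' @return numeric vector of FDR values aligned with `p_obs`.
#' @export
resampling_fdr <- function(p_obs, pseudo) {
  vapply(p_obs, function(p) {
    r_obs <- sum(p_obs <= p)
    if (r_obs == 0L) stop("R_obs is zero")  # unreachable: p <= p always
    r_exp <- mean(rowSums(pseudo <= p))
    min(1, r_exp / r_obs)
  }, numeric(1))
}

#' SNP-count-weighted gene resampling
#'
#' Tests the overlap of a candidate gene set with a target gene list by
#' drawing size-matched gene sets with probability proportional to each
#' gene's share of SNPs (correcting for gene length bias: long genes collect
#' outlier SNPs more easily). Supports a family of tests (one per
#' population) with a family-level resampling FDR in which the expected
#' counts are summed over the family.
#'
#' @param candidates named list (by population) of candidate gene-id vectors.
#' @param weights named numeric vector: per-gene SNP-count weights over the
#'   whole gene universe (will be normalised to sum to 1).
#' @param target character vector: the a priori gene list tested for
#'   overlap.
#' @param n_resamples number of resamples (default 1000).
#' @param seed RNG seed.
#' @return a `data.table` with per-population `observed` overlap, `expected`,
#'   `p` (empirical) and `fdr` (family-level).
#' @export
weighted_gene_resample <- function(candidates, weights, target,
                                   n_resamples = 1000L, seed = 1L) {
  set.seed(seed)
  genes <- names(weights)
  if (is.null(genes)) stop("weights must be named by gene id")
  w <- weights / sum(weights)
  npop <- length(candidates)
  obs <- integer(npop)
  draws <- matrix(0L, n_resamples, npop,
                  dimnames = list(NULL, names(candidates)))
  for (k in seq_len(npop)) {
    cg <- intersect(candidates[[k]], genes)
    if (length(cg) > length(genes)) stop("matched size exceeds universe")
    obs[k] <- sum(cg %in% target)
    for (r in seq_len(n_resamples)) {
      rs <- sample(genes, length(cg), prob = w)
      draws[r, k] <- sum(rs %in% target)
    }
  }
  p <- vapply(seq_len(npop), function(k)
    empirical_p(obs[k], draws[, k], "ge"), numeric(1))
  pseudo <- apply(draws, 2, function(col)
    (1 + (length(col) - rank(col, ties.method = "min") + 1)) /
      (1 + length(col)))
  # family FDR: R_exp summed over the populations
  fdr <- vapply(p, function(pp) {
    r_obs <- sum(p <= pp)
    r_exp <- sum(colMeans(pseudo <= pp))
    min(1, r_exp / r_obs)
  }, numeric(1))
  data.table::data.table(population = names(candidates), observed = obs,
                         expected = colMeans(draws), p = p, fdr = fdr)
}

#' Exact two-sided binomial overlap test
#'
#' Tests `k` successes in `n` trials against success probability `p0`,
#' two-sided by the minimum-likelihood method (the sum of all outcome
#' probabilities no larger than that of `k`).
#'
#' @param k,n successes and trials.
#' @param p0 null success probability.
#' @return the two-sided p-value.
#' @export
binomial_overlap_test <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (n == 0L) return(1)
  if (p0 == 0) return(if (k == 0) 1 else 0)
  if (p0 == 1) return(if (k == n) 1 else 0)
  stats::binom.test(k, n, p0, alternative = "two.sided")$p.value
}

#' Remove one population's tail SNPs lying in a gene set
#'
#' The counterfactual device for asking how much of a population's tail
#' genic enrichment is carried by a candidate gene set: the target
#' population's tail SNPs inside the set's genes are removed (other
#' populations' tails untouched), and downstream enrichment is recomputed on
#' what remains.
#'
#' @param scores result of [pbsnj_scan()].
#' @param gene_map SNP-to-gene map over `scores` rows ([snp_gene_map()]).
#' @param set character vector of gene ids.
#' @param pop target population.
#' @return `scores` without the removed rows.
#' @export
remove_geneset_snps <- function(scores, gene_map, set, pop) {
  if (!length(set)) return(scores)
  tail_col <- scores[[paste0("score_", pop)]] >= 0.8
  in_set <- unique(gene_map$snp[gene_map$gene %in% set])
  drop <- which(tail_col & seq_len(nrow(scores)) %in% in_set)
  if (!length(drop)) return(scores)
  out <- scores[-drop]
  for (a in c("replacement", "n_dropped", "populations"))
    data.table::setattr(out, a, attr(scores, a))
  out
}
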