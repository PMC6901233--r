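#' Rank genomic blocks by their tail SNP content
#'
#' Orders 200 kb blocks by the number of tail (outlier) genic SNPs they
#' carry (or by total tail SNPs), descending; ties break on the
#' lexicographically lowest block id for determinism.
#'
#' @param scores a table with `genic` and `block` columns (e.g.
#'   [pbsnj_scan()] output).
#' @param tail logical vector: tail membership per SNP.
#' @param ordering `"genic"` (default; gives a monotonically non-increasing
#'   enrichment trajectory under removal) or `"total"`.
#' @return a `data.table` with `block`, `tail_genic`, `tail_total`, `rank`,
#'   ordered for removal; attribute `ordering`.
#' @export
rank_blocks <- function(scores, tail, ordering = c("genic", "total")) {
  ordering <- match.arg(ordering)
  if (!any(tail)) stop("empty tail: nothing to rank")
  dt <- data.table::data.table(block = scores$block, genic = scores$genic,
                               tail = tail)
  bc <- dt[, .(tail_genic = sum(tail & genic), tail_total = sum(tail)),
           by = block]
  key <- if (ordering == "genic") bc$tail_genic else bc$tail_total
  ord <- order(-key, bc$block)
  out <- bc[ord]
  out[, rank := .I]
  data.table::setattr(out, "ordering", ordering)
  out
}

# standard recomputer: tail genic enrichment of `pop` after excluding blocks.
# mode "block" deletes all SNPs of a removed block (numerator and
# denominator both shrink); mode "tail-only" deletes only its tail SNPs.
#' Build a tail-enrichment recomputer for block removal
#'
#' @param scores [pbsnj_scan()] output (needs `genic`, `block`).
#' @param pop focal population.
#' @param mode `"block"` (remove all SNPs of a removed block, the default)
#'   or `"tail-only"` (remove only its tail SNPs).
#' @return a function `f(excluded_block_ids) -> tail genic enrichment`,
#'   with the per-block count table in attribute `counts`.
#' @export
tail_enrichment_recomputer <- function(scores, pop,
                                       mode = c("block", "tail-only")) {
  mode <- match.arg(mode)
  tail <- scores[[paste0("score_", pop)]] >= 0.8
  dt <- data.table::data.table(block = scores$block, genic = scores$genic,
                               tail = tail)
  bc <- dt[, .(m = .N, g = sum(genic), tn = sum(tail),
               tg = sum(tail & genic)), by = block]
  tot <- bc[, .(m = sum(m), g = sum(g), tn = sum(tn), tg = sum(tg))]
  f <- function(excluded) {
    ex <- bc[bc$block %in% excluded]
    if (mode == "block") {
      tg <- tot$tg - sum(ex$tg); tn <- tot$tn - sum(ex$tn)
      g <- tot$g - sum(ex$g); m <- tot$m - sum(ex$m)
    } else {
      tg <- tot$tg - sum(ex$tg); tn <- tot$tn - sum(ex$tn)
      g <- tot$g - sum(ex$tg); m <- tot$m - sum(ex$tn)
    }
    if (tn == 0L || g == 0L) return(NA_real_)
    (tg / tn) / (g / m)
  }
  attr(f, "counts") <- bc
  attr(f, "mode") <- mode
  f
}

#' Estimate the number of sweep blocks behind an excess enrichment
#'
#' Walks the ranked block list, removing one block at a time and recomputing
#' the focal population's tail genic enrichment, until it falls below a
#' threshold (typically another population's point estimate or upper 95%
#' confidence limit). The number of removals is a lower-bound-style estimate
#' of how many discrete genomic regions (putative sweeps) carry the excess.
#'
#' @param ranking a [rank_blocks()] table.
#' @param recompute a recomputer from [tail_enrichment_recomputer()] (any
#'   function of a vector of excluded block ids returning the enrichment).
#' @param threshold stop when enrichment < `threshold`.
#' @return list with `k` (blocks removed), `reached` (logical; FALSE when
#'   the threshold was never reached and all blocks were removed),
#'   `trajectory` (enrichment after 0..k removals).
#' @export
estimate_sweep_number <- function(ranking, recompute, threshold) {
  if (!nrow(ranking)) stop("empty ranking")
  traj <- numeric(nrow(ranking) + 1L)
  traj[1] <- recompute(character(0))
  if (is.finite(traj[1]) && traj[1] < threshold)
    return(list(k = 0L, reached = TRUE, trajectory = traj[1]))
  for (k in seq_len(nrow(ranking))) {
    traj[k + 1L] <- recompute(ranking$block[seq_len(k)])
    if (is.finite(traj[k + 1L]) && traj[k + 1L] < threshold)
      return(list(k = k, reached = TRUE, trajectory = traj[seq_len(k + 1L)]))
  }
  list(k = nrow(ranking), reached = FALSE, trajectory = traj)
}

#' Random removal-order baseline for the sweep count
#'
#' Shuffles the block removal order and records how many random removals are
#' needed to reach the threshold; a ranked removal reaching it much sooner
#' than the shuffled median indicates the excess is concentrated in few
#' blocks.
#'
#' @param ranking a [rank_blocks()] table (defines the block universe).
#' @param recompute as in [estimate_sweep_number()].
#' @param threshold as in [estimate_sweep_number()].
#' @param n_shuffles number of random orders (default 100).
#' @param seed RNG seed.
#' @return list with `k` (vector of per-shuffle counts), `median`,
#'   `quantiles` (5%, 25%, 75%, 95%).
#' @export
shuffle_baseline <- function(ranking, recompute, threshold,
                             n_shuffles = 100L, seed = 1L) {
  set.seed(seed)
  ks <- integer(n_shuffles)
  blocks <- ranking$block
  bc <- attr(recompute, "counts")
  for (s in seq_len(n_shuffles)) {
    ord <- sample(blocks)
    if (!is.null(bc)) {
      # vectorized trajectory from cumulative per-block counts
      b <- bc[match(ord, bc$block)]
      tail_only <- identical(attr(recompute, "mode"), "tail-only")
      tg <- sum(bc$tg) - c(0, cumsum(b$tg))
      tn <- sum(bc$tn) - c(0, cumsum(b$tn))
      g <- sum(bc$g) - c(0, cumsum(if (tail_only) b$tg else b$g))
      m <- sum(bc$m) - c(0, cumsum(if (tail_only) b$tn else b$m))
      e <- (tg / tn) / (g / m)
      below <- which(is.finite(e) & e < threshold)
      ks[s] <- if (length(below)) below[1] - 1L else length(blocks)
      next
    }
    k <- length(blocks)
    e0 <- recompute(character(0))
    if (is.finite(e0) && e0 < threshold) { ks[s] <- 0L; next }
    for (j in seq_along(ord)) {
      e <- recompute(ord[seq_len(j)])
      if (is.finite(e) && e < threshold) { k <- j; break }
    }
    ks[s] <- k
  }
  qs <- if (n_shuffles > 1L)
    stats::quantile(ks, c(0.05, 0.25, 0.75, 0.95)) else NULL
  list(k = ks, median = stats::median(ks), quantiles = qs)
}
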