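test_that("Hudson Fst matches hand-evaluated cases", {
  # fixed difference
  expect_equal(hudson_fst(10, 10, 0, 10), 1)
  # symmetric intermediate frequencies go negative (unbiased estimator)
  expect_equal(hudson_fst(5, 10, 5, 10), -1 / 9, tolerance = 1e-12)
  # unequal sample sizes: 0.3338 / 0.68
  num <- 0.36 - 0.8 * 0.2 / 19 - 0.2 * 0.8 / 9
  expect_equal(hudson_fst(16, 20, 2, 10), num / 0.68, tolerance = 1e-12)
  expect_equal(round(hudson_fst(16, 20, 2, 10), 4), 0.4909)
  # both fixed for the same allele: undefined
  expect_true(is.na(hudson_fst(0, 10, 0, 10)))
  expect_error(hudson_fst(1, 1, 0, 10), "exceed 1")
})

test_that("drift transform clamps, replaces fixed differences, errors", {
  expect_equal(drift_distance(0, 0.9), 0)
  expect_equal(drift_distance(0.5, 0.9), -log(0.5))
  expect_equal(drift_distance(1, 0.98), -log(0.02))
  expect_equal(drift_distance(-0.2, 0.9), 0)  # negative clamped
  expect_error(drift_distance(0.5, 1), "< 1")
  expect_equal(pair_replacement(c(0.2, 1, 0.98, NA)), 0.98)
  expect_error(pair_replacement(c(1, 1)), "below 1")
})

test_that("three-population branch formula", {
  expect_equal(pbs_three(0.4, 0.6, 0.8), 0.1)
  expect_equal(pbs_three(0.3, 0.3, 0.3), 0.15)
  expect_equal(pbs_three(0.1, 0.1, 0.4), -0.1)
})

test_that("NJ external branches equal the analytic 3-taxon formula", {
  set.seed(42)
  for (i in 1:10000) {
    f <- runif(3, 0, 0.98)
    tt <- -log(1 - f)
    d <- matrix(0, 3, 3)
    d[1, 2] <- d[2, 1] <- tt[1]
    d[1, 3] <- d[3, 1] <- tt[2]
    d[2, 3] <- d[3, 2] <- tt[3]
    br <- nj_branch_lengths(d)$branches
    expect_true(abs(br[1] - pbs_three(tt[1], tt[2], tt[3])) < 1e-9)
    expect_true(abs(br[2] - pbs_three(tt[1], tt[3], tt[2])) < 1e-9)
    expect_true(abs(br[3] - pbs_three(tt[2], tt[3], tt[1])) < 1e-9)
  }
})

test_that("NJ recovers external branches of random additive 4-taxon trees", {
  set.seed(7)
  for (i in 1:200) {
    ext <- runif(4, 0.1, 2)
    internal <- runif(1, 0.05, 1)
    # topology (1,2)|(3,4)
    d <- matrix(0, 4, 4)
    d[1, 2] <- ext[1] + ext[2]
    d[1, 3] <- ext[1] + internal + ext[3]
    d[1, 4] <- ext[1] + internal + ext[4]
    d[2, 3] <- ext[2] + internal + ext[3]
    d[2, 4] <- ext[2] + internal + ext[4]
    d[3, 4] <- ext[3] + ext[4]
    d <- d + t(d)
    res <- nj_branch_lengths(d)
    expect_true(max(abs(res$branches - ext)) < 1e-9)
    expect_equal(res$topology, 1L)
  }
  # all distances equal -> all external branches equal
  d <- matrix(1, 4, 4); diag(d) <- 0
  expect_equal(max(abs(diff(nj_branch_lengths(d)$branches))), 0)
  expect_error(nj_branch_lengths(matrix(c(0, 1, 2, 0), 2, 2)), "K >= 3")
  dd <- matrix(1, 4, 4); diag(dd) <- 0; dd[1, 2] <- Inf; dd[2, 1] <- Inf
  expect_error(nj_branch_lengths(dd), "finite")
})

test_that("NJ agrees with the ape reference implementation on 5 taxa", {
  skip_if_not_installed("ape")
  set.seed(11)
  for (i in 1:50) {
    p <- matrix(runif(10 * 5), 10, 5)
    d <- as.matrix(stats::dist(t(p))) / 3
    rownames(d) <- colnames(d) <- paste0("t", 1:5)
    br <- nj_branch_lengths(d)$branches
    tr <- ape::nj(as.dist(d))
    tip_edges <- match(seq_len(5), tr$edge[, 2])
    ape_br <- tr$edge.length[tip_edges]
    names(ape_br) <- tr$tip.label
    expect_equal(unname(br[tr$tip.label]), unname(ape_br), tolerance = 1e-8)
  }
})

test_that("score scaling clamps negatives and hits [0, 1]", {
  raw <- matrix(c(-0.2, 0, 1.5, 3.0), 4, 1)
  expect_equal(as.numeric(scale_scores(raw)), c(0, 0, 0.5, 1.0))
  expect_equal(as.numeric(scale_scores(matrix(2.5, 1, 1))), 1)
  expect_equal(as.numeric(scale_scores(matrix(rep(3, 4), 4, 1))), rep(1, 4))
  expect_warning(z <- scale_scores(matrix(c(-1, -2), 2, 1)), "all clamped")
  expect_equal(as.numeric(z), c(0, 0))
  r <- as.numeric(scale_scores(matrix(c(5, 1, 3), 3, 1), method = "rank"))
  expect_equal(r, c(1, 0, 0.5))
})

test_that("K=3 scan equals the classical PBS pipeline SNP by SNP", {
  spec <- strong_drift_spec(n_snps = 3000L)
  snps <- make_fixture(spec, seed = 51)
  pops <- c("eastern", "central", "western")
  sc <- pbsnj_scan(snps, populations = pops)
  # classical: pairwise Fst -> T -> three-point formula, same substitutions
  f12 <- hudson_fst(snps$dac_eastern, snps$n_eastern,
                    snps$dac_central, snps$n_central)
  f13 <- hudson_fst(snps$dac_eastern, snps$n_eastern,
                    snps$dac_western, snps$n_western)
  f23 <- hudson_fst(snps$dac_central, snps$n_central,
                    snps$dac_western, snps$n_western)
  keep <- !(is.na(f12) & is.na(f13) & is.na(f23))
  tfun <- function(f) {
    r <- pair_replacement(f)
    f[is.na(f)] <- 0
    drift_distance(f, r)
  }
  t12 <- tfun(f12[keep]); t13 <- tfun(f13[keep]); t23 <- tfun(f23[keep])
  pbs_e <- pbs_three(t12, t13, t23)
  expect_equal(nrow(sc), sum(keep))
  expect_true(max(abs(sc$raw_eastern - pbs_e)) < 1e-9)
})

test_that("permuting the population list permutes the scores", {
  spec <- strong_drift_spec(n_snps = 2000L)
  snps <- make_fixture(spec, seed = 61)
  a <- pbsnj_scan(snps)
  b <- pbsnj_scan(snps, populations = c("western", "central",
                                        "nigeria_cameroon", "eastern"))
  expect_equal(a$raw_eastern, b$raw_eastern)
  expect_equal(a$score_western, b$score_western)
})

test_that("default fixture: planted sweeps land in the target tail only", {
  snps <- make_fixture(synth_spec(), seed = 101)
  truth <- attr(snps, "sweeps")
  sc <- pbsnj_scan(snps)
  idx <- match(paste(truth$chrom, truth$pos), paste(sc$chrom, sc$pos))
  recovery <- mean(sc$score_eastern[idx] >= 0.8, na.rm = TRUE)
  expect_gte(recovery, 0.9)
  # target tail genic enrichment CI excludes 1
  sp <- suppressWarnings(pbsnj_enrichment(sc, "eastern"))
  expect_gt(sp$lo[5], 1)
  # S11-style tail targeting: derived alleles high in the target population
  # only
  tl <- which(sc$score_eastern >= 0.8)
  sidx <- match(paste(sc$chrom, sc$pos)[tl], paste(snps$chrom, snps$pos))
  expect_gt(mean(daf(snps, "eastern")[sidx]), 0.8)
  for (p in c("central", "nigeria_cameroon", "western"))
    expect_lt(mean(daf(snps, p)[sidx]), 0.3)
  # specificity: no non-target population shows significant tail genic
  # enrichment (a zero-genic micro-tail may sit below 1; what must not
  # happen is a spurious positive signal)
  for (p in c("central", "nigeria_cameroon", "western")) {
    spo <- suppressWarnings(pbsnj_enrichment(sc, p))
    expect_lte(spo$lo[5], 1)
  }
  # tail asymmetry between target and a non-target is positive (the
  # non-target tail is tiny, so its jackknife error dominates the CI) and
  # antisymmetric under swapping
  ta <- suppressWarnings(pbsnj_tail_asymmetry(sc, "eastern", "central"))
  expect_gt(ta$L, 0)
  tb <- suppressWarnings(pbsnj_tail_asymmetry(sc, "central", "eastern"))
  expect_equal(tb$L, -ta$L, tolerance = 1e-12)
})

test_that("monomorphic SNPs are dropped and counted", {
  snps <- hand_snp_table(c(0, 3), 6, c(0, 2), 6)
  dt <- data.table::copy(snps)
  dt[, `:=`(dac_C = c(0L, 1L), n_C = 6L)]
  snps3 <- snp_table(dt, c("A", "B", "C"))
  sc <- suppressWarnings(pbsnj_scan(snps3))
  expect_equal(nrow(sc), 1L)
  expect_equal(attr(sc, "n_dropped"), 1L)
})
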