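test_that("empirical p follows the add-one rule and never hits zero", {
  expect_equal(empirical_p(100, rep(1, 999), "ge"), 1 / 1000)
  expect_equal(empirical_p(0, rep(1, 999), "ge"), 1)
  expect_equal(empirical_p(10, c(rep(11, 49), rep(1, 950)), "ge"), 0.05)
  # monotone in the observed value
  rs <- stats::rnorm(500)
  obs <- seq(-3, 3, length.out = 20)
  ps <- vapply(obs, empirical_p, numeric(1), resampled = rs,
               direction = "ge")
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0))
  expect_error(empirical_p(1, numeric(0)), "at least one")
})

test_that("gene set readers handle GMT and TSV with the size filter", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3\tg4",
               "tiny\tdesc\tg1\tg2",
               "setB\tdesc\tg5\tg6\tg7"), gmt)
  expect_message(sets <- read_gene_sets(gmt), "below the minimum")
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3", "g4"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("s1\tg1", "s1\tg2", "s1\tg3", "s2\tg9"), tsv)
  sets2 <- suppressMessages(read_gene_sets(tsv))
  expect_equal(sets2, list(s1 = c("g1", "g2", "g3")))
})

test_that("snp_category_test is calibrated under the null and finds signal", {
  set.seed(5)
  n <- 2000
  category <- sample(c("hi", "lo"), n, replace = TRUE, prob = c(0.1, 0.9))
  background <- seq_len(n)
  # null: random candidate subsets -> p rarely extreme
  ok <- 0L
  for (r in 1:40) {
    cand <- sample(background, 100)
    res <- snp_category_test(cand, background, category,
                             n_resamples = 200L, seed = r)
    if (all(res$p_greater > 0.01)) ok <- ok + 1L
  }
  expect_gte(ok, 36L)
  # extreme planted case: candidates all category "hi"
  cand <- which(category == "hi")[1:100]
  res <- snp_category_test(cand, background, category,
                           n_resamples = 500L, seed = 1)
  expect_equal(res$p_greater[res$category == "hi"], 1 / 501)
  # planted 2x excess is detected in most replicates
  hit <- 0L
  for (r in 1:20) {
    set.seed(100 + r)
    cand <- c(sample(which(category == "hi"), 40),
              sample(which(category == "lo"), 160))
    res <- snp_category_test(cand, background, category,
                             n_resamples = 500L, seed = r)
    if (res$p_greater[res$category == "hi"] < 0.01) hit <- hit + 1L
  }
  expect_gte(hit, 18L)
  expect_error(snp_category_test(c(1, 9999), background, category),
               "subset")
})

test_that("gene-mode resampling: degenerate and extreme sets behave", {
  # universe: 60 genes, one SNP each; sets: all genes / a 10-gene set
  genes <- sprintf("g%02d", 1:60)
  gm <- data.table::data.table(snp = 1:60, gene = genes)
  sets <- list(all = genes, ten = genes[1:10])
  cand <- 1:10  # candidate SNPs hit exactly the 10-gene set
  res <- gene_mode_resample(cand, 1:60, gm, sets, n_resamples = 300L,
                            seed = 2)
  # the all-gene set device: p = 1 by construction
  expect_equal(res$p[res$set == "all"], 1)
  # hypergeometric probability of re-drawing all 10 is ~ 1e-11
  expect_equal(res$p[res$set == "ten"], 1 / 301)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
})

test_that("gene-mode resampling is seed-reproducible and order-invariant", {
  set.seed(9)
  genes <- sprintf("g%02d", 1:50)
  gm <- data.table::data.table(snp = rep(1:200, lengths = 1),
                               gene = sample(genes, 200, replace = TRUE))
  sets <- list(s1 = genes[1:12], s2 = genes[13:30])
  cand <- sample(1:200, 30)
  a <- gene_mode_resample(cand, 1:200, gm, sets, n_resamples = 100L,
                          seed = 4)
  b <- gene_mode_resample(rev(cand), 1:200, gm, sets, n_resamples = 100L,
                          seed = 4)
  expect_equal(a$p, b$p)
  expect_equal(a$expected, b$expected)
})

test_that("null gene sets yield no FDR-significant hits", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:300)
  gm <- data.table::data.table(snp = 1:900,
                               gene = rep(genes, each = 3))
  n_sig <- 0L
  for (r in 1:10) {
    sets <- lapply(1:8, function(i) sample(genes, 15))
    names(sets) <- paste0("s", 1:8)
    cand <- sample(1:900, 60)
    res <- gene_mode_resample(cand, 1:900, gm, sets, n_resamples = 200L,
                              seed = r)
    n_sig <- n_sig + sum(res$fdr < 0.1 & res$p < 0.05)
  }
  expect_lte(n_sig, 2L)
})

test_that("resampling FDR follows the expected/observed definition", {
  # 5 observed p's at 0.01; pseudo matrix with mean 0.5 sets <= 0.01
  p_obs <- rep(0.01, 5)
  pseudo <- matrix(1, nrow = 10, ncol = 5)
  pseudo[1:5, 1] <- 0.005  # 5 of 10 resamples have one pseudo-p <= 0.01
  fdr <- resampling_fdr(p_obs, pseudo)
  expect_equal(fdr, rep(0.5 / 5, 5))
  # observed distribution equal to pseudo distribution -> FDR ~ 1
  set.seed(2)
  pp <- matrix(runif(2000), 100, 20)
  po <- runif(20)
  f <- resampling_fdr(po, pp)
  expect_gt(mean(f), 0.7)
  expect_true(all(f <= 1))
})

test_that("weighted resampling with uniform weights matches hypergeometric", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:200)
  target <- genes[1:40]
  cand_genes <- c(genes[1:12], genes[101:118])  # overlap 12, size 30
  w <- stats::setNames(rep(1, 200), genes)
  res <- weighted_gene_resample(list(popA = cand_genes), w, target,
                                n_resamples = 4000L, seed = 3)
  # closed-form: P(X >= 12), X ~ Hypergeometric(40 of 200, draws 30)
  p_exact <- stats::phyper(11, 40, 160, 30, lower.tail = FALSE)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p - p_exact), 4 * mc_se + 1e-3)
  expect_equal(res$observed, 12L)
})

test_that("weight concentration drives the draws", {
  w <- c(big = 0.99, stats::setNames(rep(0.01 / 99, 99),
                                     sprintf("g%02d", 1:99)))
  res <- weighted_gene_resample(list(p1 = "big"), w, target = "big",
                                n_resamples = 1000L, seed = 8)
  expect_gt(res$expected, 0.95)
})

test_that("binomial overlap test matches printed and analytic cases", {
  expect_equal(round(binomial_overlap_test(3, 8, 0.13), 2), 0.07)
  expect_equal(binomial_overlap_test(0, 10, 0), 1)
  expect_equal(binomial_overlap_test(8, 8, 0.13), 0.13^8,
               tolerance = 1e-10)
  # symmetry at p0 = 0.5
  for (k in 0:6)
    expect_equal(binomial_overlap_test(k, 6, 0.5),
                 binomial_overlap_test(6 - k, 6, 0.5))
})

test_that("gene-set SNP removal hits the target population's tail only", {
  snps <- make_fixture(synth_spec(n_snps = 50000L, sweep_n = 20L),
                       seed = 301)
  sc <- pbsnj_scan(snps)
  genes <- attr(snps, "genes")
  gm <- snp_gene_map(sc, genes)
  # the gene set holding all eastern tail SNPs
  tail_idx <- which(sc$score_eastern >= 0.8)
  set_all <- unique(gm$gene[gm$snp %in% tail_idx])
  out <- remove_geneset_snps(sc, gm, set_all, "eastern")
  in_set <- unique(gm$snp[gm$gene %in% set_all])
  removed <- sum(seq_len(nrow(sc)) %in% in_set &
                   sc$score_eastern >= 0.8)
  expect_equal(nrow(out), nrow(sc) - removed)
  # every genic tail SNP lies in a set gene, so the remaining tail is
  # entirely non-genic
  expect_false(any(out$genic[out$score_eastern >= 0.8]))
  # other populations' tails untouched
  expect_equal(sum(out$score_central >= 0.8), sum(sc$score_central >= 0.8))
  # empty set: identity
  expect_equal(nrow(remove_geneset_snps(sc, gm, character(0), "eastern")),
               nrow(sc))
})
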