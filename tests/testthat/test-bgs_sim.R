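test_that("the packaged chimpanzee model parses to the expected structure", {
  m <- chimp_model()
  expect_equal(m$theta, 0.96048)
  expect_equal(m$sample_sizes, c(0L, 38L, 36L, 20L, 22L))
  expect_equal(m$pop_names[2], "eastern")
  expect_equal(m$init_sizes[3], 0.3092)
  expect_equal(m$init_mig[3, 2], 2.02290154800773)
  joins <- m$events[m$events$type == "join", ]
  expect_equal(joins$time, c(0.106325, 0.2675, 0.482625, 1.6008))
  expect_equal(joins$i, c(2L, 5L, 4L, 1L))
})

test_that("population rescaling multiplies all epoch sizes by the ratio", {
  m <- demographic_model(c(10L, 10L), theta = 1,
                         init_sizes = c(1, 2),
                         events = data.frame(time = 0.5, type = "size",
                                             i = 1L, j = 0L, x = 0.3))
  r <- rescale_population(m, 1, 3.66914400056, 4.3158739382)
  expect_equal(r$init_sizes[1] * 10000, 8501.5, tolerance = 1e-4)
  expect_equal(r$events$x, 0.3 * 3.66914400056 / 4.3158739382)
  expect_equal(r$init_sizes[2], 2)
  ident <- rescale_population(m, 1, 1, 1)
  expect_equal(ident$init_sizes, m$init_sizes)
  # present-size variant of the grafting arithmetic
  expect_equal(10000 * 0.3092 / 0.30865, 10017.8, tolerance = 1e-4)
  expect_error(rescale_population(m, "zz", 1, 1), "unknown")
  expect_error(rescale_population(m, 1, 1, 0), "positive")
})

test_that("split-time adjustment follows the Fst ratio", {
  expect_equal(adjust_split_time(0.258, 0.25, 250), 250)
  expect_equal(adjust_split_time(0.3, 0.25, 250), (0.3 - 0.008) / 0.25 * 250)
  expect_equal(adjust_split_time(0.5, 0.25, 100, correction = 0), 200)
  expect_error(adjust_split_time(0.001, 0.25, 250), "non-positive")
})

test_that("B shifting caps at one and tracks the mean", {
  s <- shift_b(c(0.7, 0.95), 0.1)
  expect_equal(as.numeric(s), c(0.8, 1))
  expect_equal(attr(s, "mean_b"), 0.9)
  expect_equal(as.numeric(shift_b(c(0.5, 0.9), 0)), c(0.5, 0.9))
  # effective genic B: ratio of mean genic to mean non-genic B
  expect_equal(round(0.75 / 0.85, 2), 0.88)
})

test_that("apply_b scales the chosen populations only", {
  m <- chimp_model()
  b <- apply_b(m, c(1, 0.825, 0.9, 0.9, 0.9))
  expect_equal(b$init_sizes[2], m$init_sizes[2] * 0.825)
  expect_equal(b$init_sizes[1], m$init_sizes[1])
  sel <- m$events$type == "size" & m$events$i == 2
  expect_equal(b$events$x[sel], m$events$x[sel] * 0.825)
  expect_equal(apply_b(m, 1)$init_sizes, m$init_sizes)
  expect_error(apply_b(m, 0), "in \\(0, 1\\]")
  expect_error(apply_b(m, c(1, 1)), "scalar or one value")
})

test_that("segregating sites match Watterson's expectation", {
  m <- demographic_model(20L, theta = 0.96)
  n_loci <- 10000
  sim <- simulate_loci(m, n_loci, seed = 7)
  s_mean <- nrow(sim) / n_loci
  expected <- 0.96 * sum(1 / (1:19))
  # Var(S) = theta*a1 + theta^2*a2 per locus
  se <- sqrt((0.96 * sum(1 / (1:19)) + 0.96^2 * sum(1 / (1:19)^2)) / n_loci)
  expect_lt(abs(s_mean - expected), 3 * se)
  expect_equal(nrow(simulate_loci(m, 0, seed = 1)), 0L)
})

test_that("diversity scales linearly with B", {
  m <- demographic_model(20L, theta = 0.96)
  div <- function(sim) {
    p <- sim$dac_pop1 / sim$n_pop1
    n <- sim$n_pop1
    sum(2 * p * (1 - p) * n / (n - 1))
  }
  base <- simulate_loci(m, 10000, genic_fraction = 1, b_genic = 1, seed = 11)
  for (B in c(0.5, 0.8, 0.9)) {
    sb <- simulate_loci(apply_b(m, B), 10000, genic_fraction = 1,
                        b_genic = 1, seed = 11)
    expect_lt(abs(div(sb) / div(base) / B - 1), 0.02)
  }
})

test_that("island-model Fst matches the exact two-deme closed form", {
  # symmetric 2-deme island, M = 4*N0*m = 1; from mean coalescence times
  # Tw = 1 and Tb = 1 + 1/(2M) (in 4*N0 generations): Fst = 1/(1 + 2M) = 1/3
  m <- demographic_model(c(10L, 10L), theta = 1,
                         init_mig = matrix(c(0, 1, 1, 0), 2, 2))
  sim <- simulate_loci(m, 30000, seed = 3)
  fst <- model_fst_check(sim_to_snp_table(sim))$fst
  expect_equal(fst, 1 / 3, tolerance = 0.03)
  # panmictic null: strong migration erases structure
  mp <- demographic_model(c(10L, 10L), theta = 1,
                          init_mig = matrix(c(0, 500, 500, 0), 2, 2))
  fst0 <- model_fst_check(sim_to_snp_table(simulate_loci(mp, 5000,
                                                         seed = 5)))$fst
  expect_lt(abs(fst0), 0.02)
  # two isolated populations at long divergence: Fst near 1
  iso <- demographic_model(c(10L, 10L), theta = 1,
                           events = data.frame(time = 20, type = "join",
                                               i = 2L, j = 1L, x = 0))
  fst1 <- model_fst_check(sim_to_snp_table(simulate_loci(iso, 2000,
                                                         seed = 9)))$fst
  expect_gt(fst1, 0.9)
})

test_that("neutral SFS is proportional to 1/i", {
  m <- demographic_model(20L, theta = 0.96)
  sim <- simulate_loci(m, 20000, seed = 13)
  s <- sfs(sim_to_snp_table(sim), "pop1")
  expect_equal(sum(s$prop), 1)
  expected <- (1 / s$count) / sum(1 / s$count)
  expect_lt(max(abs(s$prop - expected)), 0.01)
  # single SNP: indicator spectrum
  one <- hand_snp_table(3, 20, 1, 20)
  s1 <- sfs(one, "A")
  expect_equal(s1$prop[3], 1)
  expect_error(sfs(one[0], "A"), "empty")
})

test_that("simulation output is deterministic given the seed", {
  m <- chimp_model()
  a <- simulate_loci(m, 500, seed = 99)
  b <- simulate_loci(m, 500, seed = 99)
  expect_identical(a, b)
  c <- simulate_loci(m, 500, seed = 100)
  expect_false(identical(a, c))
})

test_that("fit_b recovers the generating B from a self-built library", {
  m <- chimp_model()
  spectra <- function(st) {
    pops <- attr(st, "populations")
    prs <- utils::combn(pops, 2)
    out <- list()
    for (k in seq_len(ncol(prs))) {
      bin <- bin_delta(delta(st, prs[1, k], prs[2, k]))
      out[[paste(prs[, k], collapse = "-")]] <-
        genic_enrichment(bin, st$genic)
    }
    out
  }
  mk <- function(b, seed, n = 60000) {
    sim <- simulate_loci(m, n, genic_fraction = 0.5,
                         b_genic = c(1, b, b, b, b), b_nongenic = 1,
                         seed = seed)
    spectra(sim_to_snp_table(sim))
  }
  obs <- mk(0.9, seed = 2001)
  lib <- list("0.85" = mk(0.85, seed = 3001),
              "0.90" = mk(0.90, seed = 3001),
              "0.95" = mk(0.95, seed = 3001))
  for (bins in c("all", "no-tails", "tails-only")) {
    fit <- fit_b(obs, lib, bins = bins)
    expect_equal(fit$best_b, 0.9, info = bins)
  }
  # SSD is invariant to pair order
  fit1 <- fit_b(obs, lib)
  fit2 <- fit_b(obs[rev(names(obs))], lib)
  expect_equal(fit1$ssd$ssd, fit2$ssd$ssd)
  expect_warning(fit_b(obs, lib["0.90"]), "single")
})

test_that("uniform-B simulation shows no strong delta tail asymmetry", {
  # demography alone (identical B across populations) leaves the
  # eastern-central log2 tail ratio consistent with values far below the
  # large asymmetry seen only under population-specific selection
  m <- chimp_model()
  sim <- simulate_loci(m, 100000, genic_fraction = 0.5,
                       b_genic = c(1, 0.9, 0.9, 0.9, 0.9), b_nongenic = 1,
                       seed = 71)
  st <- sim_to_snp_table(sim)
  ta <- suppressWarnings(tail_asymmetry(st, "eastern", "central"))
  expect_lt(ta$L, 0.41)
  expect_lt(ta$ci[1], 0.15)
})

test_that("halving a population's Ne does not raise its tail enrichment", {
  m <- chimp_model()
  tail_e <- function(model, seed) {
    sim <- simulate_loci(model, 100000, genic_fraction = 0.5,
                         b_genic = c(1, 0.9, 0.9, 0.9, 0.9),
                         b_nongenic = 1, seed = seed)
    sc <- pbsnj_scan(sim_to_snp_table(sim))
    suppressWarnings(pbsnj_enrichment(sc, "eastern"))$enrichment[5]
  }
  for (s in c(5001, 5002)) {
    base <- tail_e(m, s)
    halved <- tail_e(rescale_population(m, "eastern", 0.5, 1), s)
    expect_lt(halved, base)
  }
})

test_that("unsupported ms flags and missing pieces are rejected", {
  expect_error(parse_msms("prog 10 1 -t 1 -G 5"), "unsupported")
  expect_error(parse_msms("prog 10 1 -I 2 5 5"), "missing -t")
  expect_error(parse_msms("prog 10 1 -t 1"), "missing -I")
})
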