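#' Demographic model for the structured-coalescent simulator
#'
#' Time is measured pastwards in units of `4*N0` generations, population
#' sizes relative to a reference size `N0`, and migration rates as
#' `M = 4*N0*m` (ms convention). Events are applied in time order.
#'
#' @param sample_sizes integer haploid sample sizes per population.
#' @param theta per-locus scaled mutation rate `4*N0*mu*L`.
#' @param init_sizes relative population sizes at sampling time (default 1).
#' @param init_mig migration matrix `M[i, j]` (backwards rate from i to j;
#'   default 0).
#' @param events data.frame with columns `time`, `type` (`"size"`, `"mig"`,
#'   `"join"`), `i`, `j`, `x`; may be empty. `join` moves population `i`'s
#'   lineages into `j` and zeroes migration involving `i`.
#' @param pop_names optional population names.
#' @param rho per-locus scaled recombination rate (stored for provenance;
#'   the bundled single-locus engine does not recombine).
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(sample_sizes, theta, init_sizes = NULL,
                              init_mig = NULL, events = NULL,
                              pop_names = NULL, rho = 0) {
  k <- length(sample_sizes)
  if (is.null(init_sizes)) init_sizes <- rep(1, k)
  if (is.null(init_mig)) init_mig <- matrix(0, k, k)
  if (is.null(events))
    events <- data.frame(time = numeric(), type = character(),
                         i = integer(), j = integer(), x = numeric())
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(k))
  stopifnot(length(init_sizes) == k, nrow(init_mig) == k, ncol(init_mig) == k,
            length(pop_names) == k)
  if (any(init_sizes <= 0)) stop("population sizes must be positive")
  if (theta <= 0) stop("theta must be positive")
  events <- events[order(events$time), , drop = FALSE]
  structure(list(sample_sizes = as.integer(sample_sizes), theta = theta,
                 rho = rho, init_sizes = as.numeric(init_sizes),
                 init_mig = init_mig, events = events,
                 pop_names = as.character(pop_names)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model:", length(x$pop_names), "populations (",
      paste(x$pop_names, collapse = ", "), "), theta =", x$theta,
      ",", nrow(x$events), "events\n")
  invisible(x)
}

pop_index <- function(model, population) {
  i <- if (is.character(population)) match(population, model$pop_names)
       else as.integer(population)
  if (any(is.na(i)) || any(i < 1L) || any(i > length(model$pop_names)))
    stop("unknown population: ", population)
  i
}

#' Parse an ms/msms command line into a demographic model
#'
#' Accepts the flags `-t`, `-r`, `-I`, `-n`, `-m`, `-en`, `-em`, `-ej` (the
#' vocabulary of the reference chimpanzee model command), so a published
#' command string becomes a packaged configuration rather than code.
#'
#' @param cmd the command string (leading `msms nsam nreps` tolerated).
#' @param pop_names optional population names in `-I` order.
#' @return a [demographic_model()].
#' @export
parse_msms <- function(cmd, pop_names = NULL) {
  tok <- strsplit(trimws(cmd), "\\s+")[[1]]
  # drop program name and the leading nsam/nreps positional arguments
  while (length(tok) && !startsWith(tok[1], "-")) tok <- tok[-1]
  theta <- NA_real_; rho <- 0
  sample_sizes <- NULL; k <- NA_integer_
  mig0 <- NULL
  sizes <- NULL
  ev <- list()
  i <- 1
  num <- function(x) suppressWarnings(as.numeric(x))
  while (i <= length(tok)) {
    f <- tok[i]
    if (f == "-t") { theta <- num(tok[i + 1]); i <- i + 2 }
    else if (f == "-r") { rho <- num(tok[i + 1]); i <- i + 3 }
    else if (f == "-I") {
      k <- as.integer(tok[i + 1])
      sample_sizes <- as.integer(tok[i + 1 + seq_len(k)])
      sizes <- rep(1, k)
      mig0 <- matrix(0, k, k)
      i <- i + 2 + k
      if (i <= length(tok) && !startsWith(tok[i], "-")) {
        # trailing symmetric migration value M: m_ij = M/(k-1)
        M <- num(tok[i]); i <- i + 1
        mig0[] <- M / (k - 1); diag(mig0) <- 0
      }
    }
    else if (f == "-n") {
      sizes[as.integer(tok[i + 1])] <- num(tok[i + 2]); i <- i + 3
    }
    else if (f == "-m") {
      mig0[as.integer(tok[i + 1]), as.integer(tok[i + 2])] <- num(tok[i + 3])
      i <- i + 4
    }
    else if (f == "-en") {
      ev[[length(ev) + 1]] <- data.frame(time = num(tok[i + 1]),
                                         type = "size",
                                         i = as.integer(tok[i + 2]), j = 0L,
                                         x = num(tok[i + 3]))
      i <- i + 4
    }
    else if (f == "-em") {
      ev[[length(ev) + 1]] <- data.frame(time = num(tok[i + 1]),
                                         type = "mig",
                                         i = as.integer(tok[i + 2]),
                                         j = as.integer(tok[i + 3]),
                                         x = num(tok[i + 4]))
      i <- i + 5
    }
    else if (f == "-ej") {
      ev[[length(ev) + 1]] <- data.frame(time = num(tok[i + 1]),
                                         type = "join",
                                         i = as.integer(tok[i + 2]),
                                         j = as.integer(tok[i + 3]), x = 0)
      i <- i + 4
    }
    else stop("unsupported ms flag: ", f)
  }
  if (is.na(theta)) stop("missing -t")
  if (is.null(sample_sizes)) stop("missing -I")
  demographic_model(sample_sizes, theta, sizes, mig0,
                    do.call(rbind, ev), pop_names, rho)
}

#' The merged four-subspecies chimpanzee reference model
#'
#' The packaged msms parameterisation of chimpanzee demographic history
#' (bonobo outgroup unsampled plus eastern, central, Nigeria-Cameroon and
#' western populations; 19/18/10/11 diploids; theta = 0.96048 and
#' rho = 0.768384 per 2 kb locus, i.e. mu = 1.2e-8 and r = 0.96e-8 with
#' N0 ~ 10,000), including the post-split migration pulses and the adjusted
#' western/Nigeria-Cameroon split.
#'
#' @return a [demographic_model()] with populations `bonobo`, `eastern`,
#'   `central`, `nigeria_cameroon`, `western`.
#' @export
chimp_model <- function() {
  parse_msms(chimp_msms_cmd(),
             pop_names = c("bonobo", "eastern", "central",
                           "nigeria_cameroon", "western"))
}

# the reference command string (one flag vocabulary; see parse_msms)
chimp_msms_cmd <- function() {
  paste(readLines(system.file("extdata", "chimp_model_msms.txt",
                              package = "pbsnj")), collapse = " ")
}

#' Rescale one population's sizes by a ratio
#'
#' Multiplies the population's initial size and every epoch size by
#' `numerator / denominator` (the "grafting" normalisation used when merging
#' two inferred models that share a reference population).
#'
#' @param model a [demographic_model()].
#' @param population name or index.
#' @param numerator,denominator the ratio; `denominator > 0`.
#' @return the rescaled model.
#' @export
rescale_population <- function(model, population, numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  i <- pop_index(model, population)
  r <- numerator / denominator
  model$init_sizes[i] <- model$init_sizes[i] * r
  sel <- model$events$type == "size" & model$events$i == i
  model$events$x[sel] <- model$events$x[sel] * r
  model
}

#' Adjust a split time by the observed/model Fst ratio
#'
#' `t = (fst_obs + correction) / fst_model * base_time`: scales a split time
#' so the model's pairwise Fst matches the observed value, after applying a
#' fixed correction for the average model-vs-observed offset.
#'
#' @param fst_obs observed pairwise Fst.
#' @param fst_model model-predicted Fst at `base_time`.
#' @param base_time the original split time (any unit).
#' @param correction additive adjustment to the observed Fst (default -0.008).
#' @return the adjusted split time.
#' @export
adjust_split_time <- function(fst_obs, fst_model, base_time,
                              correction = -0.008) {
  if (fst_model <= 0) stop("fst_model must be positive")
  t <- (fst_obs + correction) / fst_model * base_time
  if (t <= 0) stop("adjusted time is non-positive")
  t
}

#' Shift a B-value distribution by a constant
#'
#' Adds `constant` to every B value, capping at 1, so the genome-average B
#' can be swept over a grid (e.g. 0.88-0.93 in steps of 0.01) starting from
#' empirical genic/non-genic B distributions.
#'
#' @param b numeric vector of B values in `(0, 1]`.
#' @param constant the shift.
#' @return the shifted values, with attribute `mean_b`.
#' @export
shift_b <- function(b, constant) {
  out <- pmin(b + constant, 1)
  attr(out, "mean_b") <- mean(out)
  out
}

#' Apply background-selection scaling to a model
#'
#' Multiplies every population size (initial and epoch) of population `i` by
#' `B[i]`: a B value is the fractional reduction in effective population
#' size at a neutral site due to linked purifying selection, so scaling Ne
#' by B reproduces the expected diversity reduction.
#'
#' @param model a [demographic_model()].
#' @param B scalar (uniform across populations) or one value per population,
#'   each in `(0, 1]`.
#' @return the scaled model.
#' @export
apply_b <- function(model, B) {
  k <- length(model$sample_sizes)
  if (length(B) == 1L) B <- rep(B, k)
  if (length(B) != k) stop("B must be scalar or one value per population")
  if (any(B <= 0 | B > 1)) stop("B values must be in (0, 1]")
  for (i in seq_len(k)) {
    if (B[i] == 1) next
    model <- rescale_population(model, i, B[i], 1)
  }
  model
}

# events data.frame -> numeric matrix for the C++ engine
events_matrix <- function(model) {
  ev <- model$events
  if (!nrow(ev))
    return(matrix(numeric(), 0, 5))
  type <- match(ev$type, c("size", "mig", "join")) - 1L
  if (any(is.na(type))) stop("unknown event type")
  cbind(ev$time, type, ev$i, ev$j, ev$x)
}

#' Simulate independent loci under the structured coalescent
#'
#' Single-locus Hudson-style coalescent (no intra-locus recombination) with
#' the model's sizes, migration and events; mutations dropped at rate
#' `theta/2` per unit branch length (infinite sites). Each locus may carry a
#' class label (`genic`/`non-genic`) and its own per-population B multiplier.
#'
#' @param model a [demographic_model()].
#' @param n_loci number of independent loci.
#' @param genic_fraction probability a locus is genic (default 0.5; the
#'   enrichment ratio is invariant to this fraction in expectation).
#' @param b_genic a function `(n) -> n` B values for genic loci, a fixed
#'   scalar, or a fixed per-population vector (recycled per locus). Default 1
#'   (neutral).
#' @param b_nongenic same for non-genic loci (default 1, i.e. fully neutral
#'   flanking sequence).
#' @param seed integer seed (the engine has its own RNG stream; identical
#'   seed and configuration give identical output).
#' @return a `data.table` with `locus`, `genic`, `b` (mean multiplier used)
#'   and one `dac_<pop>` / `n_<pop>` pair per sampled population; attribute
#'   `populations` (sampled populations only), `sample_sizes`.
#' @export
simulate_loci <- function(model, n_loci, genic_fraction = 0.5,
                          b_genic = 1, b_nongenic = 1, seed = 1L) {
  stopifnot(n_loci >= 0)
  k <- length(model$sample_sizes)
  if (n_loci == 0) {
    out <- data.table::data.table(locus = integer(), genic = logical(),
                                  b = numeric())
    sampled <- which(model$sample_sizes > 0)
    for (i in sampled) {
      out[, (paste0("dac_", model$pop_names[i])) := integer()]
      out[, (paste0("n_", model$pop_names[i])) := integer()]
    }
    return(out)
  }
  set.seed(seed)
  genic <- stats::runif(n_loci) < genic_fraction
  draw_b <- function(fn, n) {
    if (is.function(fn)) {
      v <- fn(n)
      matrix(rep(v, each = 1), n, k)  # scalar-per-locus, uniform across pops
    } else if (length(fn) == 1L) {
      matrix(fn, n, k)
    } else if (length(fn) == k) {
      matrix(fn, n, k, byrow = TRUE)
    } else stop("B sampler must be a function, scalar, or per-population ",
                "vector")
  }
  bmat <- matrix(1, n_loci, k)
  if (any(genic)) bmat[genic, ] <- draw_b(b_genic, sum(genic))
  if (any(!genic)) bmat[!genic, ] <- draw_b(b_nongenic, sum(!genic))
  if (any(bmat <= 0 | bmat > 1)) stop("B values must be in (0, 1]")
  engine_seed <- sample.int(.Machine$integer.max, 1)
  res <- .sim_loci_cpp(model$theta, model$sample_sizes, model$init_sizes,
                       model$init_mig, events_matrix(model), bmat,
                       engine_seed)
  out <- data.table::data.table(locus = res$locus,
                                genic = genic[res$locus],
                                b = rowMeans(bmat)[res$locus])
  sampled <- which(model$sample_sizes > 0)
  for (idx in seq_along(sampled)) {
    i <- sampled[idx]
    out[, (paste0("dac_", model$pop_names[i])) := res$counts[, i]]
    out[, (paste0("n_", model$pop_names[i])) := model$sample_sizes[i]]
  }
  data.table::setattr(out, "populations", model$pop_names[sampled])
  data.table::setattr(out, "sample_sizes", model$sample_sizes[sampled])
  out
}

#' Convert simulated loci to a SNP table
#'
#' Lays simulated SNPs on a pseudo-genome (one locus = one block, since loci
#' are simulated independently) so the differentiation and PBSnj machinery
#' can run unchanged on simulated data.
#'
#' @param sim result of [simulate_loci()].
#' @return a [snp_table()] with `genic` and `block` columns.
#' @export
sim_to_snp_table <- function(sim) {
  pops <- attr(sim, "populations")
  dt <- data.table::copy(sim)
  dt[, `:=`(chrom = "sim", pos = seq_len(nrow(dt)),
            anc = "A", der = "G", block = paste0("L", locus))]
  dt[, c("locus", "b") := NULL]
  snp_table(dt, pops)
}

#' Pairwise mean Fst table for simulated (or observed) data
#'
#' Hudson estimator combined across SNPs as a ratio of averages (mean
#' numerator over mean denominator), the recommended genome-wide combination.
#'
#' @param snps a [snp_table()].
#' @return a `data.table` with `pop1`, `pop2`, `fst`.
#' @export
model_fst_check <- function(snps) {
  pops <- pops_of(snps)
  if (length(pops) < 2L) stop("need >= 2 populations")
  prs <- utils::combn(pops, 2)
  res <- lapply(seq_len(ncol(prs)), function(m) {
    a <- prs[1, m]; b <- prs[2, m]
    p1 <- daf(snps, a); n1 <- snps[[paste0("n_", a)]]
    p2 <- daf(snps, b); n2 <- snps[[paste0("n_", b)]]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    data.table::data.table(pop1 = a, pop2 = b,
                           fst = sum(num) / sum(den))
  })
  data.table::rbindlist(res)
}

#' Site frequency spectrum
#'
#' Proportion of SNPs at derived allele count `1..n-1` for one population
#' (SNPs monomorphic within the population are excluded).
#'
#' @param snps a [snp_table()].
#' @param pop population name.
#' @return a `data.table` with `count`, `prop` (sums to 1).
#' @export
sfs <- function(snps, pop) {
  if (!nrow(snps)) stop("empty SNP table")
  dac <- snps[[paste0("dac_", pop)]]
  n <- snps[[paste0("n_", pop)]][1]
  seg <- dac[dac > 0L & dac < n]
  if (!length(seg)) stop("no segregating sites in population ", pop)
  tab <- tabulate(seg, n - 1L)
  data.table::data.table(count = seq_len(n - 1L), prop = tab / sum(tab))
}

#' Fit the best background-selection strength by SSD
#'
#' Sum of squared differences between observed and simulated genic
#' enrichment spectra, summed over population pairs and over a chosen bin
#' subset; returns the library B minimising the SSD. Bins missing (empty) in
#' either spectrum are skipped symmetrically.
#'
#' @param observed named list (by pair label) of enrichment tables
#'   ([genic_enrichment()] output) for the observed data.
#' @param sim_library named list (by B value, e.g. `"0.9"`) of lists shaped
#'   like `observed`.
#' @param bins `"all"`, `"no-tails"` (exclude bins 1 and 10), or
#'   `"tails-only"` (bins 1 and 10 only, i.e. 12 tail bins across 6 pairs).
#' @param tail_bins indices of the tail bins (default `c(1, 10)`).
#' @return list with `best_b` (numeric), `ssd` (`data.table` of B vs SSD).
#' @export
fit_b <- function(observed, sim_library,
                  bins = c("all", "no-tails", "tails-only"),
                  tail_bins = c(1L, 10L)) {
  bins <- match.arg(bins)
  if (!length(sim_library)) stop("empty simulation library")
  if (length(sim_library) == 1L)
    warning("simulation library has a single B value")
  ssd_one <- function(simspec) {
    tot <- 0
    for (pair in names(observed)) {
      eo <- observed[[pair]]$enrichment
      es <- simspec[[pair]]$enrichment
      stopifnot(length(eo) == length(es))
      sel <- switch(bins,
                    "all" = seq_along(eo),
                    "no-tails" = setdiff(seq_along(eo), tail_bins),
                    "tails-only" = tail_bins)
      if (!length(sel)) stop("empty bin subset")
      ok <- sel[is.finite(eo[sel]) & is.finite(es[sel])]
      tot <- tot + sum((eo[ok] - es[ok])^2)
    }
    tot
  }
  tab <- data.table::data.table(
    b = as.numeric(names(sim_library)),
    ssd = vapply(sim_library, ssd_one, numeric(1)))
  data.table::setorderv(tab, "b")
  list(best_b = tab$b[which.min(tab$ssd)], ssd = tab)
}
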