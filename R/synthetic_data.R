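#' Specification for a synthetic multi-population dataset
#'
#' Defines the statistical structure the selection-scan machinery assumes:
#' several populations related by a nested split tree with per-branch drift
#' times (Balding-Nichols drift), genes laid out along chromosomes (genic =
#' within a padded gene span), non-overlapping 200 kb blocks with shared
#' block-level drift deviates (so the jackknife has real linkage-like
#' correlation to absorb), and optionally planted population-specific sweeps.
#'
#' Defaults mirror the study system the package was built around: four
#' populations with haploid sample sizes 38/36/20/22 and pairwise Fst
#' spanning roughly 0.09 (closest pair) to 0.3 (most distant pair). Planted
#' sweeps emulate completed hard sweeps: the derived allele is driven to
#' (near) fixation at a genic SNP where it is nearly absent elsewhere -
#' under per-population max-scaling, only such near-fixed differences can
#' reach the PBSnj selection tail.
#'
#' @param n_pops number of populations (the default tree is 4).
#' @param haploid_sizes haploid sample size per population.
#' @param pop_names population names.
#' @param drift per-branch drift times: list with `leaf` (per population)
#'   and `internal` (pair-ancestor branches) drift in coalescent-time units.
#' @param n_snps total SNP count.
#' @param n_chrom,chrom_length chromosomes and their length in bp.
#' @param block_length jackknife window length (bp).
#' @param gene_length,gene_spacing gene span and start-to-start spacing (bp);
#'   together with the 2 kb pad these set the genic fraction of the genome.
#' @param block_drift_shape shape of the Gamma(shape, shape) block-level
#'   drift multiplier (mean 1; smaller = stronger within-block correlation).
#' @param sweep_n number of planted sweeps (0 = null dataset).
#' @param sweep_pop target population (index).
#' @param sweep_range post-sweep derived-frequency range in the target
#'   population.
#' @param sweep_private_max candidate SNPs must have derived frequency at or
#'   below this in every non-target population.
#' @param sweep_span sweep footprint in bp: private variants within half a
#'   span of the focal SNP hitchhike to the swept frequency range.
#' @param root_range range of the Uniform root frequency.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_pops = 4L,
                       haploid_sizes = c(38L, 36L, 20L, 22L),
                       pop_names = c("eastern", "central",
                                     "nigeria_cameroon", "western"),
                       drift = list(leaf = c(0.10, 0.08, 0.16, 0.24),
                                    internal = c(0.12, 0.12)),
                       n_snps = 200000L,
                       n_chrom = 4L,
                       chrom_length = 12500000L,
                       block_length = 200000L,
                       gene_length = 6000L,
                       gene_spacing = 25000L,
                       block_drift_shape = 4,
                       sweep_n = 50L,
                       sweep_pop = 1L,
                       sweep_range = c(0.995, 1),
                       sweep_private_max = 0.02,
                       sweep_span = 50000L,
                       root_range = c(0.05, 0.95)) {
  stopifnot(n_pops == length(haploid_sizes), n_pops == length(pop_names),
            length(drift$leaf) == n_pops,
            all(drift$leaf >= 0), all(drift$internal >= 0),
            sweep_range[1] >= 0, sweep_range[2] <= 1,
            sweep_private_max >= 0, sweep_private_max <= 1)
  if (n_pops != 4L)
    stop("the bundled split tree is for 4 populations")
  structure(as.list(environment()), class = "synth_spec")
}

# Balding-Nichols drift: child frequency ~ Beta with mean p and variance
# p(1-p) * F, F = 1 - exp(-tau). Degenerate at p = 0 or 1 (stays fixed).
bn_drift <- function(p, tau) {
  n <- max(length(p), length(tau))
  p <- rep_len(p, n)
  F <- rep_len(1 - exp(-tau), n)  # tau may vary per SNP (block deviates)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  q <- suppressWarnings(stats::rbeta(n, a, b))
  q[F <= 0] <- p[F <= 0]
  q[p <= 0] <- 0
  q[p >= 1] <- 1
  q
}

#' Generate per-SNP per-population derived allele frequencies
#'
#' Frequencies evolve down the split tree `((pop1, pop2), (pop3, pop4))` by
#' Balding-Nichols drift from a Uniform root frequency. Each branch's drift
#' time is multiplied, per 200 kb block, by a shared Gamma(shape, shape)
#' deviate, giving SNPs within a block correlated departures (a frequency-
#' level emulation of linkage).
#'
#' @param spec a [synth_spec()].
#' @param seed RNG seed.
#' @return a `data.table` with `chrom`, `pos`, `genic`, `block` and one
#'   `p_<pop>` column per population; attributes `spec`, `genes`.
#' @export
generate_frequencies <- function(spec, seed = 1L) {
  set.seed(seed)
  # layout: genes at regular spacing, SNP positions uniform
  genes <- data.table::data.table(
    gene = character(), chrom = character(), start = integer(),
    end = integer(), strand = "+")
  layout <- vector("list", spec$n_chrom)
  per_chrom <- diff(round(seq(0, spec$n_snps, length.out = spec$n_chrom + 1)))
  for (c_i in seq_len(spec$n_chrom)) {
    ch <- paste0("chr", c_i)
    starts <- seq(10000L, spec$chrom_length - spec$gene_length,
                  by = spec$gene_spacing)
    genes <- rbind(genes, data.table::data.table(
      gene = sprintf("g%02d_%04d", c_i, seq_along(starts)), chrom = ch,
      start = as.integer(starts),
      end = as.integer(starts + spec$gene_length - 1L), strand = "+"))
    pos <- sort(sample.int(spec$chrom_length, per_chrom[c_i]))
    layout[[c_i]] <- data.table::data.table(chrom = ch, pos = pos)
  }
  dt <- data.table::rbindlist(layout)
  dt[, block := paste0(chrom, ":", (pos - 1L) %/% spec$block_length)]
  ivl <- genic_intervals(genes, 2000L)
  sgr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, width = 1L))
  dt[, genic := GenomicRanges::countOverlaps(sgr, ivl) > 0L]

  # block-shared drift multipliers, one per block per branch
  blocks <- unique(dt$block)
  bidx <- match(dt$block, blocks)
  nb <- length(blocks)
  sh <- spec$block_drift_shape
  bmul <- function() stats::rgamma(nb, shape = sh, rate = sh)[bidx]

  p0 <- stats::runif(nrow(dt), spec$root_range[1], spec$root_range[2])
  tl <- spec$drift$leaf
  ti <- spec$drift$internal
  p12 <- bn_drift(p0, ti[1] * bmul())
  p34 <- bn_drift(p0, ti[2] * bmul())
  dt[, (paste0("p_", spec$pop_names[1])) := bn_drift(p12, tl[1] * bmul())]
  dt[, (paste0("p_", spec$pop_names[2])) := bn_drift(p12, tl[2] * bmul())]
  dt[, (paste0("p_", spec$pop_names[3])) := bn_drift(p34, tl[3] * bmul())]
  dt[, (paste0("p_", spec$pop_names[4])) := bn_drift(p34, tl[4] * bmul())]
  data.table::setattr(dt, "spec", spec)
  data.table::setattr(dt, "genes", genes)
  dt
}

#' Plant population-specific sweeps
#'
#' Emulates completed hard sweeps on population-private variants. Each
#' sweep event picks a focal genic SNP whose derived allele is nearly
#' absent (frequency at or below `sweep_private_max`) in every non-target
#' population and drives the target population's frequency into
#' `sweep_range`. The sweep also carries its hitchhikers: every other
#' private variant within `sweep_span` of the focal SNP (genic or not)
#' rises to the same frequency range, mirroring how a real sweep drags
#' linked young variants into the differentiation tail. Other populations
#' are untouched.
#'
#' @param freqs output of [generate_frequencies()].
#' @param seed RNG seed.
#' @param genic_only require focal SNPs to be genic (default TRUE; FALSE
#'   supports specificity experiments).
#' @param hitchhikers drag private same-block variants along (default TRUE).
#' @return `freqs` with the target frequencies overwritten; attribute
#'   `sweeps` is the truth table of focal SNPs (`data.table`: `snp` row
#'   index, `chrom`, `pos`, `block`, `pop`, `freq`), attribute
#'   `sweep_hitchhikers` the row indices of dragged variants.
#' @export
plant_sweeps <- function(freqs, seed = 1L, genic_only = TRUE,
                         hitchhikers = TRUE) {
  spec <- attr(freqs, "spec")
  if (spec$sweep_n == 0L) {
    data.table::setattr(freqs, "sweeps",
                        data.table::data.table(snp = integer()))
    data.table::setattr(freqs, "sweep_hitchhikers", integer())
    return(freqs)
  }
  set.seed(seed)
  others <- setdiff(seq_len(spec$n_pops), spec$sweep_pop)
  pmax_others <- do.call(pmax, lapply(others, function(k)
    freqs[[paste0("p_", spec$pop_names[k])]]))
  private <- pmax_others <= spec$sweep_private_max
  ok <- private
  if (genic_only) ok <- ok & freqs$genic
  cand <- which(ok)
  if (length(cand) < spec$sweep_n)
    stop("only ", length(cand), " candidate SNPs for ", spec$sweep_n,
         " sweeps; increase n_snps or sweep_private_max")
  sw <- sort(sample(cand, spec$sweep_n))
  hh <- integer(0)
  if (hitchhikers) {
    half <- spec$sweep_span / 2
    near <- rep(FALSE, nrow(freqs))
    for (s in sw) {
      i <- which(freqs$chrom == freqs$chrom[s] &
                   abs(freqs$pos - freqs$pos[s]) <= half)
      near[i] <- TRUE
    }
    hh <- setdiff(which(private & near), sw)
  }
  tcol <- paste0("p_", spec$pop_names[spec$sweep_pop])
  newf <- stats::runif(spec$sweep_n, spec$sweep_range[1], spec$sweep_range[2])
  freqs[sw, (tcol) := newf]
  if (length(hh))
    freqs[hh, (tcol) := stats::runif(length(hh), spec$sweep_range[1],
                                     spec$sweep_range[2])]
  truth <- data.table::data.table(
    snp = sw, chrom = freqs$chrom[sw], pos = freqs$pos[sw],
    block = freqs$block[sw], pop = spec$pop_names[spec$sweep_pop],
    freq = newf)
  data.table::setattr(freqs, "sweeps", truth)
  data.table::setattr(freqs, "sweep_hitchhikers", hh)
  freqs
}

#' Draw sampled allele counts from frequencies
#'
#' Binomial sampling of haploid genomes per population; the in-memory
#' shortcut used throughout the test-suite (skips VCF emission).
#'
#' @param freqs output of [generate_frequencies()] / [plant_sweeps()].
#' @param seed RNG seed.
#' @return a [snp_table()] with `genic` and `block` columns; attributes
#'   `sweeps` and `genes` carried over.
#' @export
sample_counts <- function(freqs, seed = 1L) {
  set.seed(seed)
  spec <- attr(freqs, "spec")
  dt <- freqs[, c("chrom", "pos", "genic", "block")]
  dt[, `:=`(anc = "A", der = "G")]
  for (k in seq_len(spec$n_pops)) {
    p <- freqs[[paste0("p_", spec$pop_names[k])]]
    n <- spec$haploid_sizes[k]
    dt[, (paste0("dac_", spec$pop_names[k])) := stats::rbinom(.N, n, p)]
    dt[, (paste0("n_", spec$pop_names[k])) := as.integer(n)]
  }
  out <- snp_table(dt, spec$pop_names)
  data.table::setattr(out, "sweeps", attr(freqs, "sweeps"))
  data.table::setattr(out, "genes", attr(freqs, "genes"))
  out
}

#' Emit a synthetic dataset as standard files
#'
#' Draws diploid genotypes Binomial(2, p) per sample and writes a VCF (with
#' an `AA` INFO tag; a configurable fraction of records is emitted with
#' REF/ALT swapped so polarization is exercised), a sample panel, a gene BED,
#' a genetic map TSV, a GMT of random gene sets and the sweep truth table.
#' All files round-trip through the package's readers.
#'
#' @param freqs output of [generate_frequencies()] / [plant_sweeps()].
#' @param dir output directory (created).
#' @param seed RNG seed.
#' @param swap_fraction fraction of records written with the derived allele
#'   as REF (default 0.3).
#' @param n_sets,set_size gene sets written to the GMT.
#' @return named list of file paths, plus the emitted [snp_table()]
#'   (`$snps`) for round-trip comparison.
#' @export
emit_dataset <- function(freqs, dir, seed = 1L, swap_fraction = 0.3,
                         n_sets = 10L, set_size = 8L) {
  set.seed(seed)
  spec <- attr(freqs, "spec")
  genes <- attr(freqs, "genes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nsnp <- nrow(freqs)

  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, nsnp, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1), character(1))

  # per-sample genotypes
  samples <- unlist(lapply(seq_len(spec$n_pops), function(k)
    sprintf("%s_%02d", spec$pop_names[k], seq_len(spec$haploid_sizes[k] / 2))))
  pops <- rep(spec$pop_names, spec$haploid_sizes / 2)
  gt <- matrix("", nsnp, length(samples),
               dimnames = list(NULL, samples))
  dac <- matrix(0L, nsnp, spec$n_pops)
  col <- 0L
  for (k in seq_len(spec$n_pops)) {
    p <- freqs[[paste0("p_", spec$pop_names[k])]]
    for (s in seq_len(spec$haploid_sizes[k] / 2)) {
      col <- col + 1L
      g <- stats::rbinom(nsnp, 2L, p)
      gt[, col] <- c("0/0", "0/1", "1/1")[g + 1L]
      dac[, k] <- dac[, k] + g
    }
  }

  swap <- stats::runif(nsnp) < swap_fraction
  ref <- ifelse(swap, der, anc)
  alt <- ifelse(swap, anc, der)
  flip <- c("0/0" = "1/1", "0/1" = "0/1", "1/1" = "0/0")
  gt[swap, ] <- flip[gt[swap, ]]

  vcf <- file.path(dir, "synthetic.vcf")
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                   paste(samples, collapse = "\t")))
  body <- data.table::data.table(
    CHROM = freqs$chrom, POS = freqs$pos, ID = ".", REF = ref, ALT = alt,
    QUAL = ".", FILTER = "PASS", INFO = paste0("AA=", anc), FORMAT = "GT")
  body <- cbind(body, data.table::as.data.table(gt))
  writeLines(meta, vcf)
  data.table::fwrite(body, vcf, sep = "\t", append = TRUE, quote = FALSE,
                     col.names = FALSE)

  panel <- file.path(dir, "panel.tsv")
  utils::write.table(data.frame(samples, pops), panel, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  bed <- file.path(dir, "genes.bed")
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene, 0L,
               genes$strand),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  # genetic map: markers every 100 kb, lognormal local rates
  mapf <- file.path(dir, "map.tsv")
  mp <- do.call(rbind, lapply(unique(freqs$chrom), function(ch) {
    mpos <- seq(1L, spec$chrom_length, by = 100000L)
    data.frame(chrom = ch, pos = mpos,
               rate = round(stats::rlnorm(length(mpos), log(0.5), 0.8), 4))
  }))
  utils::write.table(mp, mapf, sep = "\t", quote = FALSE, row.names = FALSE)

  gmt <- file.path(dir, "sets.gmt")
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes$gene, set_size))
  writeLines(vapply(seq_len(n_sets), function(i)
    paste(c(sprintf("set%02d", i), "synthetic", sets[[i]]),
          collapse = "\t"), character(1)), gmt)

  truthf <- file.path(dir, "truth.tsv")
  truth <- attr(freqs, "sweeps")
  if (is.null(truth)) truth <- data.table::data.table(snp = integer())
  data.table::fwrite(truth, truthf, sep = "\t")

  # the table the VCF should read back to (post-polarization)
  st <- freqs[, c("chrom", "pos", "genic", "block")]
  st[, `:=`(anc = anc, der = der)]
  for (k in seq_len(spec$n_pops)) {
    st[, (paste0("dac_", spec$pop_names[k])) := dac[, k]]
    st[, (paste0("n_", spec$pop_names[k])) := spec$haploid_sizes[k]]
  }
  list(vcf = vcf, panel = panel, genes = bed, map = mapf, gene_sets = gmt,
       truth = truthf, snps = snp_table(st, spec$pop_names))
}
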