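# Shared fixtures, all generated in code at test time.

# A hand-written 6-sample VCF exercising the read/polarize edge cases:
# record 2 has a missing genotype, record 3 is multi-allelic, record 4 is
# ancestral = ALT (polarization flip), record 5 has AA=N (dropped by
# polarize), record 6 sits on chrX (excluded at read).
write_toy_vcf <- function(path) {
  samples <- c("a1", "a2", "a3", "b1", "b2", "b3")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t1/1\t0/0\t0/1\t0/0\t0/0",
    "chr1\t200\t.\tC\tT\t.\tPASS\tAA=C\tGT\t./.\t0/0\t0/0\t0/0\t0/0\t0/0",
    "chr1\t300\t.\tG\tA,T\t.\tPASS\tAA=G\tGT\t0/1\t0/0\t0/0\t0/2\t0/0\t0/0",
    "chr1\t400\t.\tT\tC\t.\tPASS\tAA=C\tGT\t0/1\t1/1\t0/1\t1/1\t1/1\t0/1",
    "chr1\t500\t.\tA\tC\t.\tPASS\tAA=N\tGT\t0/1\t0/0\t0/0\t0/0\t0/0\t0/1",
    "chrX\t600\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t0/0\t0/0\t0/0\t0/0\t0/0")
  writeLines(lines, path)
  path
}

toy_panel <- function() {
  population_panel(c("a1", "a2", "a3", "b1", "b2", "b3"),
                   c("A", "A", "A", "B", "B", "B"))
}

# strong-drift layout: delta tails populated on a 2e4-SNP fixture
# (250 blocks), genic labels independent of delta under the null
strong_drift_spec <- function(n_snps = 20000L, sweep_n = 0L, ...) {
  synth_spec(n_snps = n_snps,
             drift = list(leaf = c(0.3, 0.3, 0.3, 0.3),
                          internal = c(0.05, 0.05)),
             sweep_n = sweep_n, ...)
}

# one sampled dataset from a spec (frequencies + sweeps + counts)
make_fixture <- function(spec, seed) {
  fr <- generate_frequencies(spec, seed = seed)
  fr <- plant_sweeps(fr, seed = seed + 1L)
  snps <- sample_counts(fr, seed = seed + 2L)
  attr(snps, "hitchhikers") <- attr(fr, "sweep_hitchhikers")
  snps
}

# a small snp_table built by hand (2 populations, explicit counts)
hand_snp_table <- function(dac1, n1, dac2, n2, genic = NULL, block = NULL) {
  k <- length(dac1)
  dt <- data.table::data.table(
    chrom = "chr1", pos = seq_len(k) * 100L, anc = "A", der = "G",
    dac_A = as.integer(dac1), n_A = as.integer(n1),
    dac_B = as.integer(dac2), n_B = as.integer(n2))
  if (!is.null(genic)) dt$genic <- genic
  if (!is.null(block)) dt$block <- block
  snp_table(dt, c("A", "B"))
}
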