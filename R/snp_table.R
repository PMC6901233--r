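#' SNP table
#'
#' The central container of the package: one row per bi-allelic SNP with
#' polarized (ancestral/derived) alleles and per-population derived allele
#' counts. Implemented as a `data.table` with class `snp_table` and columns
#' `chrom`, `pos` (1-based), `anc`, `der`, one pair `dac_<pop>` /
#' `n_<pop>` per population (derived allele count / called haploid count),
#' and optionally `genic` (logical), `block` (character window id) and
#' `rate` (cM/Mb).
#'
#' @param dt a data.frame/data.table with the columns above.
#' @param populations character vector of population names (in panel order).
#' @return the validated `snp_table` (a `data.table`).
#' @export
snp_table <- function(dt, populations) {
  dt <- data.table::as.data.table(dt)
  need <- c("chrom", "pos", "anc", "der",
            paste0("dac_", populations), paste0("n_", populations))
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("snp_table missing columns: ",
                         paste(miss, collapse = ", "))
  for (p in populations) {
    dac <- dt[[paste0("dac_", p)]]
    n <- dt[[paste0("n_", p)]]
    if (any(dac < 0L | dac > n))
      stop("derived counts outside [0, called] for population ", p)
  }
  if (is.unsorted(dt$pos[order(dt$chrom)], strictly = FALSE)) {
    data.table::setorderv(dt, c("chrom", "pos"))
  }
  if (anyDuplicated(dt, by = c("chrom", "pos")))
    stop("duplicated chrom/pos in snp_table")
  data.table::setattr(dt, "populations", populations)
  data.table::setattr(dt, "class", c("snp_table", class(dt)))
  dt
}

#' @export
print.snp_table <- function(x, ...) {
  cat("snp_table:", nrow(x), "SNPs,",
      length(attr(x, "populations")), "populations (",
      paste(attr(x, "populations"), collapse = ", "), ")\n")
  NextMethod()
}

pops_of <- function(snps) {
  p <- attr(snps, "populations")
  if (is.null(p)) stop("not a snp_table: missing populations attribute")
  p
}

# subset rows keeping the snp_table attributes (data.table `[` drops them)
snp_subset <- function(snps, i) {
  out <- snps[i]
  data.table::setattr(out, "populations", attr(snps, "populations"))
  data.table::setattr(out, "class", class(snps))
  out
}

#' Derived allele frequencies for one population
#'
#' @param snps a [snp_table()].
#' @param pop population name.
#' @return numeric vector of derived allele frequencies.
#' @export
daf <- function(snps, pop) {
  pops <- pops_of(snps)
  if (!pop %in% pops) stop("unknown population: ", pop)
  snps[[paste0("dac_", pop)]] / snps[[paste0("n_", pop)]]
}

#' Write / read the canonical SNP table TSV
#'
#' Field-for-field round trip: `read_snp_table(write_snp_table(x, f))` equals
#' `x` including the population set and column types.
#'
#' @param snps a [snp_table()].
#' @param path output TSV path.
#' @return `write_snp_table` returns `path` invisibly; `read_snp_table`
#'   returns a [snp_table()].
#' @export
write_snp_table <- function(snps, path) {
  data.table::fwrite(snps, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  pops <- sub("^dac_", "", grep("^dac_", names(dt), value = TRUE))
  if ("genic" %in% names(dt)) dt[, genic := as.logical(genic)]
  if ("block" %in% names(dt)) dt[, block := as.character(block)]
  snp_table(dt, pops)
}
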