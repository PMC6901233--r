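#' Read bi-allelic SNPs from a VCF into a SNP table
#'
#' Reads a VCF (plain or bgzipped), keeps autosomal bi-allelic SNPs, drops
#' every record with at least one missing genotype across the panel samples
#' (allele frequencies are only comparable across populations when computed
#' on fully called sites), and tallies ALT allele counts per population.
#' Records are provisionally polarized to REF = ancestral; run [polarize()]
#' with the real ancestral source afterwards.
#'
#' @param vcf path to a VCF file.
#' @param panel a [population_panel()]; every panel sample must be present in
#'   the VCF header.
#' @param exclude_chroms regular expression for chromosomes to drop
#'   (default: sex chromosomes, mitochondria, unplaced scaffolds).
#' @return a [snp_table()] with attributes `n_multiallelic` (records skipped
#'   as non-bi-allelic SNPs) and `n_missing` (records dropped for missing
#'   genotypes). If the VCF has an `AA` INFO tag it is carried in column `aa`.
#' @export
read_variants <- function(vcf, panel,
                          exclude_chroms = "^(chr)?(X|Y|M|MT)$|Un|random") {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    empty <- data.table::data.table(chrom = character(), pos = integer(),
                                    anc = character(), der = character())
    for (p in panel$populations) {
      empty[, (paste0("dac_", p)) := integer()]
      empty[, (paste0("n_", p)) := integer()]
    }
    return(snp_table(empty, panel$populations))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  absent <- setdiff(names(panel$samples), colnames(gt))
  if (length(absent))
    stop("panel sample(s) absent from VCF: ", paste(absent, collapse = ", "))
  gt <- gt[, names(panel$samples), drop = FALSE]

  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_multi <- sum(!snp)
  auto <- !grepl(exclude_chroms, fix$CHROM)
  keep <- snp & auto

  # allele counts; any missing allele kills the record
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  ok <- (a1 == "0" | a1 == "1") & (a2 == "0" | a2 == "1")
  ok[is.na(ok)] <- FALSE
  complete <- rowSums(ok) == ncol(gt)
  n_missing <- sum(keep & !complete)
  keep <- keep & complete

  alt <- (a1 == "1") + (a2 == "1")
  dt <- data.table::data.table(chrom = fix$CHROM[keep],
                               pos = as.integer(fix$POS[keep]),
                               anc = fix$REF[keep], der = fix$ALT[keep])
  for (p in panel$populations) {
    cols <- names(panel$samples)[panel$samples == p]
    dt[, (paste0("dac_", p)) :=
         as.integer(rowSums(alt[keep, cols, drop = FALSE]))]
    dt[, (paste0("n_", p)) := panel$haploid_sizes[[p]]]
  }
  info <- fix$INFO[keep]
  aa <- sub("^.*(^|;)AA=([^;]*).*$", "\\2", info)
  if (any(grepl("(^|;)AA=", info))) {
    aa[!grepl("(^|;)AA=", info)] <- NA_character_
    dt[, aa := toupper(aa)]
  }
  out <- snp_table(dt, panel$populations)
  data.table::setattr(out, "n_multiallelic", n_multi)
  data.table::setattr(out, "n_missing", n_missing)
  out
}

#' Polarize derived allele counts against an ancestral source
#'
#' Derived counts in a freshly read SNP table are ALT counts (REF assumed
#' ancestral). This operation re-polarizes them against an inferred ancestral
#' allele: where the ancestral allele equals the current derived (ALT) allele
#' the counts are complemented; SNPs whose ancestral state is missing or
#' matches neither allele are dropped and counted.
#'
#' @param snps a [snp_table()].
#' @param ancestral one of: the string `"info"` (use the `aa` column carried
#'   from the VCF `AA` INFO tag), a `Biostrings::DNAStringSet` outgroup
#'   reference (names = chromosomes), or a path to an outgroup FASTA.
#' @return a polarized [snp_table()] with attribute `n_unpolarized` counting
#'   dropped SNPs.
#' @export
polarize <- function(snps, ancestral = "info") {
  pops <- pops_of(snps)
  if (is.character(ancestral) && length(ancestral) == 1 &&
      identical(ancestral, "info")) {
    if (!"aa" %in% names(snps))
      stop("no 'aa' column: VCF had no AA INFO tag")
    aa <- snps$aa
  } else {
    ref <- if (is.character(ancestral)) {
      Biostrings::readDNAStringSet(ancestral)
    } else ancestral
    names(ref) <- sub("\\s.*$", "", names(ref))
    aa <- rep(NA_character_, nrow(snps))
    for (ch in unique(snps$chrom)) {
      if (!ch %in% names(ref)) next
      i <- which(snps$chrom == ch)
      aa[i] <- toupper(as.character(
        Biostrings::extractAt(ref[[ch]],
                              IRanges::IRanges(snps$pos[i], width = 1L))))
    }
  }
  keep <- !is.na(aa) & (aa == snps$anc | aa == snps$der)
  flip <- keep & aa == snps$der & aa != snps$anc
  out <- data.table::copy(snps)
  for (p in pops) {
    dc <- paste0("dac_", p); nc <- paste0("n_", p)
    out[flip, (dc) := get(nc) - get(dc)]
  }
  tmp <- out$anc[flip]
  out[flip, anc := der]
  out[which(flip), der := tmp]
  n_drop <- sum(!keep)
  out <- out[which(keep)]
  if ("aa" %in% names(out)) out[, aa := NULL]
  out <- snp_table(out, pops)
  data.table::setattr(out, "n_unpolarized", n_drop)
  out
}

#' Read gene annotation (GFF3 or BED)
#'
#' @param path a GFF3 (`.gff`, `.gff3`) or BED file. For GFF3, records of
#'   type `gene` are used (all records if none are typed `gene`). BED
#'   half-open 0-based coordinates are converted to 1-based inclusive.
#' @return a `data.table` with columns `gene`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene", na.rm = TRUE))
    gr <- gr[gr$type == "gene"]
  ids <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) gr$gene_id
         else if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID
         else if ("name" %in% names(S4Vectors::mcols(gr))) gr$name
         else paste0("gene", seq_along(gr))
  dt <- data.table::data.table(
    gene = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  if (anyDuplicated(dt$gene)) stop("duplicated gene ids in ", path)
  dt
}

# merged genic intervals: gene spans padded by `pad`, clipped at 1
genic_intervals <- function(genes, pad = 2000L) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - pad), genes$end + pad))
  GenomicRanges::reduce(gr)
}

#' Flag genic SNPs
#'
#' A SNP is genic iff it lies within any gene span extended by `pad` bp on
#' each side (merged across overlapping genes; boundaries inclusive).
#'
#' @param snps a [snp_table()].
#' @param genes gene annotation from [read_genes()] (or any data.frame with
#'   `gene`, `chrom`, `start`, `end`).
#' @param pad flank added to both gene ends, in bp (default 2000).
#' @return the SNP table with a logical `genic` column.
#' @export
annotate_genic <- function(snps, genes, pad = 2000L) {
  ivl <- genic_intervals(genes, pad)
  missing_chr <- setdiff(unique(snps$chrom),
                         as.character(unique(GenomicRanges::seqnames(ivl))))
  if (length(missing_chr))
    warning("chromosome(s) absent from gene annotation (all SNPs there ",
            "non-genic): ", paste(missing_chr, collapse = ", "))
  sgr <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(snps$pos, width = 1L))
  # suppress the seqlevel-mismatch chatter; disjoint chromosomes are already
  # reported above
  hit <- suppressWarnings(GenomicRanges::countOverlaps(sgr, ivl) > 0L)
  out <- data.table::copy(snps)
  out[, genic := hit]
  snp_table(out, pops_of(snps))
}

#' Assign non-overlapping genomic windows (blocks)
#'
#' Windows are `[k*L + 1, (k+1)*L]` per chromosome, anchored at position 1.
#' Block ids are `"<chrom>:<k>"` and stable across runs.
#'
#' @param snps a [snp_table()].
#' @param block_length window length in bp (default 200 kb).
#' @return the SNP table with a `block` column.
#' @export
assign_blocks <- function(snps, block_length = 200000L) {
  out <- data.table::copy(snps)
  out[, block := paste0(chrom, ":", (pos - 1L) %/% as.integer(block_length))]
  snp_table(out, pops_of(snps))
}

#' Read a genetic map
#'
#' @param path tab-separated file with columns `chrom`, `pos`, `rate`
#'   (cM/Mb), header optional.
#' @return a `data.table` sorted by chromosome and position.
#' @export
read_genetic_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (!all(c("chrom", "pos", "rate") %in% names(dt))) {
    data.table::setnames(dt, seq_len(3), c("chrom", "pos", "rate"))
  }
  dt[, chrom := as.character(chrom)]
  data.table::setorderv(dt, c("chrom", "pos"))
  if (any(dt$rate < 0)) stop("negative recombination rate in map")
  if (any(dt[, duplicated(pos), by = chrom]$V1))
    stop("duplicated marker positions in map")
  dt
}

#' Interpolate recombination rates at SNP positions
#'
#' A position strictly between two consecutive markers receives the average
#' of their local rates; a position at a marker receives that marker's rate;
#' positions outside the marker span receive the nearest terminal marker's
#' rate (or `NA` when `extend = FALSE`).
#'
#' @param map a genetic map ([read_genetic_map()]).
#' @param chrom,pos chromosome and position vectors (equal length).
#' @param extend logical; extend terminal rates beyond the marker span.
#' @return numeric vector of rates (cM/Mb); `NA` with a warning on
#'   chromosomes with fewer than 2 markers.
#' @export
interpolate_rates <- function(map, chrom, pos, extend = TRUE) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    m <- map[map$chrom == ch]
    if (nrow(m) < 2L) {
      warning("fewer than 2 map markers on ", ch, "; rates undefined")
      next
    }
    mp <- m$pos; mr <- m$rate
    idx <- findInterval(pos[i], mp)
    r <- rep(NA_real_, length(i))
    inside <- idx >= 1L & idx < length(mp)
    at <- inside & pos[i] == mp[pmax(idx, 1L)]
    between <- inside & !at
    r[at] <- mr[idx[at]]
    r[between] <- (mr[idx[between]] + mr[idx[between] + 1L]) / 2
    hi_at <- idx == length(mp) & pos[i] == mp[length(mp)]
    r[hi_at] <- mr[length(mp)]
    if (extend) {
      r[idx == 0L] <- mr[1L]
      r[idx == length(mp) & !hi_at] <- mr[length(mp)]
    }
    out[i] <- r
  }
  out
}

#' Filter SNPs by local recombination rate
#'
#' Retains SNPs with rate strictly below `max_rate`; SNPs lacking a rate are
#' dropped.
#'
#' @param snps a [snp_table()] with a `rate` column.
#' @param max_rate threshold in cM/Mb (default 0.5; strict `<`).
#' @return the filtered [snp_table()].
#' @export
filter_by_rate <- function(snps, max_rate = 0.5) {
  if (!"rate" %in% names(snps)) stop("no 'rate' column; run interpolate_rates")
  keep <- !is.na(snps$rate) & snps$rate < max_rate
  if (!any(keep)) warning("no SNPs retained by the rate filter")
  snp_table(snps[which(keep)], pops_of(snps))
}

#' Remove SNPs inside excluded regions
#'
#' @param snps a [snp_table()].
#' @param exclude data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. a known mega-cluster of linked differentiated alleles.
#' @return the filtered [snp_table()].
#' @export
filter_by_region <- function(snps, exclude) {
  if (is.null(exclude) || nrow(exclude) == 0)
    return(snps)
  xgr <- GenomicRanges::GRanges(exclude$chrom,
                                IRanges::IRanges(exclude$start, exclude$end))
  sgr <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(snps$pos, width = 1L))
  drop <- suppressWarnings(GenomicRanges::countOverlaps(sgr, xgr) > 0L)
  snp_table(snps[which(!drop)], pops_of(snps))
}
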