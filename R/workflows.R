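#' Run a named analysis workflow
#'
#' Thin orchestration over the package's functions: validates a config list
#' against the workflow's required keys, runs it, writes tab-separated
#' outputs plus a JSON manifest (package version, seeds, input checksums)
#' and returns the result invisibly. Given the same config and seed, outputs
#' are identical across runs.
#'
#' @param name one of `"synth"`, `"delta-scan"`, `"pbsnj-scan"`,
#'   `"simulate"`, `"fit-b"`, `"geneset-test"`, `"sweep-count"`.
#' @param config a named list; see Details.
#' @return list of output paths and in-memory results, invisibly.
#'
#' @details Required keys per workflow:
#' \describe{
#'   \item{synth}{`out_dir`, `seed`; optional any [synth_spec()] argument.}
#'   \item{delta-scan}{`vcf`, `panel`, `genes`, `pair` (length 2), `out_prefix`,
#'     optional `exclude` (data.frame), `map` + `max_rate`, `seed`.}
#'   \item{pbsnj-scan}{`vcf`, `panel`, `genes`, `out_prefix`.}
#'   \item{simulate}{`n_loci`, `seed`, `out_prefix`; optional `model`
#'     (a [demographic_model()], default [chimp_model()]), `b_genic`,
#'     `b_nongenic`, `genic_fraction`.}
#'   \item{fit-b}{`observed`, `sim_library`, `bins`, `out_prefix`.}
#'   \item{geneset-test}{`mode` (`"gene"`), `scores_tsv` or `snps`,
#'     `sets_gmt`, `genes`, `pop`, `n_resamples`, `seed`, `out_prefix`.}
#'   \item{sweep-count}{`scores` (pbsnj per-SNP TSV), `pop`, `threshold`,
#'     `order`, `out_prefix`; optional `shuffles`, `seed`.}
#' }
#' @export
run_workflow <- function(name, config) {
  name <- match.arg(name, c("synth", "delta-scan", "pbsnj-scan", "simulate",
                            "fit-b", "geneset-test", "sweep-count"))
  need <- switch(name,
    "synth" = c("out_dir", "seed"),
    "delta-scan" = c("vcf", "panel", "genes", "pair", "out_prefix"),
    "pbsnj-scan" = c("vcf", "panel", "genes", "out_prefix"),
    "simulate" = c("n_loci", "seed", "out_prefix"),
    "fit-b" = c("observed", "sim_library", "out_prefix"),
    "geneset-test" = c("snps", "sets_gmt", "genes", "pop", "out_prefix"),
    "sweep-count" = c("scores", "pop", "threshold", "out_prefix"))
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("workflow '", name, "' config missing key(s): ",
         paste(miss, collapse = ", "))
  inputs <- unlist(config[vapply(config, function(x)
    is.character(x) && length(x) == 1 && file.exists(x), logical(1))])
  res <- switch(name,
    "synth" = wf_synth(config),
    "delta-scan" = wf_delta_scan(config),
    "pbsnj-scan" = wf_pbsnj_scan(config),
    "simulate" = wf_simulate(config),
    "fit-b" = wf_fit_b(config),
    "geneset-test" = wf_geneset(config),
    "sweep-count" = wf_sweep_count(config))
  manifest <- list(
    workflow = name,
    package_version = as.character(utils::packageVersion("pbsnj")),
    seed = config$seed,
    inputs = as.list(if (length(inputs)) tools::md5sum(inputs) else list()),
    outputs = res$outputs)
  mpath <- paste0(res$prefix, ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- mpath
  invisible(res)
}

read_scan_inputs <- function(config) {
  panel <- read_panel(config$panel)
  snps <- read_variants(config$vcf, panel)
  snps <- polarize(snps, config$ancestral %||% "info")
  snps <- annotate_genic(snps, read_genes(config$genes))
  snps <- assign_blocks(snps, config$block_length %||% 200000L)
  if (!is.null(config$map)) {
    map <- read_genetic_map(config$map)
    snps[, rate := interpolate_rates(map, chrom, pos)]
    snps <- filter_by_rate(snps, config$max_rate %||% 0.5)
  }
  if (!is.null(config$exclude))
    snps <- filter_by_region(snps, config$exclude)
  snps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wf_synth <- function(config) {
  sp_args <- config[intersect(names(config), names(formals(synth_spec)))]
  spec <- do.call(synth_spec, sp_args)
  fr <- generate_frequencies(spec, seed = config$seed)
  fr <- plant_sweeps(fr, seed = config$seed + 1L)
  out <- emit_dataset(fr, config$out_dir, seed = config$seed + 2L)
  list(outputs = out[c("vcf", "panel", "genes", "map", "gene_sets", "truth")],
       snps = out$snps, prefix = file.path(config$out_dir, "synth"))
}

wf_delta_scan <- function(config) {
  snps <- read_scan_inputs(config)
  pair <- config$pair
  bin <- bin_delta(delta(snps, pair[1], pair[2]))
  spec <- enrichment_spectrum(snps, bin)
  asym <- delta_asymmetry_all_pairs(snps)
  f1 <- paste0(config$out_prefix, ".spectrum.tsv")
  f2 <- paste0(config$out_prefix, ".asymmetry.tsv")
  data.table::fwrite(spec, f1, sep = "\t")
  data.table::fwrite(asym, f2, sep = "\t")
  list(outputs = list(spectrum = f1, asymmetry = f2), spectrum = spec,
       asymmetry = asym, prefix = config$out_prefix)
}

wf_pbsnj_scan <- function(config) {
  snps <- read_scan_inputs(config)
  scores <- pbsnj_scan(snps)
  pops <- attr(scores, "populations")
  f1 <- paste0(config$out_prefix, ".scores.tsv")
  data.table::fwrite(scores, f1, sep = "\t")
  outs <- list(scores = f1)
  spectra <- list()
  for (p in pops) {
    sp <- pbsnj_enrichment(scores, p)
    fp <- paste0(config$out_prefix, ".spectrum.", p, ".tsv")
    data.table::fwrite(sp, fp, sep = "\t")
    outs[[paste0("spectrum_", p)]] <- fp
    spectra[[p]] <- sp
  }
  list(outputs = outs, scores = scores, spectra = spectra,
       prefix = config$out_prefix)
}

wf_simulate <- function(config) {
  model <- config$model %||% chimp_model()
  sim <- simulate_loci(model, config$n_loci,
                       genic_fraction = config$genic_fraction %||% 0.5,
                       b_genic = config$b_genic %||% 1,
                       b_nongenic = config$b_nongenic %||% 1,
                       seed = config$seed)
  f1 <- paste0(config$out_prefix, ".loci.tsv")
  data.table::fwrite(sim, f1, sep = "\t")
  list(outputs = list(loci = f1), sim = sim, prefix = config$out_prefix)
}

wf_fit_b <- function(config) {
  fit <- fit_b(config$observed, config$sim_library,
               bins = config$bins %||% "all")
  f1 <- paste0(config$out_prefix, ".ssd.tsv")
  data.table::fwrite(fit$ssd, f1, sep = "\t")
  list(outputs = list(ssd = f1), fit = fit, prefix = config$out_prefix)
}

wf_geneset <- function(config) {
  snps <- config$snps
  sets <- read_gene_sets(config$sets_gmt,
                         min_size = config$min_size %||% 3L)
  genes <- if (is.character(config$genes)) read_genes(config$genes)
           else config$genes
  gm <- snp_gene_map(snps, genes)
  tail_idx <- which(snps[[paste0("score_", config$pop)]] >= 0.8)
  res <- gene_mode_resample(tail_idx, seq_len(nrow(snps)), gm, sets,
                            n_resamples = config$n_resamples %||% 1000L,
                            seed = config$seed %||% 1L)
  f1 <- paste0(config$out_prefix, ".genesets.tsv")
  data.table::fwrite(res, f1, sep = "\t")
  list(outputs = list(genesets = f1), result = res,
       prefix = config$out_prefix)
}

wf_sweep_count <- function(config) {
  scores <- if (is.character(config$scores))
    data.table::fread(config$scores) else config$scores
  tail <- scores[[paste0("score_", config$pop)]] >= 0.8
  ranking <- rank_blocks(scores, tail,
                         ordering = config$order %||% "genic")
  rec <- tail_enrichment_recomputer(scores, config$pop)
  est <- estimate_sweep_number(ranking, rec, config$threshold)
  out <- list(k = est$k, reached = est$reached)
  if (!is.null(config$shuffles) && config$shuffles > 0) {
    sb <- shuffle_baseline(ranking, rec, config$threshold,
                           n_shuffles = config$shuffles,
                           seed = config$seed %||% 1L)
    out$shuffle_median <- sb$median
  }
  f1 <- paste0(config$out_prefix, ".sweeps.tsv")
  data.table::fwrite(data.table::as.data.table(out), f1, sep = "\t")
  list(outputs = list(sweeps = f1), estimate = est, prefix = config$out_prefix)
}
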