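#' Population panel
#'
#' A panel maps samples to populations and fixes the haploid sample size per
#' population. Per-population allele counts and all downstream statistics are
#' defined with respect to a panel.
#'
#' @param samples character vector of sample identifiers.
#' @param populations character vector, same length, assigning each sample to
#'   one population.
#' @return An object of class `population_panel`: a list with `samples`
#'   (named character vector sample -> population), `populations` (unique
#'   population names in order of first appearance) and `haploid_sizes`
#'   (named integer vector, `2 * diploids` per population).
#' @details Unbiased per-pair Fst correction terms require at least 4 haploid
#'   genomes (2 diploids) per population; smaller populations are rejected.
#' @export
population_panel <- function(samples, populations) {
  if (length(samples) != length(populations))
    stop("samples and populations must have equal length")
  if (anyDuplicated(samples))
    stop("duplicated sample id: ", samples[duplicated(samples)][1])
  pops <- unique(populations)
  hap <- vapply(pops, function(p) 2L * sum(populations == p), integer(1))
  if (any(hap < 4L))
    stop("each population needs >= 4 haploid genomes; too small: ",
         paste(pops[hap < 4L], collapse = ", "))
  structure(
    list(samples = stats::setNames(as.character(populations),
                                   as.character(samples)),
         populations = as.character(pops),
         haploid_sizes = hap),
    class = "population_panel")
}

#' Read a sample-to-population panel file
#'
#' @param path two-column tab-separated text file, `sample<TAB>population`,
#'   no header.
#' @return A [population_panel()].
#' @export
read_panel <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("sample", "population"),
                         colClasses = "character")
  population_panel(x$sample, x$population)
}

#' @export
print.population_panel <- function(x, ...) {
  cat("population panel:", length(x$samples), "samples,",
      length(x$populations), "populations\n")
  for (p in x$populations)
    cat(" ", p, ":", x$haploid_sizes[[p]], "haploid genomes\n")
  invisible(x)
}
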