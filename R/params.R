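#' Simulation parameters for the synthetic GLORI experiment
#'
#' Bundles every knob of the synthetic-data generators. The defaults encode
#' the study conditions the downstream statistics assume: a low-GC (32%)
#' transcriptome, near-complete deamination of unmethylated adenosines
#' (efficiency 0.99), high-stoichiometry methylation at A+1C sites
#' (Beta(20, 2), mean ~0.91), moderate stoichiometry at A+1U/+4U sites
#' (Beta(6, 6), mean 0.5), suppression of sites within 100 nt of an
#' exon-intron junction (EIJ), and a 3'-ward placement bias.
#'
#' @param n_genes number of transcripts to simulate.
#' @param length_range integer pair, min/max transcript length (nt).
#' @param gc_content target GC fraction of the transcriptome.
#' @param exon_count_range integer pair, min/max exons per transcript.
#' @param depth_mean mean GLORI read depth per transcript (reads; scaled per
#'   gene by its expression weight).
#' @param read_length read length (nt).
#' @param conversion_efficiency probability that an unmethylated A is read as
#'   G after treatment.
#' @param stoich_high Beta shape pair for stoichiometry of +1C sites.
#' @param stoich_mid Beta shape pair for stoichiometry of +1U/+4U sites.
#' @param eij_exclusion_nt sites are suppressed within this distance of an EIJ.
#' @param three_prime_bias exponent of the 3'-ward placement weight
#'   `(pos/length)^three_prime_bias`; 0 disables the bias.
#' @param site_prob maximum per-eligible-adenosine placement probability
#'   (attained at the 3' end).
#' @param seed integer seed; the same `sim_params` yields byte-identical
#'   simulator output.
#' @return a list of class `sim_params`.
#' @examples
#' p <- sim_params(n_genes = 10, seed = 1)
#' p$gc_content
#' @export
sim_params <- function(n_genes = 200,
                       length_range = c(500L, 3000L),
                       gc_content = 0.32,
                       exon_count_range = c(1L, 8L),
                       depth_mean = 100,
                       read_length = 100L,
                       conversion_efficiency = 0.99,
                       stoich_high = c(20, 2),
                       stoich_mid = c(6, 6),
                       eij_exclusion_nt = 100L,
                       three_prime_bias = 2,
                       site_prob = 0.15,
                       seed = 1L) {
  stopifnot(length(length_range) == 2, length(exon_count_range) == 2,
            length(stoich_high) == 2, length(stoich_mid) == 2)
  if (n_genes < 1) stop("`n_genes` must be a positive count", call. = FALSE)
  if (any(length_range <= 0) || length_range[1] > length_range[2])
    stop("`length_range` must be a positive, ordered pair", call. = FALSE)
  if (exon_count_range[1] < 1 || exon_count_range[1] > exon_count_range[2])
    stop("`exon_count_range` must be an ordered pair of counts >= 1", call. = FALSE)
  for (frac in list(gc_content = gc_content,
                    conversion_efficiency = conversion_efficiency,
                    site_prob = site_prob)) {
    if (frac < 0 || frac > 1)
      stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(stoich_high <= 0) || any(stoich_mid <= 0))
    stop("Beta shape parameters must be positive", call. = FALSE)
  if (eij_exclusion_nt < 0 || three_prime_bias < 0 || depth_mean <= 0 ||
      read_length < 1)
    stop("invalid simulation parameter", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes),
    length_range = as.integer(length_range),
    gc_content = gc_content,
    exon_count_range = as.integer(exon_count_range),
    depth_mean = depth_mean,
    read_length = as.integer(read_length),
    conversion_efficiency = conversion_efficiency,
    stoich_high = stoich_high,
    stoich_mid = stoich_mid,
    eij_exclusion_nt = as.integer(eij_exclusion_nt),
    three_prime_bias = three_prime_bias,
    site_prob = site_prob,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x)) cat(" ", nm, ":", format(x[[nm]]), "\n")
  invisible(x)
}
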