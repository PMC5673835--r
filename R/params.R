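#' Pipeline parameter set
#'
#' Collects every numeric threshold of the locus-processing pipeline in one
#' validated object.  Defaults are the operating point of the anchored-capture
#' study the pipeline was built for: a 46-taxon dataset at moderate coverage,
#' where the absolute cut-offs of 23 supporting reads per contig and 23
#' unmasked bases per alignment site are calibrated to taxon number and depth.
#' For smaller matrices both can instead be given as fractions of the taxon
#' count (`contig_min_reads_frac`, `site_min_unmasked_frac`), applied as
#' `ceiling(frac * n)` at the point of use.
#'
#' @param merge_alpha probability threshold for accepting a read-pair overlap;
#'   an overlap is accepted only when the probability of seeing that many
#'   matches by chance is below `merge_alpha`.
#' @param seed_kmer_length number of compared (care) positions in the spaced
#'   seed used for read recruitment.
#' @param seed_min_matches minimum matching care positions for a preliminary
#'   match.
#' @param confirm_window length of the consecutive-base confirmation window.
#' @param confirm_min_matches minimum matches within `confirm_window`.
#' @param contig_min_reads minimum supporting read (fragment) count for a
#'   retained contig; contigs below this are removed to suppress
#'   cross-contamination and index-read errors.
#' @param ortho_kmer_length k-mer size for orthology distances.
#' @param cluster_min_species_frac minimum fraction of species a retained
#'   ortholog cluster must contain ("fewer than" semantics: a cluster is
#'   removed iff its species count is strictly below `frac * n_species`).
#' @param conserved_site_frac an alignment column is conserved when its modal
#'   non-gap character occurs in strictly more than this fraction of
#'   sequences.
#' @param mask_window number of conserved columns per masking scan window.
#' @param mask_min_matches minimum matches to the common base per window.
#' @param site_min_unmasked minimum unmasked, non-gap characters for a column
#'   to survive trimming.
#' @param contig_min_reads_frac,site_min_unmasked_frac optional fractional
#'   alternatives to the absolute thresholds (of taxon count).
#' @param spaced_mask binary string giving the spaced-seed template; must have
#'   `seed_kmer_length` care positions with care first and last positions.
#' @param extension_min_depth minimum read depth required to extend a contig
#'   beyond the currently assembled region.
#' @param homolog_min_sites minimum number of phase-consistent conflicting
#'   sites before a contig is split into two homolog consensus sequences.
#' @param stop_distance orthology clustering stops joining once all allowed
#'   inter-cluster distances reach this value.
#' @param min_final_length trimmed alignments shorter than this are dropped.
#' @param rng_seed integer seed governing every stochastic step.
#' @return an object of class `pipeline_params` (a validated list).
#' @export
pipeline_params <- function(merge_alpha = 1e-10,
                            seed_kmer_length = 20L,
                            seed_min_matches = 17L,
                            confirm_window = 100L,
                            confirm_min_matches = 55L,
                            contig_min_reads = 23L,
                            ortho_kmer_length = 20L,
                            cluster_min_species_frac = 0.5,
                            conserved_site_frac = 0.5,
                            mask_window = 20L,
                            mask_min_matches = 10L,
                            site_min_unmasked = 23L,
                            contig_min_reads_frac = NULL,
                            site_min_unmasked_frac = NULL,
                            spaced_mask = "111011101110111011111111",
                            extension_min_depth = 3L,
                            homolog_min_sites = 5L,
                            stop_distance = 0.97,
                            min_final_length = 50L,
                            rng_seed = 1L) {
  p <- list(merge_alpha = merge_alpha,
            seed_kmer_length = as.integer(seed_kmer_length),
            seed_min_matches = as.integer(seed_min_matches),
            confirm_window = as.integer(confirm_window),
            confirm_min_matches = as.integer(confirm_min_matches),
            contig_min_reads = as.integer(contig_min_reads),
            ortho_kmer_length = as.integer(ortho_kmer_length),
            cluster_min_species_frac = cluster_min_species_frac,
            conserved_site_frac = conserved_site_frac,
            mask_window = as.integer(mask_window),
            mask_min_matches = as.integer(mask_min_matches),
            site_min_unmasked = as.integer(site_min_unmasked),
            contig_min_reads_frac = contig_min_reads_frac,
            site_min_unmasked_frac = site_min_unmasked_frac,
            spaced_mask = spaced_mask,
            extension_min_depth = as.integer(extension_min_depth),
            homolog_min_sites = as.integer(homolog_min_sites),
            stop_distance = stop_distance,
            min_final_length = as.integer(min_final_length),
            rng_seed = as.integer(rng_seed))
  validate_pipeline_params(p)
  structure(p, class = "pipeline_params")
}

validate_pipeline_params <- function(p) {
  stopifnot(p$merge_alpha > 0, p$merge_alpha < 1,
            p$seed_min_matches <= p$seed_kmer_length,
            p$confirm_min_matches <= p$confirm_window,
            p$mask_min_matches <= p$mask_window,
            p$cluster_min_species_frac > 0, p$cluster_min_species_frac <= 1,
            p$contig_min_reads >= 1L,
            p$site_min_unmasked >= 1L,
            p$extension_min_depth >= 1L)
  pat <- spaced_pattern(p$spaced_mask)
  if (pat$weight != p$seed_kmer_length)
    stop("spaced_mask has ", pat$weight, " care positions but seed_kmer_length is ",
         p$seed_kmer_length)
  invisible(p)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("AHE pipeline parameters\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Spaced-seed template
#'
#' A spaced seed compares only a subset of positions (the care positions) of a
#' window, which tolerates mismatches at the ignored positions and improves
#' sensitivity for divergent matching relative to a contiguous k-mer of the
#' same weight.
#'
#' @param mask character string over `{0,1}`; `1` marks a care position.
#' @return list with `mask` (logical vector), `span`, `weight`, and `care0`
#'   (0-based care offsets, used by the matching kernels).
#' @export
spaced_pattern <- function(mask = "111011101110111011111111") {
  bits <- strsplit(mask, "", fixed = TRUE)[[1]]
  if (!all(bits %in% c("0", "1"))) stop("mask must be a binary string")
  care <- bits == "1"
  if (!care[1] || !care[length(care)])
    stop("first and last positions of a spaced seed must be care positions")
  list(mask = care,
       span = length(care),
       weight = sum(care),
       care0 = which(care) - 1L)
}

# resolve the absolute/fractional dual thresholds
resolve_min_reads <- function(params, n_taxa = NULL) {
  if (!is.null(params$contig_min_reads_frac) && !is.null(n_taxa))
    ceiling(params$contig_min_reads_frac * n_taxa)
  else params$contig_min_reads
}

resolve_min_unmasked <- function(params, n_taxa) {
  if (!is.null(params$site_min_unmasked_frac))
    ceiling(params$site_min_unmasked_frac * n_taxa)
  else params$site_min_unmasked
}
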