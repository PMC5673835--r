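#' Shared-k-mer distance between two sequences
#'
#' Similarity is the containment fraction of shared k-mers, computed twice —
#' over the sets of continuous k-mers and over the sets of spaced k-mers
#' (care-position characters of each window of `pattern$span`) — and averaged:
#' `d = 1 - (s_cont + s_spaced) / 2` with
#' `s = |A∩B| / min(|A|, |B|)` over the unique k-mer sets.  The
#' containment denominator lets a short consensus fragment of a longer
#' sequence score as similar, which matters because capture efficiency makes
#' consensus lengths uneven.  K-mers are orientation-sensitive unless
#' `canonical = TRUE`.
#'
#' @param seq_a,seq_b character scalars.
#' @param k continuous k-mer length (default 20).
#' @param pattern spaced template, a [spaced_pattern()].
#' @param canonical if TRUE, each k-mer is replaced by the lexicographic
#'   minimum of itself and its reverse complement.
#' @return distance in `[0, 1]`; sequences shorter than the pattern span give
#'   distance 1 with a warning.
#' @export
kmer_distance <- function(seq_a, seq_b, k = 20L, pattern = spaced_pattern(),
                          canonical = FALSE) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (la < pattern$span || lb < pattern$span) {
    warning("sequence shorter than the spaced pattern span; distance set to 1")
    return(1)
  }
  s_cont <- kmer_containment(continuous_kmers(seq_a, k, canonical),
                             continuous_kmers(seq_b, k, canonical))
  s_spaced <- kmer_containment(spaced_kmers(seq_a, pattern, canonical),
                               spaced_kmers(seq_b, pattern, canonical))
  1 - (s_cont + s_spaced) / 2
}

continuous_kmers <- function(seq, k, canonical = FALSE) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  km <- substring(toupper(seq), 1:(L - k + 1L), k:L)
  if (canonical) km <- pmin(km, revcomp(km))
  unique(km)
}

spaced_kmers <- function(seq, pattern, canonical = FALSE) {
  L <- nchar(seq)
  if (L < pattern$span) return(character(0))
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  starts <- 1:(L - pattern$span + 1L)
  cols <- lapply(pattern$care0, function(off) ch[starts + off])
  km <- do.call(paste0, cols)
  if (canonical) km <- pmin(km, revcomp(km))
  unique(km)
}

kmer_containment <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' All pairwise k-mer distances among a set of sequences
#'
#' @param seqs named character vector.
#' @inheritParams kmer_distance
#' @return symmetric matrix with zero diagonal, dimnames from `seqs`.
#' @export
kmer_distance_matrix <- function(seqs, k = 20L, pattern = spaced_pattern(),
                                 canonical = FALSE) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], k, pattern,
                                          canonical)
    }
  }
  d
}

#' Species-constrained ortholog clustering for one locus
#'
#' Agglomerative joining in order of ascending average-linkage distance, with
#' the hard constraint that no cluster may contain two sequences of the same
#' species.  A join whose union would violate the constraint is forbidden;
#' joining stops when every remaining allowed pair is at distance
#' `stop_distance` or more, or no join is allowed.  Every input sequence ends
#' in exactly one cluster.  Ties in the minimum distance are broken
#' lexicographically by the sorted member ids of the joined pair, so the
#' result is invariant to input order.
#'
#' When one species contributes two divergent homologs, the copy whose
#' average distance to the other members is smaller joins the multi-species
#' cluster and the other copy ends up isolated — the operational rule for
#' picking, among paralogs, the consensus most similar to that of the closest
#' relatives.
#'
#' @param species named character vector: sequence id -> species.
#' @param distances symmetric distance matrix with dimnames matching
#'   `names(species)`.
#' @param stop_distance joining threshold.
#' @return list of clusters, each a list with `members` (sequence ids) and
#'   `species` (their species, same order).
#' @export
cluster_locus <- function(species, distances, stop_distance = 0.97) {
  ids <- names(species)
  stopifnot(!is.null(ids), all(ids %in% rownames(distances)))
  clusters <- lapply(ids, function(i) i)
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- NULL
    best_d <- Inf
    best_key <- ""
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        sp_i <- species[clusters[[i]]]
        sp_j <- species[clusters[[j]]]
        if (length(intersect(sp_i, sp_j))) next
        d <- mean(distances[clusters[[i]], clusters[[j]], drop = FALSE])
        if (d >= stop_distance) next
        key <- paste(sort(c(clusters[[i]], clusters[[j]])), collapse = "\r")
        if (d < best_d || (d == best_d && key < best_key)) {
          best <- c(i, j); best_d <- d; best_key <- key
        }
      }
    }
    if (is.null(best)) break
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  out <- lapply(clusters, function(m) {
    m <- sort(m)
    list(members = m, species = unname(species[m]))
  })
  # deterministic output order: by first member id
  out[order(vapply(out, function(cl) cl$members[1], character(1)))]
}

#' Filter ortholog clusters by species representation
#'
#' A cluster is removed iff it contains fewer than `min_frac` of the species
#' (strict inequality): with 46 species and the default 0.5, a 23-species
#' cluster is retained and a 22-species cluster is removed.
#'
#' @param clusters list from [cluster_locus()].
#' @param n_species_total total species in the study.
#' @param min_frac minimum species fraction.
#' @return the retained clusters.
#' @export
filter_clusters <- function(clusters, n_species_total, min_frac = 0.5) {
  stopifnot(n_species_total >= 1)
  Filter(function(cl) {
    !(length(unique(cl$species)) < min_frac * n_species_total)
  }, clusters)
}

#' Mean homolog count per recovered locus (nHomologs)
#'
#' For one species, the mean number of homolog consensus sequences recovered
#' per locus, over loci with at least one homolog.  Values near 1 indicate
#' that recent duplication (or unmerged allelic variation) is rare; a species
#' with two homologs at 71 of 100 loci scores 1.71.
#'
#' @param contigs list of contigs for one species (e.g. from
#'   [assemble_sample()]).
#' @param loci optional character vector restricting the statistic to these
#'   loci (e.g. the retained ortholog clusters).
#' @return the statistic (>= 1), or `NA` with a message when no locus was
#'   recovered.
#' @export
n_homologs <- function(contigs, loci = NULL) {
  locus_of <- vapply(contigs, function(ct) ct$locus_id, character(1))
  if (!is.null(loci)) {
    keep <- locus_of %in% loci
    contigs <- contigs[keep]
    locus_of <- locus_of[keep]
  }
  if (!length(contigs)) {
    message("no recovered loci; nHomologs undefined")
    return(NA_real_)
  }
  mean(table(locus_of))
}

#' Cross-sample orthology assessment
#'
#' Gathers homolog consensus sequences per locus across samples, computes
#' k-mer distances, clusters under the one-sequence-per-species constraint
#' and applies the species-fraction filter.
#'
#' @param contigs list of contigs across samples.
#' @param species_map named character vector: sample id -> species.
#' @param params a [pipeline_params()].
#' @return list with `clusters` (per retained cluster: locus, members as
#'   contig indices, species), `report` (data.frame: locus, cluster,
#'   n_species, retained) and `n_species_total`.
#' @export
assess_orthology <- function(contigs, species_map, params = pipeline_params()) {
  pat <- spaced_pattern(params$spaced_mask)
  n_species_total <- length(unique(species_map))
  loci <- sort(unique(vapply(contigs, function(ct) ct$locus_id, character(1))))
  retained <- list()
  rep_rows <- list()
  for (loc in loci) {
    idx <- which(vapply(contigs, function(ct) ct$locus_id == loc, logical(1)))
    seqs <- vapply(contigs[idx], function(ct) ct$consensus, character(1))
    ids <- vapply(contigs[idx], function(ct)
      sprintf("%s|%s|%s", ct$locus_id, ct$sample_id, ct$homolog), character(1))
    names(seqs) <- ids
    sp <- setNames(unname(species_map[vapply(contigs[idx],
                                             function(ct) ct$sample_id,
                                             character(1))]), ids)
    d <- kmer_distance_matrix(seqs, params$ortho_kmer_length, pat)
    cls <- cluster_locus(sp, d, params$stop_distance)
    keep <- filter_clusters(cls, n_species_total, params$cluster_min_species_frac)
    for (ci in seq_along(cls)) {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        locus = loc, cluster = ci,
        n_species = length(unique(cls[[ci]]$species)),
        retained = any(vapply(keep, function(kk)
          identical(kk$members, cls[[ci]]$members), logical(1))),
        stringsAsFactors = FALSE)
    }
    for (cl in keep) {
      retained[[length(retained) + 1L]] <- list(
        locus = loc,
        members = idx[match(cl$members, ids)],
        species = cl$species)
    }
  }
  list(clusters = retained,
       report = if (length(rep_rows)) do.call(rbind, rep_rows) else
         data.frame(locus = character(0), cluster = integer(0),
                    n_species = integer(0), retained = logical(0)),
       n_species_total = n_species_total)
}
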