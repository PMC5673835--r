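#' Coordinate-based alignment of an ortholog cluster
#'
#' Contigs from [assemble_locus()] live on a shared coordinate system (the
#' probe reference's frame, extended into the flanks).  Because read
#' placement is ungapped, cluster members can be stacked by left-padding each
#' consensus to its global start offset and right-padding to a common length.
#' This is exact for indel-free regions (the anchors) and degrades gracefully
#' in flanks that carry indels, where the downstream masking step removes the
#' drifted stretches — in production use the unaligned cluster FASTA would be
#' passed to an external aligner instead.
#'
#' @param contigs list of contigs of one cluster.
#' @param taxa row labels to use (default: the contigs' sample ids).
#' @return character matrix with one row per contig.
#' @export
offset_align_cluster <- function(contigs, taxa = NULL) {
  starts <- vapply(contigs, function(ct) ct$start, numeric(1))
  seqs <- vapply(contigs, function(ct) ct$consensus, character(1))
  if (is.null(taxa)) taxa <- vapply(contigs, function(ct) ct$sample_id, character(1))
  lo <- min(starts)
  lens <- nchar(seqs)
  width <- max(starts + lens) - lo
  m <- matrix("-", nrow = length(seqs), ncol = width, dimnames = list(taxa, NULL))
  for (i in seq_along(seqs)) {
    off <- starts[i] - lo
    m[i, (off + 1L):(off + lens[i])] <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
  }
  m
}

#' Multiple alignment of an ortholog cluster with the external mafft binary
#'
#' Thin wrapper around `mafft --auto` for the alignment stage that sits
#' between orthology assessment and masking; the alignment algorithm itself
#' is deliberately external, as in production target-capture workflows.
#'
#' @param contigs list of contigs of one cluster.
#' @param taxa row labels (default: the contigs' sample ids).
#' @return character matrix (upper case).
#' @export
mafft_align_cluster <- function(contigs, taxa = NULL) {
  if (Sys.which("mafft") == "") stop("mafft executable not found on the PATH")
  if (is.null(taxa)) taxa <- vapply(contigs, function(ct) ct$sample_id, character(1))
  fa <- tempfile(fileext = ".fa")
  fo <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fa, fo)), add = TRUE)
  writeLines(paste0(">s", seq_along(contigs), "\n",
                    vapply(contigs, function(ct) ct$consensus, character(1))), fa)
  status <- system2("mafft", c("--quiet", "--auto", shQuote(fa)), stdout = fo)
  if (status != 0L) stop("mafft failed with status ", status)
  m <- read_alignment_fasta(fo)
  m <- m[match(paste0("s", seq_along(contigs)), rownames(m)), , drop = FALSE]
  rownames(m) <- taxa
  m
}

#' Run the full locus-processing pipeline
#'
#' Chains every stage: read-pair merging, divergent reference assembly with
#' the supporting-read filter, species-constrained orthology clustering with
#' the species-fraction filter, per-locus alignment (coordinate-based by
#' default; supply pre-aligned loci to use an external aligner), masking and
#' site trimming, and supermatrix concatenation.  Outputs are written under
#' `out_dir` when given; the run report is returned either way.
#'
#' @param params a [pipeline_params()].
#' @param read_sets per-sample reads: either a named list of
#'   `c(mate1_path, mate2_path)` FASTQ pairs, or a named list of in-memory
#'   read sets (`id`, `seq1`, `qual1`, `seq2`, `qual2`) as produced by
#'   [simulate_reads()].
#' @param references probe references: FASTA path or named character vector
#'   (one sequence per locus).
#' @param species_map named character vector mapping every sample to its
#'   species.
#' @param aligner how to align each ortholog cluster before masking:
#'   `"offset"` (built-in coordinate stacking, exact for indel-free anchors)
#'   or `"mafft"` (external multiple alignment via the `mafft` executable,
#'   the kind of aligner used in production AHE workflows; required on the
#'   PATH when selected).
#' @param out_dir optional output directory.
#' @return run report (class `ahe_run`): per-sample statistics, per-stage
#'   counts, the retained loci with trimmed alignments, the supermatrix, the
#'   per-species nHomologs table and [per_taxon_stats()].
#' @export
run_pipeline <- function(params, read_sets, references, species_map,
                         aligner = c("offset", "mafft"), out_dir = NULL) {
  stopifnot(inherits(params, "pipeline_params"))
  aligner <- match.arg(aligner)
  if (aligner == "mafft" && Sys.which("mafft") == "")
    stop("aligner = 'mafft' requires the mafft executable on the PATH")
  samples <- names(read_sets)
  if (is.null(samples) || !length(samples)) stop("read_sets must be a named list")
  missing_sp <- setdiff(samples, names(species_map))
  if (length(missing_sp))
    stop("species_map lacks samples: ", paste(missing_sp, collapse = ", "))
  if (is.character(references) && length(references) == 1L &&
      file.exists(references)) {
    fa <- Biostrings::readDNAStringSet(references)
    references <- setNames(as.character(fa), sub("\\s.*$", "", names(fa)))
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1-2: merge and assemble per sample
  all_contigs <- list()
  per_sample <- list()
  for (smp in samples) {
    rs <- read_sets[[smp]]
    if (is.character(rs)) rs <- read_fastq_pairs(rs[1], rs[2])
    if (!length(rs$id)) {
      warning("sample ", smp, " has no reads; carried with no data")
      per_sample[[smp]] <- data.frame(sample = smp, pairs = 0L, merged = 0L,
                                      contigs = 0L, contigs_retained = 0L,
                                      nhomologs = NA_real_)
      next
    }
    mg <- merge_read_set(rs, params$merge_alpha)
    message(sprintf("[%s] %d pairs, %d merged, %d unmerged", smp,
                    mg$summary$pairs_in, mg$summary$merged, mg$summary$unmerged))
    reads <- c(setNames(mg$merged$seq, mg$merged$id),
               setNames(mg$unmerged$seq1, paste0(mg$unmerged$id, "/1")),
               setNames(mg$unmerged$seq2, paste0(mg$unmerged$id, "/2")))
    raw <- assemble_sample(reads, references, params, sample_id = smp,
                           filter = FALSE)
    kept <- filter_contigs(raw, resolve_min_reads(params))
    message(sprintf("[%s] %d contigs assembled, %d retained (>= %d reads)", smp,
                    length(raw), length(kept), resolve_min_reads(params)))
    all_contigs <- c(all_contigs, kept)
    per_sample[[smp]] <- data.frame(sample = smp,
                                    pairs = mg$summary$pairs_in,
                                    merged = mg$summary$merged,
                                    contigs = length(raw),
                                    contigs_retained = length(kept),
                                    nhomologs = NA_real_)
  }
  per_sample <- do.call(rbind, per_sample)

  # stage 3: orthology
  orth <- assess_orthology(all_contigs, species_map, params)
  n_candidates <- nrow(orth$report)
  n_retained <- length(orth$clusters)
  message(sprintf("orthology: %d candidate clusters, %d retained (>= %d%% of %d species)",
                  n_candidates, n_retained,
                  round(100 * params$cluster_min_species_frac),
                  orth$n_species_total))

  # stage 4-5: align (by shared coordinates), mask, trim
  loci <- list()
  trim_report <- list()
  cluster_count <- table(vapply(orth$clusters, function(cl) cl$locus, character(1)))
  for (cl in orth$clusters) {
    nm <- if (cluster_count[[cl$locus]] > 1L)
      sprintf("%s.c%d", cl$locus, sum(names(loci) == cl$locus |
                                        startsWith(names(loci), paste0(cl$locus, ".c"))) + 1L)
    else cl$locus
    taxa_cl <- unname(species_map[vapply(all_contigs[cl$members],
                                         function(ct) ct$sample_id, character(1))])
    aln <- if (aligner == "mafft")
      mafft_align_cluster(all_contigs[cl$members], taxa = taxa_cl)
    else
      offset_align_cluster(all_contigs[cl$members], taxa = taxa_cl)
    tr <- trim_locus(aln, params)
    trim_report[[length(trim_report) + 1L]] <- data.frame(
      locus = nm, cols_in = ncol(aln),
      cols_out = if (tr$dropped) 0L else ncol(tr$alignment),
      masked = tr$n_masked, dropped = tr$dropped, stringsAsFactors = FALSE)
    if (!tr$dropped) loci[[nm]] <- tr$alignment
  }
  trim_report <- if (length(trim_report)) do.call(rbind, trim_report) else NULL
  message(sprintf("trimming: %d of %d loci retained", length(loci), n_retained))

  # stage 6: supermatrix + statistics
  species_all <- sort(unique(unname(species_map[samples])))
  sm <- if (length(loci)) concatenate_loci(loci, all_taxa = species_all) else NULL
  if (is.null(sm)) warning("no loci retained; empty supermatrix")
  stats <- if (length(loci)) per_taxon_stats(loci, all_taxa = species_all) else NULL

  retained_loci <- sort(unique(vapply(orth$clusters, function(cl) cl$locus,
                                      character(1))))
  for (smp in samples) {
    ct_s <- Filter(function(ct) ct$sample_id == smp, all_contigs)
    if (length(ct_s))
      per_sample$nhomologs[per_sample$sample == smp] <-
        suppressMessages(n_homologs(ct_s, retained_loci))
  }

  report <- structure(list(params = params,
                           per_sample = per_sample,
                           contigs = all_contigs,
                           orthology = orth,
                           trim_report = trim_report,
                           loci = loci,
                           supermatrix = sm,
                           per_taxon = stats,
                           counts = list(candidate_clusters = n_candidates,
                                         clusters_retained = n_retained,
                                         loci_final = length(loci))),
                      class = "ahe_run")
  if (!is.null(out_dir)) write_run_outputs(report, out_dir)
  report
}

#' @export
print.ahe_run <- function(x, ...) {
  cat("AHE pipeline run\n")
  cat(sprintf("  samples: %d\n", nrow(x$per_sample)))
  cat(sprintf("  candidate clusters: %d; retained: %d; loci after trimming: %d\n",
              x$counts$candidate_clusters, x$counts$clusters_retained,
              x$counts$loci_final))
  if (!is.null(x$supermatrix))
    cat(sprintf("  supermatrix: %d taxa x %d sites\n",
                nrow(x$supermatrix$matrix), ncol(x$supermatrix$matrix)))
  invisible(x)
}

write_run_outputs <- function(report, out_dir) {
  write_contigs(report$contigs, file.path(out_dir, "contigs.fasta"))
  write.table(report$per_sample, file.path(out_dir, "per_sample.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$orthology$report))
    write.table(report$orthology$report, file.path(out_dir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$trim_report))
    write.table(report$trim_report, file.path(out_dir, "trim_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (nm in names(report$loci))
    write_alignment_fasta(report$loci[[nm]],
                          file.path(aln_dir, paste0(nm, ".fasta")))
  if (!is.null(report$supermatrix)) {
    write_phylip(report$supermatrix, file.path(out_dir, "supermatrix.phy"))
    write_nexus_supermatrix(report$supermatrix, file.path(out_dir, "supermatrix.nex"))
    write_partitions(report$supermatrix, file.path(out_dir, "partitions.txt"))
  }
  if (!is.null(report$per_taxon))
    write.table(report$per_taxon, file.path(out_dir, "per_taxon_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
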