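#' Concatenate trimmed locus alignments into a supermatrix
#'
#' Loci are laid side by side in the order given; taxa absent from a locus
#' are padded with the missing character `?` (distinct from the within-locus
#' gap `-`).  The partition table records each locus's 1-based inclusive
#' column range; ranges are contiguous, non-overlapping and cover every
#' column.
#'
#' @param loci named list of character matrices with taxon rownames; taxon
#'   ids must be unique within each locus.
#' @param all_taxa optional character vector fixing row order (default: the
#'   sorted union of taxa across loci).
#' @return object of class `supermatrix`: list with `matrix` and
#'   `partitions` (data.frame: locus, start, end).
#' @export
concatenate_loci <- function(loci, all_taxa = NULL) {
  if (!length(loci)) stop("nothing to concatenate: zero loci")
  if (is.null(names(loci))) names(loci) <- sprintf("locus%d", seq_along(loci))
  for (nm in names(loci)) {
    tx <- rownames(loci[[nm]])
    if (is.null(tx) || anyDuplicated(tx))
      stop("locus ", nm, " has missing or duplicated taxon ids")
  }
  if (is.null(all_taxa))
    all_taxa <- sort(unique(unlist(lapply(loci, rownames))))
  widths <- vapply(loci, ncol, integer(1))
  total <- sum(widths)
  m <- matrix("?", nrow = length(all_taxa), ncol = total,
              dimnames = list(all_taxa, NULL))
  at <- 0L
  starts <- integer(length(loci)); ends <- integer(length(loci))
  for (k in seq_along(loci)) {
    w <- widths[k]
    starts[k] <- at + 1L
    ends[k] <- at + w
    if (w > 0L) {
      tx <- intersect(all_taxa, rownames(loci[[k]]))
      m[tx, (at + 1L):(at + w)] <- loci[[k]][tx, , drop = FALSE]
    }
    at <- at + w
  }
  structure(list(matrix = m,
                 partitions = data.frame(locus = names(loci),
                                         start = starts, end = ends,
                                         stringsAsFactors = FALSE)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d sites, %d loci\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$partitions)))
  invisible(x)
}

#' Per-taxon sequencing statistics
#'
#' For each taxon: the count of determined nucleotides (characters that are
#' not gaps, not missing and not the mask character) across loci, the number
#' of loci the taxon is present in (any determined character), and the
#' proportion of missing data relative to the total alignment length.
#'
#' @param loci named list of character matrices (as for
#'   [concatenate_loci()]).
#' @param all_taxa optional full taxon set.
#' @return data.frame: taxon, nucleotides, loci_present, prop_missing.
#' @export
per_taxon_stats <- function(loci, all_taxa = NULL) {
  if (is.null(all_taxa))
    all_taxa <- sort(unique(unlist(lapply(loci, rownames))))
  total <- sum(vapply(loci, ncol, integer(1)))
  nuc <- setNames(numeric(length(all_taxa)), all_taxa)
  present <- setNames(integer(length(all_taxa)), all_taxa)
  for (m in loci) {
    for (tx in intersect(all_taxa, rownames(m))) {
      k <- sum(!(m[tx, ] %in% c("-", "?", "N")))
      nuc[tx] <- nuc[tx] + k
      if (k > 0L) present[tx] <- present[tx] + 1L
    }
  }
  data.frame(taxon = all_taxa,
             nucleotides = as.integer(nuc),
             loci_present = as.integer(present),
             prop_missing = if (total > 0) 1 - nuc / total else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Diagnostic neighbor-joining tree from a supermatrix
#'
#' Standard neighbor joining on uncorrected (p) distances with pairwise
#' deletion of non-informative sites.  Intended for validating topology
#' recovery on simulated data, not for publication-grade inference.
#'
#' @param sm a [concatenate_loci()] result (or a bare character matrix).
#' @return an unrooted `phylo` tree.
#' @export
diagnostic_tree <- function(sm) {
  m <- if (inherits(sm, "supermatrix")) sm$matrix else sm
  stopifnot(nrow(m) >= 4L)
  mm <- tolower(m)
  mm[mm == "?"] <- "n"
  dna <- ape::as.DNAbin(mm)
  d <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  bad <- which(!is.finite(dm) & row(dm) < col(dm), arr.ind = TRUE)
  if (nrow(bad))
    stop("taxon pairs with no overlapping sites: ",
         paste(rownames(dm)[bad[, 1]], colnames(dm)[bad[, 2]],
               sep = "-", collapse = ", "))
  ape::nj(d)
}

#' Supermatrix writers and reader
#'
#' `write_phylip()` writes relaxed PHYLIP (full taxon names, single
#' sequential block); `read_phylip()` reads it back.  `write_nexus_supermatrix()`
#' writes a NEXUS data block plus a sets block of per-locus charsets;
#' `write_partitions()` writes RAxML-style partition lines
#' (`DNA, locus = start-end`).
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_phylip <- function(sm, path) {
  m <- sm$matrix
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste0(rownames(m)[i], "  ", paste(m[i, ], collapse = "")), con)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- strsplit(trimws(lines[1 + seq_len(hdr[1])]), "\\s+")
  taxa <- vapply(rows, `[`, character(1), 1L)
  seqs <- vapply(rows, `[`, character(1), 2L)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- taxa
  stopifnot(ncol(m) == hdr[2])
  m
}

#' @rdname write_phylip
#' @export
write_nexus_supermatrix <- function(sm, path) {
  m <- sm$matrix
  seqs <- lapply(seq_len(nrow(m)), function(i) tolower(m[i, ]))
  names(seqs) <- rownames(m)
  ape::write.nexus.data(seqs, path, format = "dna", interleaved = FALSE,
                        gap = "-", missing = "?")
  sets <- c("begin sets;",
            sprintf("  charset %s = %d-%d;",
                    sm$partitions$locus, sm$partitions$start, sm$partitions$end),
            "end;")
  cat(paste(sets, collapse = "\n"), "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}

#' @rdname write_phylip
#' @export
write_partitions <- function(sm, path) {
  writeLines(sprintf("DNA, %s = %d-%d",
                     sm$partitions$locus, sm$partitions$start, sm$partitions$end),
             path)
  invisible(path)
}
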