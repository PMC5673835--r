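#' Spaced-seed window comparison
#'
#' Compares two windows of length `pattern$span` at the pattern's care
#' positions only.  A preliminary match is called when at least `min_matches`
#' care positions carry the same unambiguous base.
#'
#' @param window_a,window_b character scalars, both exactly `pattern$span`
#'   characters long.
#' @param pattern a [spaced_pattern()].
#' @param min_matches pass threshold (default 17 of 20).
#' @return list with `matches` (count over care positions) and `pass`.
#' @export
spaced_seed_match <- function(window_a, window_b, pattern = spaced_pattern(),
                              min_matches = 17L) {
  if (nchar(window_a) != pattern$span || nchar(window_b) != pattern$span)
    stop("both windows must have length ", pattern$span)
  a <- strsplit(toupper(window_a), "", fixed = TRUE)[[1]][pattern$mask]
  b <- strsplit(toupper(window_b), "", fixed = TRUE)[[1]][pattern$mask]
  m <- sum(a == b & a %in% DNA_BASES)
  list(matches = m, pass = m >= min_matches)
}

#' Confirm a preliminary read placement
#'
#' A placement at `offset` (0-based position of the read's first base on the
#' reference) is confirmed when some window of `window` consecutive aligned
#' positions contains at least `min_matches` identities.  Near contig ends,
#' where fewer than `window` aligned positions exist, the whole available
#' overlap is evaluated proportionally (`matches/overlap >= min_matches/window`)
#' provided at least `min_len` positions align.
#'
#' @param read,reference character scalars.
#' @param offset 0-based alignment offset of the read on the reference (may
#'   be negative for left overhangs).
#' @param window,min_matches confirmation window and threshold.
#' @param min_len smallest overlap evaluated under the proportional rule.
#' @return logical pass/fail, with attribute `matches` (best window count).
#' @export
confirm_match <- function(read, reference, offset, window = 100L,
                          min_matches = 55L, min_len = 50L) {
  r <- strsplit(toupper(read), "", fixed = TRUE)[[1]]
  s <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  lo <- max(0L, -offset)
  hi <- min(length(r), length(s) - offset)
  if (hi <= lo) return(structure(FALSE, matches = 0L))
  idx <- (lo + 1L):hi
  match <- as.integer(r[idx] == s[idx + offset] & r[idx] %in% DNA_BASES)
  ov <- length(match)
  if (ov >= window) {
    cs <- cumsum(c(0L, match))
    wins <- cs[(window + 1L):(ov + 1L)] - cs[1:(ov - window + 1L)]
    best <- max(wins)
    structure(best >= min_matches, matches = best)
  } else if (ov >= min_len) {
    best <- sum(match)
    structure(best / ov >= min_matches / window, matches = best)
  } else {
    structure(FALSE, matches = sum(match))
  }
}

#' Assemble one locus for one sample by divergent reference assembly
#'
#' Iteratively recruits reads to the current consensus (initially the probe
#' reference) using spaced-seed preliminary matching confirmed by the
#' consecutive-base rule, places recruited reads ungapped at their seed
#' offsets, recalls the consensus (majority base, IUPAC ambiguity when the
#' second base reaches 30% of depth), and extends left and right into the
#' flanks wherever extension depth reaches `extension_min_depth`.  Iteration
#' stops when no new read is recruited.  If the recruited reads contain at
#' least `homolog_min_sites` bimodal conflicting sites that phase into two
#' internally consistent groups, the contig is split into two homolog
#' consensus sequences.
#'
#' Reads are sorted by id before recruitment, which makes the procedure
#' deterministic for any input order.
#'
#' @param reads character vector of read sequences (merged reads and both
#'   mates of unmerged pairs), named by read id.  Mates of one pair should
#'   share an id up to a `/1`/`/2` suffix so that the pair counts as a single
#'   supporting fragment.
#' @param reference probe-region reference sequence for the locus.
#' @param params a [pipeline_params()].
#' @param locus_id,sample_id labels carried into the contigs.
#' @return list of contigs (possibly empty).  Each contig is a list with
#'   `locus_id`, `sample_id`, `homolog`, `consensus`, `n_reads` (supporting
#'   fragments), `depth` (per consensus column), `start` (0-based offset of
#'   the consensus on the reference coordinate system), `anchor_start`,
#'   `anchor_end` (1-based interval of the consensus overlapping the
#'   reference, NA when none), and `read_ids`.
#' @export
assemble_locus <- function(reads, reference, params = pipeline_params(),
                           locus_id = "locus", sample_id = "sample") {
  if (length(reads) == 0) return(list())
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  ord <- order(ids)
  reads <- toupper(unname(reads[ord]))
  ids <- ids[ord]
  pat <- spaced_pattern(params$spaced_mask)
  reference <- toupper(reference)
  ref_len <- nchar(reference)

  cons <- reference
  start <- 0L  # reference coordinate of cons[1]
  rec_idx <- integer(0)   # indices into reads
  rec_off <- integer(0)   # global (reference-frame) offsets
  rec_seq <- character(0) # oriented sequences

  for (iter in seq_len(30L)) {
    cand <- setdiff(seq_along(reads), rec_idx)
    if (!length(cand)) break
    res <- recruit_reads_cpp(cons, reads[cand], pat$care0, pat$span,
                             params$seed_min_matches, params$confirm_window,
                             params$confirm_min_matches, 50L, 11L, 8L)
    hit <- which(res$pass == 1L)
    if (!length(hit)) break
    idx <- cand[hit]
    newseq <- reads[idx]
    rcsel <- res$orient[hit] == 1L
    if (any(rcsel)) newseq[rcsel] <- vapply(newseq[rcsel], revcomp_cpp, character(1))
    rec_idx <- c(rec_idx, idx)
    rec_seq <- c(rec_seq, newseq)
    rec_off <- c(rec_off, res$offset[hit] + start)

    rb <- rebuild_consensus(rec_seq, rec_off, cons, start, params)
    cons <- rb$cons
    start <- rb$start
  }

  if (!length(rec_idx)) return(list())
  finish_locus(rec_seq, rec_off, ids[rec_idx], start, nchar(cons), ref_len,
               params, locus_id, sample_id)
}

# Recall the working consensus over the union of the recruited reads and the
# current span; extension beyond the previous span requires contiguous depth
# of at least extension_min_depth, and previous backbone characters are kept
# where reads give no information yet.
rebuild_consensus <- function(rec_seq, rec_off, cons, start, params) {
  lo <- min(c(rec_off, start))
  hi <- max(c(rec_off + nchar(rec_seq), start + nchar(cons)))
  counts <- pile_cpp(rec_seq, rec_off, lo, hi - lo)
  depth <- colSums(counts[1:4, , drop = FALSE])
  prev_lo <- start - lo + 1L
  prev_hi <- prev_lo + nchar(cons) - 1L
  left <- prev_lo
  while (left > 1L && depth[left - 1L] >= params$extension_min_depth)
    left <- left - 1L
  right <- prev_hi
  while (right < length(depth) && depth[right + 1L] >= params$extension_min_depth)
    right <- right + 1L
  newchars <- consensus_from_counts(counts[, left:right, drop = FALSE])
  prevchars <- strsplit(cons, "", fixed = TRUE)[[1]]
  for (z in which(depth[left:right] == 0L)) {
    g <- left + z - 1L
    if (g >= prev_lo && g <= prev_hi) newchars[z] <- prevchars[g - prev_lo + 1L]
  }
  list(cons = paste(newchars, collapse = ""), start = lo + left - 1L)
}

# Homolog splitting, finalization and deterministic homolog numbering for one
# locus's recruited reads.
finish_locus <- function(rec_seq, rec_off, rec_ids, span_lo, span_len, ref_len,
                         params, locus_id, sample_id) {
  groups <- split_homologs(rec_seq, rec_off, span_lo, span_len, params)
  contigs <- lapply(groups, function(g) {
    finalize_contig(rec_seq[g], rec_off[g], rec_ids[g],
                    span_lo, span_len, ref_len, locus_id, sample_id)
  })
  contigs <- Filter(Negate(is.null), contigs)
  if (!length(contigs)) return(list())
  # larger support first, then sequence order
  o <- order(-vapply(contigs, function(ct) ct$n_reads, numeric(1)),
             vapply(contigs, function(ct) ct$consensus, character(1)))
  contigs <- contigs[o]
  for (k in seq_along(contigs)) contigs[[k]]$homolog <- sprintf("h%d", k)
  contigs
}

# Build the final consensus for one read group: trim to the read-covered range
# inside the working span, call majority/IUPAC bases, N at interior zero-depth.
finalize_contig <- function(seqs, offs, read_ids, span_lo, span_len, ref_len,
                            locus_id, sample_id) {
  counts <- pile_cpp(seqs, offs, span_lo, span_len)
  depth <- colSums(counts[1:4, , drop = FALSE])
  cov <- which(depth > 0L)
  if (!length(cov)) return(NULL)
  a <- min(cov); b <- max(cov)
  chars <- consensus_from_counts(counts[, a:b, drop = FALSE])
  g_start <- span_lo + a - 1L
  g_end <- span_lo + b - 1L
  ov_lo <- max(g_start, 0L)
  ov_hi <- min(g_end, ref_len - 1L)
  frag_ids <- unique(sub("/[12]$", "", read_ids))
  list(locus_id = locus_id, sample_id = sample_id, homolog = "h1",
       consensus = paste(chars, collapse = ""),
       n_reads = length(frag_ids),
       depth = depth[a:b],
       start = g_start,
       anchor_start = if (ov_lo <= ov_hi) ov_lo - g_start + 1L else NA_integer_,
       anchor_end = if (ov_lo <= ov_hi) ov_hi - g_start + 1L else NA_integer_,
       read_ids = read_ids)
}

# Detect bimodal conflicting sites and try to phase reads into two internally
# consistent groups.  Returns a list of read-index groups (length 1 = no
# split).  Reads carrying no informative allele are assigned to both groups.
split_homologs <- function(seqs, offs, span_lo, span_len, params) {
  all_idx <- seq_along(seqs)
  counts <- pile_cpp(seqs, offs, span_lo, span_len)
  acgt <- counts[1:4, , drop = FALSE]
  depth <- colSums(acgt)
  top1 <- apply(acgt, 2L, which.max)
  # second-highest count per column
  c2 <- vapply(seq_len(ncol(acgt)), function(j) {
    v <- acgt[, j]; v[top1[j]] <- -1L; max(v)
  }, integer(1))
  conflict <- which(c2 >= 3L & c2 >= 0.3 * depth)
  if (length(conflict) < params$homolog_min_sites) return(list(all_idx))
  top2 <- vapply(conflict, function(j) {
    v <- acgt[, j]; v[top1[j]] <- -1L; which.max(v)
  }, integer(1))
  # allele matrix: 0 = major base, 1 = second base, NA otherwise/uncovered
  n <- length(seqs)
  A <- matrix(NA_integer_, n, length(conflict))
  for (r in seq_len(n)) {
    s <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
    pos <- conflict - (offs[r] - span_lo) # 1-based positions within the read
    ok <- pos >= 1L & pos <= length(s)
    if (!any(ok)) next
    bc <- match(s[pos[ok]], DNA_BASES)
    al <- ifelse(bc == top1[conflict[ok]], 0L,
                 ifelse(bc == top2[match(conflict[ok], conflict)], 1L, NA_integer_))
    A[r, ok] <- al
  }
  informative <- which(rowSums(!is.na(A)) > 0)
  if (length(informative) < 6L) return(list(all_idx))
  seedr <- informative[which.max(rowSums(!is.na(A[informative, , drop = FALSE])))]
  profA <- A[seedr, ]
  profB <- 1L - profA
  grpA <- logical(n)
  for (it in seq_len(10L)) {
    prev <- grpA
    for (r in informative) {
      both <- !is.na(A[r, ]) & !is.na(profA)
      if (!any(both)) { grpA[r] <- TRUE; next }
      sa <- mean(A[r, both] == profA[both])
      grpA[r] <- sa >= 0.5
    }
    # re-estimate profiles as per-site majorities within groups
    for (j in seq_along(conflict)) {
      va <- A[informative[grpA[informative]], j]
      vb <- A[informative[!grpA[informative]], j]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      profA[j] <- if (length(va)) as.integer(mean(va) >= 0.5) else NA_integer_
      profB[j] <- if (length(vb)) as.integer(mean(vb) >= 0.5) else NA_integer_
    }
    if (identical(prev, grpA)) break
  }
  ia <- informative[grpA[informative]]
  ib <- informative[!grpA[informative]]
  if (length(ia) < 3L || length(ib) < 3L) return(list(all_idx))
  # internal consistency: fraction of informative allele calls agreeing with
  # the caller's own group profile
  agree <- 0L; tot <- 0L
  for (r in informative) {
    prof <- if (grpA[r]) profA else profB
    both <- !is.na(A[r, ]) & !is.na(prof)
    agree <- agree + sum(A[r, both] == prof[both])
    tot <- tot + sum(both)
  }
  if (tot == 0L || agree / tot < 0.9) return(list(all_idx))
  shared <- setdiff(all_idx, informative)
  list(c(ia, shared), c(ib, shared))
}

#' Remove weakly supported contigs
#'
#' Retains exactly the contigs supported by at least `min_reads` fragments,
#' the filter used to suppress cross-contamination and index-read errors.
#'
#' @param contigs list of contigs from [assemble_locus()].
#' @param min_reads minimum supporting fragment count (default 23).
#' @return the retained contigs.
#' @export
filter_contigs <- function(contigs, min_reads = 23L) {
  Filter(function(ct) ct$n_reads >= min_reads, contigs)
}

#' Assemble every locus of one sample
#'
#' Pooled multi-locus version of [assemble_locus()]: all locus consensuses
#' grow simultaneously and each round scans only the still-unassigned reads
#' against a combined index over every current consensus (loci separated by
#' runs of `N`, which no word or seed window can cross).  Each recruited read
#' is assigned to the locus holding its best seed window and leaves the pool,
#' so the pass count stays linear in the read number rather than scaling with
#' the locus count.  Recruitment, confirmation, consensus calling, extension
#' and homolog splitting follow [assemble_locus()] exactly; the
#' supporting-read filter is applied at the end.
#'
#' @param reads named character vector of read sequences (see
#'   [assemble_locus()]).
#' @param references named character vector of probe reference sequences, one
#'   per locus.
#' @param params a [pipeline_params()].
#' @param sample_id sample label.
#' @param filter apply [filter_contigs()] before returning (default TRUE).
#' @return list of retained contigs across loci.
#' @export
assemble_sample <- function(reads, references, params = pipeline_params(),
                            sample_id = "sample", filter = TRUE) {
  if (!length(reads) || !length(references)) return(list())
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  ord <- order(ids)
  reads <- toupper(unname(reads[ord]))
  ids <- ids[ord]
  pat <- spaced_pattern(params$spaced_mask)
  nl <- length(references)
  loci <- names(references)
  cons <- toupper(unname(unlist(references)))
  ref_len <- nchar(cons)
  starts <- rep(0L, nl)
  rec <- lapply(seq_len(nl), function(i)
    list(seq = character(0), off = integer(0), ids = character(0)))
  pool <- seq_along(reads)
  sep <- strrep("N", 100L)

  for (iter in seq_len(60L)) {
    if (!length(pool)) break
    lens <- nchar(cons)
    beg <- cumsum(c(0L, (lens + 100L)[-nl]))  # 0-based combined start per locus
    combined <- paste(cons, collapse = sep)
    res <- recruit_reads_cpp(combined, reads[pool], pat$care0, pat$span,
                             params$seed_min_matches, params$confirm_window,
                             params$confirm_min_matches, 50L, 11L, 8L)
    hit <- which(res$pass == 1L)
    if (!length(hit)) break
    lc <- pmin(pmax(findInterval(res$seedpos[hit], beg), 1L), nl)
    oriented <- reads[pool[hit]]
    rcsel <- res$orient[hit] == 1L
    if (any(rcsel))
      oriented[rcsel] <- vapply(oriented[rcsel], revcomp_cpp, character(1))
    loc_off <- res$offset[hit] - beg[lc] + starts[lc]
    for (u in unique(lc)) {
      sel <- which(lc == u)
      rec[[u]]$seq <- c(rec[[u]]$seq, oriented[sel])
      rec[[u]]$off <- c(rec[[u]]$off, loc_off[sel])
      rec[[u]]$ids <- c(rec[[u]]$ids, ids[pool[hit[sel]]])
      rb <- rebuild_consensus(rec[[u]]$seq, rec[[u]]$off, cons[u], starts[u],
                              params)
      cons[u] <- rb$cons
      starts[u] <- rb$start
    }
    pool <- pool[-hit]
  }

  contigs <- list()
  for (u in seq_len(nl)) {
    if (!length(rec[[u]]$seq)) next
    contigs <- c(contigs,
                 finish_locus(rec[[u]]$seq, rec[[u]]$off, rec[[u]]$ids,
                              starts[u], nchar(cons[u]), ref_len[u],
                              params, loci[u], sample_id))
  }
  if (filter) filter_contigs(contigs, resolve_min_reads(params)) else contigs
}

#' Write contigs as FASTA
#'
#' Headers follow `locus|sample|homologN|nreads`.
#'
#' @param contigs list of contigs.
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
write_contigs <- function(contigs, path) {
  if (!length(contigs)) { file.create(path); return(invisible(path)) }
  x <- Biostrings::DNAStringSet(vapply(contigs, function(ct) ct$consensus, character(1)))
  names(x) <- vapply(contigs, function(ct)
    sprintf("%s|%s|%s|%d", ct$locus_id, ct$sample_id, ct$homolog, ct$n_reads),
    character(1))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
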