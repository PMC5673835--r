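#' Probability of an observed overlap match count arising by chance
#'
#' For a candidate overlap of `overlap_len` aligned positions between two
#' reads, the number of matching bases under the null hypothesis of unrelated
#' sequences is binomial with success probability 1/4 (uniform base
#' composition).  The returned value is the upper tail `P(X >= m)` where `m`
#' is the observed number of matching informative positions.  Positions where
#' either base is ambiguous (`N`) are uninformative and excluded from both the
#' trial count and the match count; if no informative positions remain the
#' probability is 1.
#'
#' `seq_b` must already be reverse-complemented into `seq_a`'s orientation:
#' the overlap aligns the last `overlap_len` bases of `seq_a` with the first
#' `overlap_len` bases of `seq_b`.
#'
#' @param seq_a,seq_b character scalars over `{A,C,G,T,N}`.
#' @param overlap_len candidate overlap length, `1 <= overlap_len <=
#'   min(nchar(seq_a), nchar(seq_b))`.
#' @return the tail probability, a number in `[0, 1]`.
#' @export
overlap_pvalue <- function(seq_a, seq_b, overlap_len) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (overlap_len < 1 || overlap_len > min(la, lb))
    stop("overlap_len must be in 1..min(length a, length b)")
  a <- substr(seq_a, la - overlap_len + 1L, la)
  b <- substr(seq_b, 1L, overlap_len)
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  inf <- ca %in% DNA_BASES & cb %in% DNA_BASES
  n <- sum(inf)
  if (n == 0) return(1)
  m <- sum(ca[inf] == cb[inf])
  pbinom(m - 1L, n, 0.25, lower.tail = FALSE)
}

#' Merge one read pair by lowest-probability overlap
#'
#' Every candidate overlap length `1..min(len1, len2)` is scored by
#' [overlap_pvalue()]; the overlap with the smallest probability is selected
#' (ties broken toward the longest overlap) and the pair is merged iff that
#' probability is below `alpha`.  In the merged overlap, disagreeing bases
#' take the base of the mate with the higher Phred score (ties favour mate 1)
#' with quality `|q1 - q2|`; agreeing bases get quality `min(q1 + q2, 93)`.
#' Pairs failing the threshold are reported unmerged and pass through the
#' pipeline unchanged.
#'
#' @param pair list with `seq1`, `qual1`, `seq2`, `qual2` (mate 2 in raw
#'   sequencing orientation, i.e. reverse-complement strand) and optionally
#'   `id`.
#' @param alpha acceptance threshold on the overlap probability.
#' @return list with `status` ("merged"/"unmerged"), `overlap_len`,
#'   `p_value`, and for merged pairs `merged_seq`, `merged_qual`.
#' @export
merge_pair <- function(pair, alpha = 1e-10) {
  r <- merge_pairs_cpp(toupper(pair$seq1), pair$qual1,
                       toupper(pair$seq2), pair$qual2, alpha)
  if (r$status[1] == "merged") {
    list(status = "merged", merged_seq = r$merged_seq[1],
         merged_qual = r$merged_qual[1],
         overlap_len = r$overlap_len[1], p_value = r$p_value[1])
  } else {
    list(status = "unmerged", overlap_len = r$overlap_len[1],
         p_value = r$p_value[1])
  }
}

#' Merge all pairs of a paired FASTQ set
#'
#' Reads two synchronous FASTQ files (same ids, same order), merges each pair
#' with [merge_pair()], and writes the merged reads plus the still-paired
#' unmerged reads.  Every input pair lands in exactly one output stream.
#'
#' @param in1,in2 FASTQ paths for mates 1 and 2 (Phred+33).
#' @param out_prefix output prefix; writes `<prefix>_merged.fastq`,
#'   `<prefix>_unmerged_R1.fastq`, `<prefix>_unmerged_R2.fastq`.
#' @param alpha overlap acceptance threshold.
#' @return summary list: `pairs_in`, `merged`, `unmerged`, `median_overlap`
#'   (median accepted overlap length, NA when nothing merged).
#' @export
merge_fastq <- function(in1, in2, out_prefix, alpha = 1e-10) {
  prs <- read_fastq_pairs(in1, in2)
  res <- merge_read_set(prs, alpha)
  write_fastq(res$merged$id, res$merged$seq, res$merged$qual,
              paste0(out_prefix, "_merged.fastq"))
  write_fastq(res$unmerged$id, res$unmerged$seq1, res$unmerged$qual1,
              paste0(out_prefix, "_unmerged_R1.fastq"))
  write_fastq(res$unmerged$id, res$unmerged$seq2, res$unmerged$qual2,
              paste0(out_prefix, "_unmerged_R2.fastq"))
  res$summary
}

# in-memory merge of a read set (list of id/seq1/qual1/seq2/qual2 vectors)
merge_read_set <- function(prs, alpha = 1e-10) {
  n <- length(prs$id)
  if (n == 0L) {
    return(list(merged = list(id = character(0), seq = character(0),
                              qual = character(0), overlap_len = integer(0)),
                unmerged = list(id = character(0),
                                seq1 = character(0), qual1 = character(0),
                                seq2 = character(0), qual2 = character(0)),
                summary = list(pairs_in = 0L, merged = 0L, unmerged = 0L,
                               median_overlap = NA_real_)))
  }
  r <- merge_pairs_cpp(toupper(prs$seq1), prs$qual1,
                       toupper(prs$seq2), prs$qual2, alpha)
  mg <- which(r$status == "merged")
  um <- which(r$status != "merged")
  list(merged = list(id = prs$id[mg], seq = r$merged_seq[mg],
                     qual = r$merged_qual[mg], overlap_len = r$overlap_len[mg]),
       unmerged = list(id = prs$id[um],
                       seq1 = prs$seq1[um], qual1 = prs$qual1[um],
                       seq2 = prs$seq2[um], qual2 = prs$qual2[um]),
       summary = list(pairs_in = n, merged = length(mg), unmerged = length(um),
                      median_overlap = if (length(mg)) median(r$overlap_len[mg])
                      else NA_real_))
}
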