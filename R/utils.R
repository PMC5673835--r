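# Small shared helpers: alphabet handling, Phred conversion, seed derivation.

DNA_BASES <- c("A", "C", "G", "T")

# two-base IUPAC ambiguity codes, keyed by the sorted base pair
IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the IUPAC alphabet. Characters outside
#' the alphabet become `N`; gaps are preserved.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, revcomp_cpp, character(1), USE.NAMES = FALSE)
}

phred_to_chars <- function(q) {
  vapply(q, function(v) intToUtf8(pmin(v, 93L) + 33L), character(1))
}

chars_to_phred <- function(s) {
  lapply(s, function(v) utf8ToInt(v) - 33L)
}

# Deterministic per-stage substream: stages can be re-run in isolation and the
# full run stays reproducible from one seed.  Kept below 2^31.
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(stage) * 7919L
}

seq_to_int <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
}

int_to_seq <- function(v) {
  paste(DNA_BASES[v], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# majority/IUPAC consensus from a 5 x L count matrix (rows A,C,G,T,other)
consensus_from_counts <- function(counts, ambig_frac = 0.30) {
  acgt <- counts[1:4, , drop = FALSE]
  depth <- colSums(acgt)
  L <- ncol(acgt)
  out <- character(L)
  for (j in seq_len(L)) {
    if (depth[j] == 0L) { out[j] <- "N"; next }
    cj <- acgt[, j]
    top <- which.max(cj)
    c2 <- cj
    c2[top] <- -1L
    second <- which.max(c2)
    if (cj[second] > 0L && cj[second] >= ambig_frac * depth[j]) {
      key <- paste(sort(DNA_BASES[c(top, second)]), collapse = "")
      out[j] <- IUPAC2[[key]]
    } else {
      out[j] <- DNA_BASES[top]
    }
  }
  out
}
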