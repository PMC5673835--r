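# Independent reference implementations used as oracles.  These deliberately
# use naive loops and a different code path from the package internals.

# P(X >= m) for X ~ Binomial(n, p), by dynamic programming over single trials
# (no binomial coefficients, no pbinom)
binom_tail_dp <- function(n, m, p = 0.25) {
  probs <- 1
  for (i in seq_len(n)) probs <- c(probs * (1 - p), 0) + c(0, probs * p)
  if (m <= 0) return(1)
  sum(probs[(m + 1):(n + 1)])
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

naive_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# set-based k-mer distance by explicit loops
naive_kmer_distance <- function(a, b, k = 20, mask = "111011101110111011111111") {
  bits <- strsplit(mask, "")[[1]] == "1"
  span <- length(bits)
  if (nchar(a) < span || nchar(b) < span) return(1)
  kms <- function(s, kk) {
    out <- character(0)
    for (i in seq_len(nchar(s) - kk + 1)) out <- c(out, substr(s, i, i + kk - 1))
    unique(out)
  }
  spk <- function(s) {
    out <- character(0)
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(length(ch) - span + 1)) {
      w <- ch[i:(i + span - 1)]
      out <- c(out, paste(w[bits], collapse = ""))
    }
    unique(out)
  }
  contain <- function(x, y) {
    if (!length(x) || !length(y)) return(0)
    sum(x %in% y) / min(length(x), length(y))
  }
  1 - (contain(kms(a, k), kms(b, k)) + contain(spk(a), spk(b))) / 2
}

# step-by-step masking + trimming reference implementation
naive_trim <- function(aln, window = 20, min_match = 10, conserved_frac = 0.5,
                       min_unmasked = 23, mask_char = "N") {
  n <- nrow(aln)
  L <- ncol(aln)
  common <- rep(NA_character_, L)
  conserved <- logical(L)
  for (j in seq_len(L)) {
    col <- aln[, j]
    col <- col[col != "-"]
    if (!length(col)) next
    tab <- table(col)
    mx <- max(tab)
    common[j] <- sort(names(tab)[tab == mx])[1]
    conserved[j] <- (mx / n) > conserved_frac
  }
  cc <- which(conserved)
  masked <- aln
  if (length(cc) > 0 && length(cc) < window) {
    for (r in seq_len(n)) {
      if (sum(aln[r, cc] == common[cc]) / length(cc) < min_match / window) {
        row <- masked[r, ]
        row[row != "-"] <- mask_char
        masked[r, ] <- row
      }
    }
  } else if (length(cc) >= window) {
    nw <- length(cc) - window + 1
    for (r in seq_len(n)) {
      passes <- logical(nw)
      for (w in seq_len(nw))
        passes[w] <- sum(aln[r, cc[w:(w + window - 1)]] ==
                           common[cc[w:(w + window - 1)]]) >= min_match
      for (j in seq_len(L)) {
        covering <- integer(0)
        for (w in seq_len(nw)) {
          lo <- if (w == 1) 1 else cc[w]
          hi <- if (w == nw) L else cc[w + window - 1]
          if (j >= lo && j <= hi) covering <- c(covering, w)
        }
        if (length(covering) && !any(passes[covering]) && aln[r, j] != "-")
          masked[r, j] <- mask_char
      }
    }
  }
  keep <- which(colSums(!(masked == "-" | masked == mask_char | masked == "?")) >=
                  min_unmasked)
  list(alignment = masked[, keep, drop = FALSE], kept = keep)
}

# random alignment: a clean consensus-derived block plus optional junk rows,
# gaps, and mutations
random_alignment <- function(n_taxa, n_cols, p_mut = 0.1, p_gap = 0.05,
                             n_junk = 0) {
  base <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
  m <- matrix(rep(base, each = n_taxa), nrow = n_taxa)
  mut <- matrix(runif(n_taxa * n_cols) < p_mut, n_taxa, n_cols)
  m[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
  gap <- matrix(runif(n_taxa * n_cols) < p_gap, n_taxa, n_cols)
  m[gap] <- "-"
  if (n_junk > 0) {
    rows <- sample(n_taxa, n_junk)
    for (r in rows)
      m[r, ] <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
  }
  rownames(m) <- sprintf("tx%02d", seq_len(n_taxa))
  m
}

# minimal contig stub for filter tests
stub_contig <- function(n_reads, locus = "L001", sample = "s1", seq = NULL) {
  list(locus_id = locus, sample_id = sample, homolog = "h1",
       consensus = seq %||% paste(rep("A", 100), collapse = ""),
       n_reads = n_reads, depth = rep(n_reads, 100), start = 0L,
       anchor_start = 1L, anchor_end = 100L, read_ids = character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
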