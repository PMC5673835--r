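test_that("spaced-seed matching counts care positions only", {
  pat <- spaced_pattern()
  w <- strrep("ACGTAC", 4)
  expect_equal(spaced_seed_match(w, w, pat)$matches, 20)
  expect_true(spaced_seed_match(w, w, pat)$pass)
  # flip characters at exactly 3 care positions: boundary pass at 17/20
  care <- which(pat$mask)
  flip <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- chartr("ACGT", "GTAC", ch[pos])  # always a different base
    paste(ch, collapse = "")
  }
  w3 <- flip(w, care[c(1, 5, 9)])
  r3 <- spaced_seed_match(w, w3, pat)
  expect_equal(r3$matches, 17)
  expect_true(r3$pass)
  w4 <- flip(w, care[c(1, 5, 9, 13)])
  r4 <- spaced_seed_match(w, w4, pat)
  expect_equal(r4$matches, 16)
  expect_false(r4$pass)
  # mismatches at ignored positions do not count
  ign <- which(!pat$mask)
  expect_equal(spaced_seed_match(w, flip(w, ign), pat)$matches, 20)
  expect_error(spaced_seed_match("ACGT", w, pat))
})

test_that("confirmation requires 55 matches in a 100-base window", {
  set.seed(31)
  ref <- random_dna(1, 300)
  expect_true(confirm_match(substr(ref, 51, 150), ref, 50))
  # exactly 55 matches of 100: boundary pass
  r100 <- substr(ref, 101, 200)
  ch <- strsplit(r100, "")[[1]]
  kill <- sample(100, 45)
  ch[kill] <- chartr("ACGT", "GTAC", ch[kill])  # guaranteed mismatches
  expect_true(confirm_match(paste(ch, collapse = ""), ref, 100))
  # one more mismatch: 54/100 fails
  left <- setdiff(seq_len(100), kill)[1]
  ch[left] <- chartr("ACGT", "GTAC", ch[left])
  expect_false(confirm_match(paste(ch, collapse = ""), ref, 100))
  # an unrelated read (~25% chance matches) fails
  expect_false(confirm_match(random_dna(1, 100), ref, 100))
  # short overlap at a contig end: proportional rule over >= 50 bases
  expect_true(confirm_match(substr(ref, 1, 60), ref, 0))
  expect_false(confirm_match(substr(ref, 1, 30), ref, 0))
})

# n_frags fragments tiling the locus; three extra fragments pinned at each
# end so terminal depth reaches the extension threshold
make_locus_reads <- function(truth_seq, n_frags, frag_len = 240, read_len = 150,
                             prefix = "r") {
  L <- nchar(truth_seq)
  starts <- c(rep(1, 3),
              floor(seq(1, L - frag_len + 1, length.out = n_frags - 6)),
              rep(L - frag_len + 1, 3))
  frags <- substring(truth_seq, starts, starts + frag_len - 1)
  reads <- c(substr(frags, 1, read_len),
             vapply(frags, function(f)
               naive_revcomp(substr(f, nchar(f) - read_len + 1, nchar(f))),
               character(1), USE.NAMES = FALSE))
  names(reads) <- c(sprintf("%s%04d/1", prefix, seq_len(n_frags)),
                    sprintf("%s%04d/2", prefix, seq_len(n_frags)))
  reads
}

test_that("zero-error assembly reproduces the truth sequence beyond the anchor", {
  set.seed(33)
  truth <- random_dna(1, 700)
  ref <- substr(truth, 201, 500)     # the anchor region
  reads <- make_locus_reads(truth, 60)
  ct <- assemble_locus(reads, ref, pipeline_params(), "L1", "s1")
  expect_length(ct, 1)
  expect_equal(ct[[1]]$n_reads, 60)  # mates collapse to fragments
  expect_equal(ct[[1]]$consensus, truth)
  expect_equal(ct[[1]]$start, -200)  # extended 200 bases left of the anchor
  expect_equal(substr(ct[[1]]$consensus, ct[[1]]$anchor_start,
                      ct[[1]]$anchor_end), ref)
  expect_equal(length(ct[[1]]$depth), nchar(truth))
  # every supporting read passes confirmation against the final consensus
  for (id in sample(ct[[1]]$read_ids, 10)) {
    r <- reads[[id]]
    ok <- confirm_match(r, ct[[1]]$consensus, 0) ||
      confirm_match(naive_revcomp(r), ct[[1]]$consensus, 0)
    idx <- regexpr(r, ct[[1]]$consensus, fixed = TRUE)
    idx2 <- regexpr(naive_revcomp(r), ct[[1]]$consensus, fixed = TRUE)
    off <- max(idx, idx2) - 1
    expect_true(confirm_match(if (idx > 0) r else naive_revcomp(r),
                              ct[[1]]$consensus, off))
  }
})

test_that("reads from a different locus never seed a contig", {
  set.seed(34)
  reads <- make_locus_reads(random_dna(1, 700), 40)
  ref <- random_dna(1, 300)
  expect_length(assemble_locus(reads, ref, pipeline_params(), "L1", "s1"), 0)
  expect_length(assemble_locus(character(0), ref, pipeline_params()), 0)
})

test_that("assembly is invariant to read order", {
  set.seed(35)
  truth <- random_dna(1, 600)
  reads <- make_locus_reads(truth, 40)
  ct1 <- assemble_locus(reads, substr(truth, 151, 450), pipeline_params())
  ct2 <- assemble_locus(rev(reads), substr(truth, 151, 450), pipeline_params())
  expect_equal(ct1[[1]]$consensus, ct2[[1]]$consensus)
  expect_equal(ct1[[1]]$n_reads, ct2[[1]]$n_reads)
})

test_that("a diverged paralog is split into two homolog consensuses", {
  set.seed(36)
  truth_a <- random_dna(1, 700)
  # 5% divergence for the duplicate copy
  ch <- strsplit(truth_a, "")[[1]]
  mut <- sample(700, 35)
  ch[mut] <- chartr("ACGT", "GTAC", ch[mut])
  truth_b <- paste(ch, collapse = "")
  reads <- c(make_locus_reads(truth_a, 40, prefix = "a"),
             make_locus_reads(truth_b, 40, prefix = "b"))
  ct <- assemble_locus(reads, substr(truth_a, 201, 500), pipeline_params(),
                       "L1", "s1")
  expect_length(ct, 2)
  expect_setequal(vapply(ct, function(x) x$homolog, character(1)), c("h1", "h2"))
  expect_setequal(vapply(ct, function(x) x$consensus, character(1)),
                  c(truth_a, truth_b))
  expect_true(all(vapply(ct, function(x) x$n_reads, numeric(1)) >= 40))
})

test_that("single-copy loci are not split", {
  set.seed(37)
  truth <- random_dna(1, 700)
  reads <- make_locus_reads(truth, 80)
  ct <- assemble_locus(reads, substr(truth, 201, 500), pipeline_params())
  expect_length(ct, 1)
})

test_that("the supporting-read filter keeps 23 and removes 22", {
  contigs <- list(stub_contig(23), stub_contig(22), stub_contig(100))
  kept <- filter_contigs(contigs, 23)
  expect_equal(vapply(kept, function(ct) ct$n_reads, numeric(1)), c(23, 100))
})

test_that("pooled multi-locus assembly agrees with per-locus assembly", {
  set.seed(38)
  truths <- random_dna(3, 650)
  refs <- setNames(substr(truths, 151, 500), sprintf("L%03d", 1:3))
  reads <- unlist(lapply(1:3, function(i)
    make_locus_reads(truths[i], 45, prefix = sprintf("x%d_", i))))
  pooled <- assemble_sample(reads, refs, pipeline_params(), "s1")
  expect_length(pooled, 3)
  for (i in 1:3) {
    single <- assemble_locus(reads, refs[[i]], pipeline_params(),
                             sprintf("L%03d", i), "s1")
    match_idx <- which(vapply(pooled, function(ct) ct$locus_id,
                              character(1)) == sprintf("L%03d", i))
    expect_equal(pooled[[match_idx]]$consensus, single[[1]]$consensus)
    expect_equal(pooled[[match_idx]]$n_reads, single[[1]]$n_reads)
  }
})
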