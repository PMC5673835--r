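# seq_b below is always given already reverse-complemented into seq_a's
# orientation, as the overlap model requires.

test_that("overlap probability matches closed-form and single-base cases", {
  expect_equal(overlap_pvalue("A", "A", 1), 0.25)
  expect_equal(overlap_pvalue("A", "C", 1), 1)
  s <- strrep("ACGT", 5)
  expect_equal(overlap_pvalue(s, s, 20), 0.25^20, tolerance = 1e-12)
})

test_that("overlap probability is non-increasing in the match count", {
  set.seed(42)
  for (o in c(5, 12, 30)) {
    ps <- vapply(0:o, function(m) {
      a <- strrep("A", o)
      b <- paste(c(rep("A", m), rep("C", o - m)), collapse = "")
      overlap_pvalue(a, b, o)
    }, numeric(1))
    expect_true(all(diff(ps) <= 1e-15))
  }
})

test_that("ambiguous positions are excluded from trials and matches", {
  # 5 informative of 8, all matching
  a <- "AAAAANNN"
  b <- "AAAAAAAA"
  expect_equal(overlap_pvalue(a, b, 8), 0.25^5, tolerance = 1e-12)
  expect_equal(overlap_pvalue("NNN", "AAA", 3), 1)
  expect_error(overlap_pvalue("ACGT", "ACGT", 5))
  expect_error(overlap_pvalue("ACGT", "ACGT", 0))
})

test_that("a full-overlap pair merges to its own length", {
  set.seed(7)
  s <- random_dna(1, 150)
  pair <- list(seq1 = s, qual1 = strrep("D", 150),
               seq2 = naive_revcomp(s), qual2 = strrep("D", 150))
  r <- merge_pair(pair)
  expect_equal(r$status, "merged")
  expect_equal(r$overlap_len, 150)
  expect_equal(nchar(r$merged_seq), 150)
  expect_equal(r$merged_seq, s)
})

test_that("pairs merge at the true overlap and obey the length identity", {
  set.seed(8)
  for (o in c(30, 60, 101)) {
    frag <- random_dna(1, 300 - o)
    s1 <- substr(frag, 1, 150)
    s2 <- naive_revcomp(substr(frag, nchar(frag) - 149, nchar(frag)))
    r <- merge_pair(list(seq1 = s1, qual1 = strrep("D", 150),
                         seq2 = s2, qual2 = strrep("D", 150)))
    expect_equal(r$status, "merged")
    expect_equal(r$overlap_len, o)
    expect_equal(nchar(r$merged_seq), 150 + 150 - o)
    expect_equal(r$merged_seq, frag)
    expect_lt(r$p_value, 0.25^(o - 1))
  }
})

test_that("disagreements in the overlap follow the quality rules", {
  # 40-base exact overlap with one disagreement; mate 2 higher quality there
  s <- strrep("ACGT", 10)
  s1 <- s
  s2_fwd <- paste0("T", substr(s, 2, 40))     # disagrees at overlap pos 1
  q1 <- paste0("#", strrep("D", 39))          # q 2 at the disagreement
  q2_fwd <- strrep("D", 40)                   # q 35
  r <- merge_pair(list(seq1 = s1, qual1 = q1,
                       seq2 = naive_revcomp(s2_fwd),
                       qual2 = paste(rev(strsplit(q2_fwd, "")[[1]]), collapse = "")))
  expect_equal(r$status, "merged")
  expect_equal(r$overlap_len, 40)
  expect_equal(substr(r$merged_seq, 1, 1), "T")  # higher-quality base wins
  q <- utf8ToInt(r$merged_qual) - 33
  expect_equal(q[1], 33)                         # |35 - 2|
  expect_equal(q[2], min(35 + 35, 93))           # agreement: capped sum
})

test_that("unrelated reads are left unmerged", {
  set.seed(9)
  a <- random_dna(200, 150)
  b <- random_dna(200, 150)
  res <- ahepipe:::merge_read_set(list(id = as.character(1:200),
                                       seq1 = a, qual1 = rep(strrep("D", 150), 200),
                                       seq2 = b, qual2 = rep(strrep("D", 150), 200)))
  expect_equal(res$summary$merged, 0)
  expect_equal(res$summary$unmerged, 200)
})

test_that("merge_fastq conserves every pair across output streams", {
  set.seed(10)
  td <- withr::local_tempdir()
  n <- 50
  o <- sample(30:150, n, replace = TRUE)
  frag <- vapply(300 - o, function(L) random_dna(1, L), character(1))
  s1 <- substr(frag, 1, 150)
  s2 <- vapply(frag, function(f)
    naive_revcomp(substr(f, nchar(f) - 149, nchar(f))), character(1))
  # make a third of the pairs unrelated so both streams are populated
  un <- seq_len(n) %% 3 == 0
  s2[un] <- random_dna(sum(un), 150)
  ids <- sprintf("p%03d", seq_len(n))
  ahepipe:::write_fastq(ids, s1, rep(strrep("D", 150), n),
                        file.path(td, "R1.fastq"))
  ahepipe:::write_fastq(ids, unname(s2), rep(strrep("D", 150), n),
                        file.path(td, "R2.fastq"))
  sm <- merge_fastq(file.path(td, "R1.fastq"), file.path(td, "R2.fastq"),
                    file.path(td, "out"))
  expect_equal(sm$pairs_in, n)
  expect_equal(sm$merged + sm$unmerged, n)
  merged <- Biostrings::readDNAStringSet(file.path(td, "out_merged.fastq"),
                                         format = "fastq")
  un1 <- Biostrings::readDNAStringSet(file.path(td, "out_unmerged_R1.fastq"),
                                      format = "fastq")
  expect_equal(length(merged) + length(un1), n)
  expect_setequal(c(names(merged), names(un1)), ids)
})

test_that("merge_fastq rejects out-of-sync mates and passes empty input through", {
  td <- withr::local_tempdir()
  ahepipe:::write_fastq("a", "ACGT", "DDDD", file.path(td, "a1.fastq"))
  ahepipe:::write_fastq("b", "ACGT", "DDDD", file.path(td, "a2.fastq"))
  expect_error(merge_fastq(file.path(td, "a1.fastq"), file.path(td, "a2.fastq"),
                           file.path(td, "x")), "mismatch")
  ahepipe:::write_fastq(character(0), character(0), character(0),
                        file.path(td, "e1.fastq"))
  ahepipe:::write_fastq(character(0), character(0), character(0),
                        file.path(td, "e2.fastq"))
  sm <- merge_fastq(file.path(td, "e1.fastq"), file.path(td, "e2.fastq"),
                    file.path(td, "e"))
  expect_equal(sm$pairs_in, 0)
  expect_equal(sm$merged, 0)
})
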