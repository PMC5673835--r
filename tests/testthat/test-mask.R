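test_that("site profiling applies the strict majority rule", {
  aln <- rbind(c("A", "A", "-"),
               c("A", "A", "-"),
               c("A", "C", "-"),
               c("C", "C", "-"))
  p <- profile_sites(aln)
  expect_equal(p$common[1], "A")
  expect_equal(p$fraction[1], 0.75)
  expect_true(p$conserved[1])
  # exactly 50%: NOT conserved
  expect_equal(p$fraction[2], 0.5)
  expect_false(p$conserved[2])
  # all-gap column: no common character
  expect_true(is.na(p$common[3]))
  expect_false(p$conserved[3])
})

test_that("gaps count in the denominator but not as candidates", {
  aln <- rbind(c("A"), c("A"), c("A"), c("-"))
  p <- profile_sites(aln)
  expect_equal(p$fraction[1], 0.75)
  expect_true(p$conserved[1])
  aln2 <- rbind(c("A"), c("A"), c("-"), c("-"))
  expect_false(profile_sites(aln2)$conserved[1])
})

test_that("a consensus-identical sequence is never masked", {
  set.seed(51)
  aln <- random_alignment(10, 120, p_mut = 0.05, p_gap = 0)
  prof <- profile_sites(aln)
  masked <- mask_sequence_regions(aln, prof)
  # rows that match the common base everywhere stay untouched
  match_all <- apply(aln, 1, function(r) all(r == prof$common))
  if (any(match_all))
    expect_equal(masked[match_all, ], aln[match_all, ])
  # masking never alters an unmasked character
  changed <- masked != aln
  expect_true(all(masked[changed] == "N"))
})

test_that("an unrelated row is fully masked, others untouched", {
  set.seed(52)
  aln <- random_alignment(12, 150, p_mut = 0.02, p_gap = 0, n_junk = 0)
  junk_row <- 5
  aln[junk_row, ] <- sample(c("A", "C", "G", "T"), 150, replace = TRUE)
  prof <- profile_sites(aln)
  masked <- mask_sequence_regions(aln, prof)
  # expected match rate 25% of 20 conserved positions is far below 10
  expect_true(mean(masked[junk_row, ] == "N") > 0.95)
  clean <- setdiff(seq_len(12), junk_row)
  expect_true(mean(masked[clean, ] == aln[clean, ]) > 0.98)
})

test_that("a sequence matching exactly 10 of every 20 conserved sites is kept", {
  # alternating match/mismatch against an otherwise uniform alignment
  n <- 10
  L <- 60
  aln <- matrix("A", n, L)
  row <- rep(c("A", "C"), L / 2)
  aln[1, ] <- row
  prof <- profile_sites(aln)
  expect_true(all(prof$conserved))   # A in 9 or 10 of 10 rows
  masked <- mask_sequence_regions(aln, prof)
  expect_equal(masked[1, ], row)     # boundary: >= 10 of 20, nothing masked
  # tip a matching site over to 9 of 20 in some window: the row gets masked
  aln2 <- aln
  aln2[1, 3] <- "G"
  masked2 <- mask_sequence_regions(aln2, profile_sites(aln2))
  expect_true(any(masked2[1, ] == "N"))
})

test_that("thin-site trimming keeps 23 unmasked bases and drops 22", {
  n <- 46
  aln <- cbind(matrix("A", n, 2),
               c(rep("A", 23), rep("N", 23)),
               c(rep("A", 22), rep("N", 24)),
               c(rep("A", 22), rep("-", 24)))
  tr <- drop_thin_sites(aln, 23)
  expect_equal(tr$kept, c(1, 2, 3))
  expect_false(tr$dropped)
  # identity case: nothing masked, no gaps
  clean <- matrix("C", 46, 10)
  tr2 <- drop_thin_sites(clean, 23)
  expect_equal(tr2$alignment, clean)
  # raising the threshold never increases retained columns
  kept_at <- vapply(1:46, function(k) length(drop_thin_sites(aln, k)$kept),
                    integer(1))
  expect_true(all(diff(kept_at) <= 0))
})

test_that("trimming equals the naive reference implementation on random data", {
  set.seed(53)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    L <- sample(40:200, 1)
    aln <- random_alignment(n, L, p_mut = runif(1, 0, 0.3),
                            p_gap = runif(1, 0, 0.15),
                            n_junk = sample(0:2, 1))
    mu <- sample(2:n, 1)
    prof <- profile_sites(aln)
    masked <- mask_sequence_regions(aln, prof)
    got <- drop_thin_sites(masked, mu)
    ref <- naive_trim(aln, min_unmasked = mu)
    expect_identical(got$alignment, ref$alignment)
    expect_identical(got$kept, ref$kept)
  }
})

test_that("trim_locus composes the three steps once and can drop a locus", {
  set.seed(54)
  aln <- random_alignment(10, 150, p_mut = 0.03, p_gap = 0.02)
  pp <- pipeline_params(site_min_unmasked_frac = 0.5)
  tr <- trim_locus(aln, pp)
  expect_false(tr$dropped)
  expect_true(ncol(tr$alignment) <= 150)
  # two taxa cannot reach 23 unmasked bases per site: locus dropped
  tiny <- random_alignment(2, 100, p_mut = 0, p_gap = 0)
  tr2 <- trim_locus(tiny, pipeline_params())
  expect_true(tr2$dropped)
  expect_null(tr2$alignment)
  # trimming only deletes whole columns, in order
  expect_true(all(diff(tr$kept) > 0))
})

test_that("alignments with few conserved columns fall back proportionally", {
  set.seed(55)
  # only 10 conserved columns (< window): whole-sequence evaluation
  aln <- matrix(sample(c("A", "C", "G", "T"), 8 * 10, replace = TRUE), 8, 10)
  aln[, 1:10] <- matrix("A", 8, 10)
  aln[3, ] <- c("C", "C", "C", "C", "C", "C", "C", "C", "C", "C")
  prof <- profile_sites(aln)
  masked <- mask_sequence_regions(aln, prof)
  expect_true(all(masked[3, ] == "N"))
  expect_true(all(masked[1, ] == aln[1, ]))
})
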