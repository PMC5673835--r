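test_that("k-mer distance has the right limits", {
  set.seed(41)
  s <- random_dna(1, 200)
  expect_equal(kmer_distance(s, s), 0)
  # unrelated random 200-mers share no 20-mer
  expect_equal(kmer_distance(random_dna(1, 200), random_dna(1, 200)), 1)
  expect_warning(d <- kmer_distance("ACGT", s), "shorter")
  expect_equal(d, 1)
})

test_that("a central mismatch in a 60-mer matches the set-enumeration oracle", {
  set.seed(42)
  a <- random_dna(1, 60)
  ch <- strsplit(a, "")[[1]]
  ch[30] <- chartr("ACGT", "GTAC", ch[30])
  b <- paste(ch, collapse = "")
  expect_equal(kmer_distance(a, b), naive_kmer_distance(a, b), tolerance = 1e-12)
  expect_gt(kmer_distance(a, b), 0)
})

test_that("k-mer distance equals the brute-force oracle on random pairs", {
  set.seed(43)
  for (i in 1:50) {
    la <- sample(40:300, 1)
    lb <- sample(40:300, 1)
    a <- random_dna(1, la)
    b <- if (runif(1) < 0.3) {  # related pair: mutated copy
      ch <- strsplit(substr(a, 1, min(la, lb)), "")[[1]]
      mut <- which(runif(length(ch)) < 0.05)
      ch[mut] <- chartr("ACGT", "GTAC", ch[mut])
      paste(ch, collapse = "")
    } else random_dna(1, lb)
    expect_equal(kmer_distance(a, b), naive_kmer_distance(a, b),
                 tolerance = 1e-12)
  }
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(44)
  seqs <- setNames(random_dna(5, 120), paste0("q", 1:5))
  d <- kmer_distance_matrix(seqs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("mutually similar sequences form one all-species cluster", {
  ids <- paste0("s", 1:4)
  d <- matrix(0.1, 4, 4, dimnames = list(ids, ids)); diag(d) <- 0
  cl <- cluster_locus(setNames(paste0("sp", 1:4), ids), d)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$species, paste0("sp", 1:4))
})

test_that("the paralog closer to the relatives joins; the other is isolated", {
  # sp1 contributes two homologs: s1a close to the others, s1b divergent
  ids <- c("s1a", "s1b", "s2", "s3", "s4")
  sp <- setNames(c("sp1", "sp1", "sp2", "sp3", "sp4"), ids)
  d <- matrix(0.9, 5, 5, dimnames = list(ids, ids))
  d[c("s2", "s3", "s4"), c("s2", "s3", "s4")] <- 0.15
  d["s1a", c("s2", "s3", "s4")] <- d[c("s2", "s3", "s4"), "s1a"] <- 0.2
  d["s1b", c("s2", "s3", "s4")] <- d[c("s2", "s3", "s4"), "s1b"] <- 0.5
  d["s1a", "s1b"] <- d["s1b", "s1a"] <- 0.5
  diag(d) <- 0
  cl <- cluster_locus(sp, d)
  sizes <- vapply(cl, function(x) length(x$members), integer(1))
  expect_setequal(sizes, c(4, 1))
  big <- cl[[which.max(sizes)]]
  expect_true("s1a" %in% big$members)
  expect_false("s1b" %in% big$members)
})

test_that("two separated paralog groups give two species-disjoint clusters", {
  ids <- c(paste0("a", 1:6), paste0("b", 1:6))
  sp <- setNames(rep(paste0("sp", 1:6), 2), ids)
  d <- matrix(1, 12, 12, dimnames = list(ids, ids))
  d[1:6, 1:6] <- 0.2
  d[7:12, 7:12] <- 0.25
  diag(d) <- 0
  cl <- cluster_locus(sp, d)
  expect_length(cl, 2)
  for (x in cl) expect_equal(anyDuplicated(x$species), 0)
  expect_setequal(cl[[1]]$members, paste0("a", 1:6))
  expect_setequal(cl[[2]]$members, paste0("b", 1:6))
})

test_that("no cluster ever holds two sequences of one species", {
  set.seed(45)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    ids <- sprintf("q%02d", 1:n)
    sp <- setNames(sprintf("sp%d", sample(ceiling(n / 2), n, replace = TRUE)), ids)
    d <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    cl <- cluster_locus(sp, d, stop_distance = runif(1, 0.3, 1))
    expect_equal(sum(vapply(cl, function(x) length(x$members), integer(1))), n)
    for (x in cl) expect_equal(anyDuplicated(x$species), 0)
  }
})

test_that("clustering is invariant to input order", {
  set.seed(46)
  n <- 8
  ids <- sprintf("q%02d", 1:n)
  sp <- setNames(sprintf("sp%d", c(1, 1, 2, 2, 3, 3, 4, 4)), ids)
  d <- matrix(runif(n * n, 0, 0.8), n, n, dimnames = list(ids, ids))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  cl1 <- cluster_locus(sp, d)
  perm <- sample(n)
  cl2 <- cluster_locus(sp[perm], d[perm, perm])
  expect_equal(lapply(cl1, `[[`, "members"), lapply(cl2, `[[`, "members"))
})

test_that("species-fraction filter uses strict 'fewer than' semantics", {
  mk <- function(k) list(members = paste0("m", 1:k),
                         species = paste0("sp", 1:k))
  cl <- list(mk(23), mk(22), mk(46))
  kept <- filter_clusters(cl, 46, 0.5)
  expect_equal(vapply(kept, function(x) length(x$species), integer(1)), c(23, 46))
  expect_length(filter_clusters(list(mk(4)), 8, 0.5), 1)
  expect_length(filter_clusters(list(mk(3)), 8, 0.5), 0)
})

test_that("nHomologs reproduces the two-homologs-at-71-percent reading", {
  one <- lapply(sprintf("L%03d", 1:100), function(lc) stub_contig(30, lc))
  expect_equal(n_homologs(one), 1.0)
  dup <- lapply(sprintf("L%03d", 1:71), function(lc) {
    ct <- stub_contig(30, lc); ct$homolog <- "h2"; ct
  })
  expect_equal(n_homologs(c(one, dup)), 1.71)
  expect_true(n_homologs(c(one, dup)) >= 1)
  expect_message(na <- n_homologs(list()), "undefined")
  expect_true(is.na(na))
  # restriction to retained loci
  expect_equal(n_homologs(c(one, dup), loci = sprintf("L%03d", 72:100)), 1.0)
})

test_that("orthology assessment assembles clusters from contig sets", {
  set.seed(47)
  base <- random_dna(1, 300)
  contigs <- list()
  for (i in 1:5) {
    ch <- strsplit(base, "")[[1]]
    mut <- which(runif(300) < 0.03)
    ch[mut] <- chartr("ACGT", "GTAC", ch[mut])
    contigs[[i]] <- stub_contig(40, "L001", sprintf("s%d", i),
                                paste(ch, collapse = ""))
  }
  # an unrelated contig at the same locus for species 6
  contigs[[6]] <- stub_contig(40, "L001", "s6", random_dna(1, 300))
  sp <- setNames(paste0("sp", 1:6), paste0("s", 1:6))
  orth <- assess_orthology(contigs, sp, pipeline_params())
  expect_equal(orth$n_species_total, 6)
  expect_length(orth$clusters, 1)
  expect_setequal(orth$clusters[[1]]$species, paste0("sp", 1:5))
  expect_equal(sum(orth$report$retained), 1)
})
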