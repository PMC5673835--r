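#' Simulation configuration
#'
#' Parameters of the ground-truthed data generator.  Each locus is a highly
#' conserved anchor core flanked on both sides by faster-evolving flanks — the
#' structure targeted by anchored hybrid enrichment probes.  Sequences evolve
#' along a random ultrametric tree under Jukes-Cantor substitution with
#' separate anchor and flank rates, indels restricted to the flanks, optional
#' recent gene duplication per taxon and locus, and paired-end reads with
#' configurable insert geometry, error rate and cross-sample contamination.
#'
#' Defaults describe the desk-scale validation conditions used throughout the
#' package's own tests: 8 taxa, 30 loci, 400 bp anchors with 300 bp flanks,
#' 5% anchor and 15% flank root-to-tip divergence, 40x coverage, 150 bp reads
#' on 240 bp inserts (so mates typically overlap by ~60 bp), 0.5% sequencing
#' error.
#'
#' @param n_taxa number of terminal taxa (>= 2).
#' @param n_loci number of loci.
#' @param anchor_len anchor (probe-region) length in bp.
#' @param flank_len flank length in bp on each side of the anchor.
#' @param anchor_divergence expected substitutions/site from root to tip in
#'   the anchor.
#' @param flank_divergence same for the flanks; must be >= `anchor_divergence`.
#' @param indel_rate indel events per flank site per lineage (flanks only).
#' @param duplication_prob probability that a taxon carries a recent duplicate
#'   of a locus.
#' @param duplication_divergence expected substitutions/site between the two
#'   paralog copies.
#' @param duplication_taxa optional character vector restricting duplication
#'   to the named taxa (default: all taxa).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd normal insert-size (fragment length) model,
#'   truncated to `[read_len, locus length]`.
#' @param coverage requested mean per-base depth per homolog copy.
#' @param seq_error_rate per-base substitution error probability.
#' @param contamination_frac fraction of a sample's fragments drawn from a
#'   random other sample at the same locus.
#' @param tree_min_internal minimum internal branch length (as a fraction of
#'   tree depth) of the simulated species tree; trees are redrawn until every
#'   internal branch reaches it.  At the default study conditions 0.01
#'   corresponds to roughly 30 expected substitutions across a 30-locus
#'   matrix, the minimum for the true topology to be identifiable at all —
#'   recovery cannot be assessed against a bipartition that no data support.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_taxa = 8L, n_loci = 30L,
                              anchor_len = 400L, flank_len = 300L,
                              anchor_divergence = 0.05, flank_divergence = 0.15,
                              indel_rate = 0.002,
                              duplication_prob = 0, duplication_divergence = 0.05,
                              duplication_taxa = NULL,
                              read_len = 150L, insert_mean = 240, insert_sd = 30,
                              coverage = 40, seq_error_rate = 0.005,
                              contamination_frac = 0,
                              tree_min_internal = 0.01, seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci),
              anchor_len = as.integer(anchor_len), flank_len = as.integer(flank_len),
              anchor_divergence = anchor_divergence,
              flank_divergence = flank_divergence,
              indel_rate = indel_rate,
              duplication_prob = duplication_prob,
              duplication_divergence = duplication_divergence,
              duplication_taxa = duplication_taxa,
              read_len = as.integer(read_len),
              insert_mean = insert_mean, insert_sd = insert_sd,
              coverage = coverage, seq_error_rate = seq_error_rate,
              contamination_frac = contamination_frac,
              tree_min_internal = tree_min_internal,
              seed = as.integer(seed))
  stopifnot(cfg$n_taxa >= 2L, cfg$n_loci >= 1L,
            cfg$flank_divergence >= cfg$anchor_divergence,
            cfg$indel_rate >= 0, cfg$indel_rate <= 1,
            cfg$duplication_prob >= 0, cfg$duplication_prob <= 1,
            cfg$seq_error_rate >= 0, cfg$seq_error_rate <= 1,
            cfg$contamination_frac >= 0, cfg$contamination_frac <= 1)
  if (cfg$read_len > cfg$insert_mean)
    warning("read_len exceeds insert_mean; mates will overlap fully or read through")
  structure(cfg, class = "sim_config")
}

# Jukes-Cantor: substitute each site independently with the closed-form
# probability of observing a different base after branch length d.
jc_mutate <- function(intseq, d) {
  if (d <= 0) return(intseq)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(runif(length(intseq)) < p)
  if (length(hit))
    intseq[hit] <- ((intseq[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  intseq
}

# indels restricted to a flank vector; geometric lengths (mean 2);
# insertions draw uniform random bases
apply_indels <- function(flank, rate) {
  if (rate <= 0 || length(flank) == 0) return(flank)
  n_events <- sum(runif(length(flank)) < rate)
  if (n_events == 0) return(flank)
  for (i in seq_len(n_events)) {
    len <- rgeom(1, 0.5) + 1L
    pos <- sample.int(length(flank), 1L)
    if (runif(1) < 0.5) {
      flank <- append(flank, sample.int(4L, len, replace = TRUE), after = pos)
    } else {
      drop <- pos:min(pos + len - 1L, length(flank))
      if (length(drop) < length(flank)) flank <- flank[-drop]
    }
  }
  flank
}

#' Generate ground-truthed loci
#'
#' Simulates a random ultrametric species tree (pure-birth Yule process,
#' scaled to unit root-to-tip depth), draws uniform-random root sequences per
#' locus, and
#' evolves them along the tree with the anchor rate in the core and the flank
#' rate outside it.  Indels are applied per tip lineage, flanks only.  Recent
#' duplications copy a tip's finished sequence and add `duplication_divergence`
#' substitutions to the copy.
#'
#' @param config a [simulation_config()].
#' @return object of class `truth_set`: list with `tree` (ape phylo),
#'   `newick`, `sequences` (data.frame: taxon, locus, homolog, seq,
#'   anchor_start, anchor_end — 1-based inclusive anchor coordinates within
#'   the sequence), `probe_refs` (the root anchor sequence per locus, the
#'   synthetic stand-in for a distantly related probe-region reference), and
#'   the `config`.
#' @export
generate_loci <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  taxa <- sprintf("t%02d", seq_len(config$n_taxa))
  # Yule tree, redrawn until the topology is identifiable (no internal branch
  # shorter than tree_min_internal of the unit depth)
  for (try in seq_len(200L)) {
    tree <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    internal <- tree$edge.length[tree$edge[, 2L] > config$n_taxa]
    if (!length(internal) || min(internal) >= config$tree_min_internal) break
  }
  tree$tip.label <- taxa[as.integer(sub("^t", "", tree$tip.label))]
  tree <- ape::reorder.phylo(tree, "cladewise")

  L_anchor <- config$anchor_len
  L_flank <- config$flank_len
  rate <- c(rep(config$flank_divergence, L_flank),
            rep(config$anchor_divergence, L_anchor),
            rep(config$flank_divergence, L_flank))
  n_tot <- length(rate)

  dup_taxa <- config$duplication_taxa %||% taxa
  rows <- vector("list", config$n_loci * config$n_taxa * 2L)
  ri <- 0L
  loci <- sprintf("L%03d", seq_len(config$n_loci))
  root_node <- config$n_taxa + 1L
  edge <- tree$edge

  probe_refs <- character(config$n_loci)
  for (li in seq_len(config$n_loci)) {
    root <- sample.int(4L, n_tot, replace = TRUE)
    probe_refs[li] <- int_to_seq(root[L_flank + seq_len(L_anchor)])
    seqs_at_node <- vector("list", max(edge))
    seqs_at_node[[root_node]] <- root
    # cladewise edge order guarantees each parent is visited before its children
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1L]; chd <- edge[e, 2L]
      bl <- tree$edge.length[e]
      # region-wise rates: mutate with per-site probability from rate * bl
      s <- seqs_at_node[[par]]
      p <- 0.75 * (1 - exp(-4 * rate * bl / 3))
      hit <- which(runif(n_tot) < p)
      if (length(hit))
        s[hit] <- ((s[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
      seqs_at_node[[chd]] <- s
    }
    for (ti in seq_len(config$n_taxa)) {
      tip <- which(tree$tip.label == taxa[ti])
      s <- seqs_at_node[[tip]]
      left <- apply_indels(s[seq_len(L_flank)], config$indel_rate)
      anchor <- s[L_flank + seq_len(L_anchor)]
      right <- apply_indels(s[L_flank + L_anchor + seq_len(L_flank)], config$indel_rate)
      full <- c(left, anchor, right)
      a_start <- length(left) + 1L
      a_end <- length(left) + L_anchor
      ri <- ri + 1L
      rows[[ri]] <- data.frame(taxon = taxa[ti], locus = loci[li], homolog = "h1",
                               seq = int_to_seq(full),
                               anchor_start = a_start, anchor_end = a_end,
                               stringsAsFactors = FALSE)
      if (config$duplication_prob > 0 && taxa[ti] %in% dup_taxa &&
          runif(1) < config$duplication_prob) {
        dup <- jc_mutate(full, config$duplication_divergence)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(taxon = taxa[ti], locus = loci[li], homolog = "h2",
                                 seq = int_to_seq(dup),
                                 anchor_start = a_start, anchor_end = a_end,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  sequences <- do.call(rbind, rows[seq_len(ri)])
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 sequences = sequences,
                 probe_refs = setNames(probe_refs, loci),
                 config = config),
            class = "truth_set")
}

#' Simulate paired-end reads from a truth set
#'
#' Draws fragments of normal length (truncated to `[read_len, locus length]`)
#' uniformly along each truth sequence so that expected per-base depth matches
#' `coverage` per homolog copy, emits mate 1 forward and mate 2
#' reverse-complemented, injects substitution errors at `seq_error_rate`
#' (error bases carry Phred 12, all others Phred 35), and optionally replaces
#' a fraction of each sample's fragments with fragments drawn from another
#' sample at the same locus (cross-contamination).
#'
#' @param truth a [generate_loci()] result.
#' @param config the same [simulation_config()].
#' @return list with `reads` (per-sample list of `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`) and `provenance` (data.frame: sample, id, taxon, locus,
#'   homolog, frag_start, frag_len, true_overlap).
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  if (config$coverage <= 0) stop("coverage must be positive")
  set.seed(derive_seed(config$seed, 2L))
  seqs <- truth$sequences
  samples <- sort(unique(seqs$taxon))
  reads <- list()
  prov <- list()
  q_good <- 35L
  q_err <- 12L
  for (smp in samples) {
    own <- seqs[seqs$taxon == smp, , drop = FALSE]
    frag_src <- list()   # rows: source row index in seqs, start, len
    for (k in seq_len(nrow(own))) {
      L <- nchar(own$seq[k])
      # fragment starts are uniform over S = L - F + 1 positions; a position p
      # is covered by v(p) = min(p, S) - max(1, p - F + 1) + 1 of them, so the
      # expected anchor depth is n * mean(v(p)) / S.  Solve for n so the mean
      # depth over the anchor equals the requested coverage.
      f_bar <- min(config$insert_mean, L)
      support <- max(1, L - f_bar + 1)
      p <- own$anchor_start[k]:own$anchor_end[k]
      v_bar <- mean(pmax(pmin(p, support) - pmax(1, p - f_bar + 1) + 1, 0))
      n_frag <- max(1L, round(config$coverage * support / max(v_bar, 1)))
      flen <- round(rnorm(n_frag, config$insert_mean, config$insert_sd))
      flen <- pmin(pmax(flen, config$read_len), L)
      fstart <- floor(runif(n_frag, min = 1, max = L - flen + 1 + 1))
      src_row <- rep(which(seqs$taxon == smp)[k], n_frag)
      frag_src[[k]] <- data.frame(src = src_row, start = fstart, len = flen)
    }
    frags <- do.call(rbind, frag_src)
    # contamination: swap the source of a random subset to another taxon,
    # same locus (first homolog of the contaminating taxon)
    if (config$contamination_frac > 0 && length(samples) > 1) {
      swap <- which(runif(nrow(frags)) < config$contamination_frac)
      for (w in swap) {
        loc <- seqs$locus[frags$src[w]]
        pool <- which(seqs$locus == loc & seqs$taxon != smp & seqs$homolog == "h1")
        if (!length(pool)) next
        newsrc <- pool[sample.int(length(pool), 1L)]
        L2 <- nchar(seqs$seq[newsrc])
        len2 <- min(frags$len[w], L2)
        frags$src[w] <- newsrc
        frags$len[w] <- len2
        frags$start[w] <- floor(runif(1, min = 1, max = L2 - len2 + 1 + 1))
      }
    }
    n <- nrow(frags)
    ids <- sprintf("%s_r%06d", smp, seq_len(n))
    seq1 <- character(n); seq2 <- character(n)
    qual1 <- character(n); qual2 <- character(n)
    rl <- config$read_len
    for (i in seq_len(n)) {
      frag <- substr(seqs$seq[frags$src[i]], frags$start[i],
                     frags$start[i] + frags$len[i] - 1L)
      r1 <- substr(frag, 1L, rl)
      r2 <- revcomp_cpp(substr(frag, nchar(frag) - rl + 1L, nchar(frag)))
      er <- inject_errors(r1, config$seq_error_rate, q_good, q_err)
      seq1[i] <- er$seq; qual1[i] <- er$qual
      er <- inject_errors(r2, config$seq_error_rate, q_good, q_err)
      seq2[i] <- er$seq; qual2[i] <- er$qual
    }
    reads[[smp]] <- list(id = ids, seq1 = seq1, qual1 = qual1,
                         seq2 = seq2, qual2 = qual2)
    prov[[smp]] <- data.frame(sample = smp, id = ids,
                              taxon = seqs$taxon[frags$src],
                              locus = seqs$locus[frags$src],
                              homolog = seqs$homolog[frags$src],
                              frag_start = frags$start, frag_len = frags$len,
                              true_overlap = pmax(0L, 2L * rl - frags$len),
                              stringsAsFactors = FALSE)
  }
  list(reads = reads, provenance = do.call(rbind, prov))
}

inject_errors <- function(seq, rate, q_good, q_err) {
  n <- nchar(seq)
  qual <- strrep(intToUtf8(q_good + 33L), n)
  if (rate > 0) {
    hit <- which(runif(n) < rate)
    if (length(hit)) {
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      idx <- match(ch[hit], DNA_BASES)
      ok <- !is.na(idx)
      if (any(ok)) {
        h <- hit[ok]
        ch[h] <- DNA_BASES[((idx[ok] - 1L + sample.int(3L, sum(ok), replace = TRUE)) %% 4L) + 1L]
        seq <- paste(ch, collapse = "")
        qv <- rep(q_good, n)
        qv[h] <- q_err
        qual <- intToUtf8(qv + 33L)
      }
    }
  }
  list(seq = seq, qual = qual)
}

#' Write simulated reads as paired FASTQ files
#'
#' @param sample_reads one element of `simulate_reads()$reads`.
#' @param prefix output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` (Phred+33).
#' @return invisibly, the two paths.
#' @export
write_paired_fastq <- function(sample_reads, prefix) {
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  write_fastq(sample_reads$id, sample_reads$seq1, sample_reads$qual1, p1)
  write_fastq(sample_reads$id, sample_reads$seq2, sample_reads$qual2, p2)
  invisible(c(p1, p2))
}

write_fastq <- function(ids, seqs, quals, path) {
  if (length(ids) == 0) { file.create(path); return(invisible(path)) }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("mate files differ in record count: ", path1, " vs ", path2)
  id1 <- sub("[/ ].*$", "", names(r1))
  id2 <- sub("[/ ].*$", "", names(r2))
  bad <- which(id1 != id2)
  if (length(bad))
    stop("mate id mismatch at record ", bad[1], ": '", id1[bad[1]],
         "' vs '", id2[bad[1]], "'")
  list(id = id1,
       seq1 = unname(as.character(r1)),
       qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
       seq2 = unname(as.character(r2)),
       qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)))
}

#' Write truth tables
#'
#' Writes the true tree (newick), true sequences (FASTA + TSV of anchor
#' coordinates and homolog labels) and, if given, the read provenance table.
#'
#' @param truth a `truth_set`.
#' @param dir output directory (created if needed).
#' @param provenance optional provenance data.frame from [simulate_reads()].
#' @return invisibly, the directory.
#' @export
write_truth_tables <- function(truth, dir, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(truth$newick, file.path(dir, "true_tree.nwk"))
  s <- truth$sequences
  fa <- Biostrings::DNAStringSet(s$seq)
  names(fa) <- sprintf("%s|%s|%s", s$locus, s$taxon, s$homolog)
  Biostrings::writeXStringSet(fa, file.path(dir, "true_sequences.fasta"))
  write.table(s[, c("taxon", "locus", "homolog", "anchor_start", "anchor_end")],
              file.path(dir, "true_sequences.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(provenance))
    write.table(provenance, file.path(dir, "read_provenance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
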