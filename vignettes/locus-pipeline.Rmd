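---
title: "Methods: anchored-capture locus processing from reads to supermatrix"
author: "ahepipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored-capture locus processing from reads to supermatrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Anchored hybrid enrichment (AHE) captures hundreds of loci whose probe-targeted
cores ("anchors") are highly conserved across deep divergences, while the
flanking sequence recovered around each anchor is progressively more variable.
Turning the raw paired-end reads from such an experiment into a concatenated
phylogenomic matrix requires a chain of decisions — how to merge overlapping
mates, how to map reads onto references from distantly related taxa, how to
separate paralogous copies, which sequences are orthologous across species,
and which alignment regions are trustworthy.  `ahepipe` implements that chain
as a set of composable stages, each with an explicit statistical or
combinatorial rule, plus a ground-truthed simulator so that every stage can be
validated against known answers.

The stages, in pipeline order:

1. **Read merging** (`merge_pair`, `merge_fastq`)
2. **Divergent reference assembly** (`assemble_locus`, `assemble_sample`,
   `filter_contigs`)
3. **Orthology assessment** (`kmer_distance`, `cluster_locus`,
   `filter_clusters`, `n_homologs`)
4. **External alignment** (out of scope by design; a coordinate-based stacking
   is built in, and `mafft` can be called when available)
5. **Masking and trimming** (`profile_sites`, `mask_sequence_regions`,
   `drop_thin_sites`, `trim_locus`)
6. **Supermatrix construction** (`concatenate_loci`, `per_taxon_stats`,
   writers, `diagnostic_tree`)

`run_pipeline()` chains them; `inst/scripts/ahe-pipeline.R` exposes each as a
shell subcommand.

## Read merging by overlap probability

For a candidate overlap of length $n$ between the 3' end of mate 1 and the 5'
end of the reverse-complemented mate 2, the number of matching bases under the
null hypothesis that the reads are unrelated is $X \sim \mathrm{Binomial}(n,
1/4)$.  Every candidate overlap length is scored by the upper tail $P(X \ge
m)$, the overlap with the smallest probability is selected, and the pair is
merged only when that probability is below `merge_alpha` ($10^{-10}$ by
default — stringent enough that 10,000 unrelated read pairs produce zero false
merges in the acceptance suite, while any error-free true overlap of 20 bases
or more is always accepted, since $0.25^{20} \approx 9\times10^{-13}$).

Numerical choices:

* The null match probability is fixed at 1/4 (uniform composition).  A
  composition-aware null would need a genome-wide estimate that a per-pair
  test does not have.
* `N` bases are uninformative: excluded from both $n$ and $m$ rather than
  counted as mismatches.
* Ties in the minimum probability are resolved toward the longest overlap —
  deterministic, and the longer overlap rests on more evidence.
* In the merged overlap, agreeing bases get quality $\min(q_1+q_2, 93)$;
  disagreeing bases take the higher-quality base (ties to mate 1) with
  quality $|q_1-q_2|$ — the convention of widely used read mergers.
* Only overlaps up to $\min(\ell_1,\ell_2)$ are tested; read-through
  geometry (insert shorter than the read) is out of scope and such pairs
  simply remain unmerged.

## Divergent reference assembly

Reads are recruited to a per-locus reference that may come from a distantly
related taxon, so exact matching is too brittle.  Recruitment is two-staged:

* **Preliminary match**: some window of the read aligned against the current
  consensus must match at `seed_min_matches` (17) of the 20 care positions of
  a spaced seed.  The default template is `111011101110111011111111`
  (span 24, weight 20, care positions at both ends).  Spaced seeds tolerate
  the periodic mismatch structure of diverged coding sequence better than
  contiguous k-mers of the same weight; the specific mask is configurable and
  nothing downstream depends on its exact shape, only on its weight.
* **Confirmation**: at least `confirm_min_matches` (55) identities in some
  window of `confirm_window` (100) consecutive aligned positions.  Near contig
  ends, where fewer than 100 positions align, the full overlap is evaluated
  proportionally (identity $\ge$ 0.55) provided at least 50 bases align —
  without this, flank-tip reads could never confirm and extension would stall.

Candidate placements come from exact shared 11-base words (a hash index of
the consensus, both read orientations scanned in one rolling pass); a
diagonal needs at least two shared words before the seed and confirmation
rules are evaluated.  This is a pure indexing accelerator: a placement that
cannot produce two exact 11-mers within a 150-300 base read is far below the
17/20 + 55/100 acceptance region at the divergences this pipeline targets.

Placement is **ungapped**: anchors are effectively indel-free at these
scales, and a sample's own flank indels do not disturb placement because
extension is driven by the sample's own consensus, not the reference.
Cross-sample indels surface later as alignment-stage gaps and are the masking
step's problem by design.

Assembly iterates recruit → place → recall consensus → extend until no new
read joins.  The consensus base is the majority base; when the second most
common base reaches 30% of the depth at a site, the two-base IUPAC ambiguity
code is emitted (allelic differences are treated as ambiguity, not as
separate haplotypes).  Extension beyond the currently assembled region
requires contiguous depth of at least `extension_min_depth` (3) — a single
read is never allowed to run the contig out on its own.

`assemble_sample()` grows all loci simultaneously against a combined index
and assigns each read to the locus holding its best seed window, which keeps
the cost linear in the number of reads; it is tested to agree exactly with
per-locus assembly.

### Homolog separation

If the recruited reads contain at least `homolog_min_sites` (5) *conflict
sites* — sites where the second base has at least 3 reads and at least 30% of
the depth — the reads are phased over those sites by iterative two-group
assignment (seeded from the most informative read, profiles re-estimated as
per-site majorities).  The contig is split into two homolog consensus
sequences only when both groups keep at least three informative reads and at
least 90% of all informative read-site observations agree with their own
group's profile.  The consistency requirement is what separates true
paralogy (coherent phase across sites) from scattered conflicts caused by
alignment slippage or error; in simulation it yields split recall above 0.9
at 5% paralog divergence and 30-40x coverage with no false splits observed.
Splits beyond two homologs are not attempted.

Contigs supported by fewer than `contig_min_reads` (23) fragments are
removed; a merged pair or an unmerged mate pair counts as **one** fragment
(both mates derive from one molecule, so counting them twice would
double-weight unmerged — typically lower-quality — evidence).

## Orthology

Pairwise distances among homolog consensus sequences at a locus combine two
similarities: the containment fraction of shared continuous 20-mers and of
shared spaced 20-mers, averaged, $d = 1 - (s_{\rm cont} + s_{\rm spaced})/2$
with $s = |A \cap B| / \min(|A|, |B|)$ over the unique k-mer sets.  The
containment (minimum) denominator means a short consensus that is a fragment
of a longer one still scores as similar — capture efficiency makes consensus
lengths very uneven.  K-mers are orientation-sensitive because every
consensus is already oriented by its reference; a `canonical` flag exists for
unoriented input.

Clustering joins groups in order of ascending average-linkage distance under
a hard constraint: **no cluster may ever contain two sequences of the same
species**.  The constraint, not the distance threshold, is what separates
paralogs — when a species contributes two copies, the copy closer to the
other species' sequences joins the shared cluster first and the other copy
is then locked out.  Joining stops at `stop_distance`, default **0.97**.
This default deserves a note: shared-20-mer similarity decays as roughly
$(1-p)^{20}$ in the pairwise divergence $p$, so sequence pairs beyond ~10%
divergence already sit at distances above 0.9, and a deep outgroup sits near
0.93 against the whole ingroup.  Genuinely unrelated sequences, however, sit
at exactly 1.0 (no shared 20-mer at all).  The stop therefore only needs to
exclude the no-signal point, and anything materially below 1 is still
evidence of homology; 0.97 keeps deep outgroups clusterable while rejecting
cross-locus junk.  Clusters containing fewer than half of the species
(strictly fewer: 23 of 46 is retained) are removed.

`n_homologs()` reports, per species, the mean number of homolog consensuses
per recovered locus — near 1 when recent duplication is absent; a species
with two homologs at 71% of its loci scores 1.71.  In simulation the
duplicated-locus fraction is recovered as $(\mathrm{nHomologs}-1)/r$ with
$r$ the measured split recall, within 0.05 of the simulated value.

## Masking and site trimming

Each alignment column's modal non-gap character is computed with all
sequences in the denominator (a gap lowers the fraction but is never the
common character; ties are broken alphabetically for determinism).  A column
is *conserved* when the fraction strictly exceeds 1/2 — an exactly-50%
column does not qualify.

Each sequence is then scanned with windows of 20 conserved columns, stride
one; a window passes when the sequence matches the common base at 10 or more
of them (a gap at a conserved column is a mismatch — it does not match the
common base).  A character is masked (replaced by `N`, which keeps the
matrix rectangular and is distinct from a gap) when every window covering
its alignment column fails; one passing window rescues everything in its
span.  The first and last windows' spans are extended to the alignment
edges, so unanchored edge regions — where misassembled or misaligned flanks
accumulate — fall under the nearest window's verdict instead of escaping the
scan.  When an alignment has fewer than 20 conserved columns, each sequence
is judged once over all of them at the proportional threshold (10/20), and a
failing sequence is masked entirely.

Finally, columns with fewer than `site_min_unmasked` (23) unmasked,
non-gap characters are removed, and loci shorter than `min_final_length`
(50) columns after trimming are dropped.  Masking never alters a surviving
character and trimming only deletes whole columns; re-profiling after
masking could change conservation, so the profile → mask → trim order is
fixed, applied exactly once, and not idempotent by design.

The whole masking/trimming path is verified against an independent naive
loop-based implementation on randomized alignments (exact equality).

### Absolute thresholds and the fractional mode

The defaults 23 (contig support) and 23 (unmasked bases per site) are the
operating point of the 46-taxon study this pipeline reproduces; they encode
"half the taxa" and "about half the expected coverage" for that design.  For
differently sized studies both accept a fractional form
(`site_min_unmasked_frac`, `contig_min_reads_frac`, applied as
$\lceil f\,n\rceil$).  The desk-scale validation runs with 8 taxa use
`site_min_unmasked_frac = 0.5`; an absolute 23 would delete every column of
an 8-taxon alignment.

## The synthetic-data generator

`simulation_config()` / `generate_loci()` / `simulate_reads()` generate the
validation data.  What they emulate, and the study conditions the defaults
encode:

* Loci are a 400 bp anchor with 300 bp flanks on each side, evolved by
  Jukes-Cantor substitution along a Yule (pure-birth) tree scaled to unit
  root-to-tip depth, at 0.05 expected substitutions/site in the anchor and
  0.15 in the flanks — the conserved-core/variable-flank contrast that AHE
  probes exploit.  JC is deliberately minimal: the pipeline under test is
  model-agnostic, and nothing downstream estimates substitution parameters.
* The species tree is redrawn until every internal branch is at least 1% of
  the tree depth (`tree_min_internal`).  At the default matrix size that is
  roughly 30 expected substitutions per bipartition — the minimum for the
  true topology to be identifiable at all.  Topology-recovery validation
  against a bipartition supported by ~0 expected substitutions would measure
  noise, not the pipeline.
* Indels occur only in the flanks (rate 0.002 events/site per tip lineage,
  geometric lengths with mean 2): anchors stay alignable while the flanks
  exercise the masking stage.  Indels are applied per terminal lineage, so
  shared internal-branch indels are not modeled.
* Each taxon-locus pair duplicates with probability `duplication_prob`; the
  duplicate accrues `duplication_divergence` (default 5%) extra
  substitutions.  Both copies are sequenced at full coverage (a recent
  duplication is captured as efficiently as the original).
* Reads are 150 bp pairs on Normal(240, 30) inserts truncated to
  [read length, locus length], so mates typically overlap by ~60 bp and the
  merger has real work to do.  The fragment count per homolog is solved so
  the mean depth over the anchor equals the requested coverage (40x),
  accounting for the uniform-start edge deficit.  Base errors occur at 0.005
  per base; error bases carry Phred 12 against a constant Phred 35
  background, so quality-aware consensus logic is exercised
  deterministically.
* `contamination_frac` redirects that fraction of a sample's fragments to a
  random other sample at the same locus — the failure mode the 23-read
  contig filter exists to suppress.
* The root anchor sequence of each locus doubles as the probe-region
  reference, standing in for the distantly related references used in
  practice: at 5% root-to-tip anchor divergence every tip is about as far
  from it as real samples are from a cross-family reference.

What the generator does **not** emulate: probe hybridization
thermodynamics, GC and PCR bias, duplicate reads, quality decay along the
read, pooled conspecific specimens (one read set is one terminal), and
shared indel histories.  Passing the synthetic validation therefore shows
the *rules* are implemented correctly and interact as intended at realistic
divergences and coverages — not that the defaults are optimal for any
particular empirical library.

All stochastic steps derive their streams deterministically from one seed
(`rng_seed` / `seed`), so stages can be re-run in isolation and whole runs
are bit-reproducible.

## Alignment: built-in stacking vs external MSA

Multiple alignment is deliberately external to this package, as it is in
the workflow the pipeline reproduces.  Two options exist at the pipeline
stage:

* `aligner = "offset"` (default, self-contained): cluster members are
  stacked on the shared reference coordinate system.  Exact wherever no
  indel intervenes (the anchors), drifting in flanks past an indel — which
  the masking stage then removes.  Fine for anchors-plus-proximal-flank
  matrices.
* `aligner = "mafft"`: each cluster's unaligned FASTA is passed through
  `mafft --auto`.  Used in the package's own end-to-end validation, where it
  recovers the full flanks and the true topology (Robinson-Foulds distance 0
  on every seed tested).

## Internal conventions

Coordinates are 0-based half-open internally (contig `start` is the offset
of the consensus on the reference frame, possibly negative after left
extension); human-facing outputs (partition tables, anchor intervals) are
1-based inclusive.  The supermatrix distinguishes `?` (taxon absent from a
locus) from `-` (gap within a present sequence) and `N` (masked or
ambiguous).  Reads are sorted by id before recruitment, cluster ties break
lexicographically, and profile ties break alphabetically, so every stage is
deterministic for any input order.

## Problem sizes used in validation

The package's own tests validate at desk scale: merging characteristics on
10,000 pairs; masking equivalence on 100 randomized alignments (up to
20 x 200); k-mer distances against brute-force enumeration on 1,000 random
pairs; end-to-end recovery on 8 taxa x 30 loci at 40x (about 40,000 read
pairs); duplication recovery on 10 replicates of 200 loci.  These sizes give
the binomial checks enough resolution (e.g. recovering a 0.3 duplication
fraction to within 0.05) while a full run of the suite stays in the
minutes range.

## Known limitations

* Homolog splitting is two-way; a locus with three or more recent copies
  collapses into two consensus groups.
* The orthology distance saturates near 1 above ~15% pairwise divergence;
  cluster joins among very deep taxa then rest on thin margins (see the
  `stop_distance` note above).  Tree-based orthology is out of scope.
* Ungapped placement means a large indel *inside* the anchor (not modeled by
  the generator, rare in practice) would truncate extension at that point.
* The coordinate-based aligner is a validation convenience, not a substitute
  for a real MSA program on empirical data.
* `per_taxon_stats()` counts `N` as undetermined, so heavily IUPAC-coded
  consensus regions slightly undercount "nucleotides sequenced".
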