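---
title: "Methods: homeodomain profile search, cluster architecture and loss mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homeodomain profile search, cluster architecture and loss mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxr)
```

## The problem

Hox genes pattern the anterior–posterior axis of bilaterian animals and are
classically organised in a single genomic cluster whose gene order mirrors
the order of expression domains (collinearity). Nematodes break this
picture: *Caenorhabditis elegans* keeps only six Hox genes from four of the
ancestral orthology groups, dispersed over several megabases, while other
nematode and nematomorph genomes retain compact clusters with different gene
complements. Cataloguing which orthology groups a genome retains, how the
surviving genes are arranged, what interrupts them, and where in the
phylogeny the missing groups were lost, is a recurring annotation task every
time a new assembly appears.

hoxr implements that task as a reusable pipeline over five stages:

1. **Profiles** — per-orthology-group position-specific log-odds matrices
   built from a labelled homeodomain reference alignment, with empirical
   E-value calibration.
2. **Scan** — six-frame translation of the assembly (or direct protein-mode
   scanning of a proteome), window scoring against every profile, E-value
   filtering, interval merging into loci, and an iterative second search
   round in which first-round hits enrich the profiles.
3. **Classify** — orthology-group assignment with an explicit ambiguity
   margin, duplication calling, and the species-by-group complement matrix.
4. **Clusters & interruptions** — cluster detection under a "four or more
   genes within a bounded span" definition, gene order and transcriptional
   orientation, a Kendall-style collinearity statistic, non-Hox gene counts
   within cluster hulls, and seed-and-extend localisation of mature miRNAs.
5. **Loss mapping** — Dollo parsimony reconstruction of per-group
   presence/absence on a rooted species tree.

A seeded synthetic-genome generator with ground-truth manifests makes every
stage testable end to end without external downloads.

## The scoring model

Each orthology group `g` is modelled by a matrix `M_g` of per-column
log-odds scores over the 20 amino acids. From a gapped labelled alignment,
columns with gap fraction at or above `gap_max` (default 0.5) are dropped;
for a retained column `i`,

```
p_i(a) = (n_i(a) + alpha * q(a)) / (N_i + alpha)
M[a, i] = log2(p_i(a) / q(a))   [bits]
```

where `n_i(a)` counts residue `a` in the column, `N_i` is the non-gap count,
`alpha` (default 1) is a background-mixing pseudocount, and `q` is the
background distribution, by default the pooled residue composition of the
whole reference alignment (self-contained; no external frequency tables). A
window of length `L` (60 columns for a homeodomain core) scores the sum of
its per-column entries; `X` contributes 0 bits and a stop (`*`) anywhere
vetoes the window. This is a deliberate simplification of full profile HMMs:
the homeodomain is a fixed-length ungapped core after column filtering, and
detection plus classification does not require insert/delete states.

**E-values.** Significance is calibrated per profile: `n_windows` (default
10,000) i.i.d. windows are drawn from the null residue distribution
(default `q`), scored, and fitted by method of moments to a Gumbel
distribution (`lambda = sd * sqrt(6) / pi`, `mu = mean − gamma * lambda`).
The E-value of score `S` over a search space of `m` windows is
`E(S, m) = m * (1 − GumbelCDF(S))`, with `m` the total window count
genome-wide across all six frames, so E-values are shared Bonferroni-style
across the scan. The default acceptance threshold is `E <= 1e-5`. The
method-of-moments Gumbel has a heavier tail than the near-Gaussian null
score sum, so the operating point is conservative: observed false-positive
counts on null genomes sit below the nominal `m * threshold_E` budget,
which the test suite verifies over 20 seeded 1 Mb null genomes.

**Two search rounds.** Windows accepted in round 1 are added to their
matched profile's counts at weight 1, the matrix and calibration are
recomputed (with the profile's stored calibration seed, keeping runs
deterministic), and the scan repeats. If round 1 accepts nothing, round 2 is
provably identical to round 1, and only augmented profiles are rescanned.
The iteration broadens profiles toward the diverged homologues actually
present in the target genome, which is what lifts recovery of diverged
implants in the divergence sweep.

## Coordinates and merging

All internal coordinates are 0-based half-open on the forward strand of the
source scaffold; GFF3 I/O converts at the boundary, and minus-frame window
hits map through the reverse complement. Hits on one scaffold and strand
within `max_gap` (default 5,000 nt) merge into a locus spanning their hull;
the default tolerates a single intron of up to a few kb splitting the
homeodomain across frame hits. A locus keeps the best window score per group
(`group_scores`), and the margin between the best and second-best group
drives classification.

One consequence of the fixed-length window model is worth stating plainly:
an intron inserted inside the homeodomain means no single 60-residue window
aligns the full profile, so each exon-side window aligns only part of the
columns and scores roughly half a full-length match. Such split loci fall
below the default `E <= 1e-5` operating point and need a more permissive
threshold to be detected (the merge step then bridges the intron, which the
test suite asserts at `threshold_E = 1e-2`). Genomes rich in
homeodomain-splitting introns are better scanned in protein mode on a
predicted proteome, or with a relaxed threshold; by the same token the
synthetic generator leaves introns off by default.

## Classification, duplications, complements

A locus is `assigned` when its score margin is at least `margin_delta`
(default 3 bits — about an 8-fold likelihood ratio between the two best
groups); otherwise it stays `ambiguous`, is reported, but is excluded from
cluster membership and counted separately in the complement table. The three
HOX6-8 subtypes (ftz-like, Antp-like, Ubx/AbdA-like) are distinct groups for
profiles and classification but share one canonical rank for collinearity.
Same-group loci further apart than `min_separation` (default = the merge
gap, so duplication calls and merging cannot disagree) count as separate
copies — absence is 0 and a duplication is 2 in the complement matrix.

## Cluster architecture

A Hox cluster is four or more assigned loci on one scaffold whose hull is at
most `max_span`. The default `max_span` is 300,000 nt (0.3 Mb): compact
nematode clusters span tens to a couple of hundred kb, while the loosely
connected *C. elegans* arrangement spans megabases, so 0.3 Mb separates the
two regimes; it is configurable. When overlapping windows of loci qualify,
selection maximises member count, then minimises span, then takes the
leftmost start, removes those loci and repeats — a total order that makes
detection deterministic and lets an exhaustive window enumeration serve as a
test oracle. Collinearity is scored over member pairs with distinct
canonical ranks: `tau = (C − D) / (C + D)` with `C` the pairs whose genomic
order matches rank order; equal-rank pairs (subtype pairs, duplicate copies)
are excluded, and `tau` is undefined with fewer than two distinct ranks.
Orientation ties break to `+`.

Interruptions are annotated genes, other than the Hox loci themselves, that
overlap the cluster hull by at least one nucleotide. Any-overlap with the
hull is the reproducible reading of "between Hox loci", and errs toward
counting boundary-straddling genes.

## miRNA search

Mature miRNAs (15–30 nt queries) are located by exact `k`-mer seeding
(default `k = 9`) on both strands followed by ungapped extension across the
full query, accepting alignments with identity >= 0.85 and query coverage
>= 0.9, deduplicated per query to the best identity. The thresholds are set
so an exact 22-mer always passes and four or more substitutions never do
(18/22 ≈ 0.818). A caveat follows from seeding: a 22-mer with two
substitutions placed ~7 nt apart can leave no intact 9-mer and will be
missed even though its identity (20/22 ≈ 0.909) clears the threshold; an
E-value-calibrated local aligner would be disproportionate for 22-nt
queries, so this residual insensitivity is accepted and documented.

## Dollo loss mapping

Per orthology group, presence (multiplicity >= 1) across species is
reconstructed on a rooted tree under Dollo parsimony: one gain on the edge
above the last common ancestor of all present leaves, plus the minimal loss
set — the maximal all-absent subtrees inside the gain clade. This matches
the biology of Hox groups, which are ancient and not regained once lost;
an unrestricted Fitch count (`fitch_changes()`) is exposed for comparison.
Polytomies are supported, losses counted per child edge. Species whose loci
are all ambiguous become all-absent rows with a warning, since an
unassignable locus cannot prove presence — and absence in a single assembly
can always reflect assembly gaps rather than true loss, which is why the
event tables should be read alongside the ambiguous-locus counts. The
reconstruction has no explicit "unknown" leaf state; that is a known
limitation. Note also that the loss count is not monotone under adding
present leaves: making one leaf of an all-absent subtree present splits that
subtree into several maximal absent subtrees, so the minimal loss set can
legitimately grow.

## The synthetic generator

`simulate_genome()` emulates exactly what the pipeline must face: i.i.d.
background at GC 0.42 (a typical nematode-like composition), implanted
homeodomain genes per orthology group (group consensus mutated at a chosen
per-site amino-acid divergence, substitutions uniform over the 19
alternatives, back-translated with a deterministic first-codon rule),
optional single introns with canonical `GT...AG` ends (the interior avoids
`T` so no stop codon can open on the implant strand), decoy genes
(composition-preserving shuffles of consensus windows, which destroy the
positional signal, plus random ORFs), and ~22 nt miRNA implants with a
controlled substitution count, all with a ground-truth GFF3 and manifest,
byte-reproducible from one seed. The packaged reference alignment is itself
synthetic (`synthetic_reference_alignment()`): each group gets a random
60-residue consensus and six members mutated at 15% divergence, making
groups separable by construction.

What the generator deliberately does **not** model: codon-usage bias,
repeats and isochore structure, indels within the homeodomain, multi-exon
gene structure beyond one intron, pseudogenes, and correlated substitution
processes. Passing the synthetic suite therefore demonstrates coordinate
correctness, calibration, determinism and the detection/classification
logic — not sensitivity on real, fast-evolving nematode homeodomains, where
profile quality and divergence matter more than anything the simulator
emulates.

## Numerical and scale choices

Desk-scale problem sizes used throughout the tests and the acceptance
script: 1 Mb single-scaffold genomes (10 recovery seeds, 20 null seeds), a
divergence sweep 0 to 0.4 in 0.05 steps with 20 implants per point on
250 kb genomes, Gumbel calibration at 10,000 null windows, and Dollo oracle
checks over all rooted binary shapes on up to 5 leaves (all presence
patterns) plus seeded random topologies with polytomies on 6–7 leaves. The
window scanner is a small C++ kernel with an admissible branch-and-bound
cutoff (per-column best-case suffix sums), which keeps a two-round scan of a
1 Mb genome under ~10 s on one core without changing any reported score.

Other fixed choices: ambiguity codes other than `N` are rejected at input;
`N` codons translate to `X` (0 bits); stop-containing windows are never
reported; duplicate-group members share a rank and are excluded from `tau`;
cluster span boundaries are inclusive; orientation ties break to `+`;
absence thresholds and all defaults above are arguments, not constants.
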