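---
title: "Discovering and characterizing ultraconserved DNA elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and characterizing ultraconserved DNA elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultracons)
```

## The problem

Ultraconserved elements (UCEs) are stretches of DNA that are 100%
identical between the genomes of species separated by hundreds of
millions of years — for example between a cnidarian and a vertebrate.
Perfect identity over ≥50 bp essentially never happens by chance between
two diverged genomes of ordinary size, so such elements are evidence of
extreme purifying selection, and they are repeatedly found near
developmental genes and transcription-factor loci, often acting as
enhancers. `ultracons` implements the complete comparative workflow for
finding and characterizing them:

1. **Masking** — hard-mask tandem repeats and low-complexity sequence so
   that repeat-driven identity cannot masquerade as conservation.
2. **Discovery** — find *all* maximal exact matches (MEMs) at a length
   threshold (≥50 bp; a ≥30 bp "short element" track is run separately)
   between every species pair, on both strands, including non-unique
   matches; then re-mask the matches themselves and trim or drop any
   that are repeat-contaminated.
3. **Merging** — project matches onto each species and join overlapping
   elements into non-overlapping ultraconserved regions (UCRs), carrying
   the set of partner species and 50 bp of flanking sequence.
4. **Clustering** — connect UCRs whose local-alignment *score density*
   (bit score per alignment column) is significant, cluster with Markov
   clustering (MCL), and embed members by 5-mer composition with
   non-centered minimum curvilinear embedding (MCE).
5. **Characterization** — per cluster, test protein-domain enrichment of
   genes within 100 kb (cumulative hypergeometric) and 8-mer
   overrepresentation of a cluster consensus against a 10 kb
   species-proportional random background (cumulative binomial).
6. **Phylogeny** — maximum-likelihood JTT distances from concatenated
   single-copy protein alignments, neighbor-joining, and bootstrap
   support, for the species tree that frames the comparison.

A synthetic-data module generates multi-species genomes with planted
conserved elements, repeats, annotations and JTT-evolved protein
families, so the full pipeline is testable with known ground truth and
no downloads.

## Models and statistics

### Maximal exact matches

A MEM between sequences $a$ and $b$ is a maximal run of agreeing
positions along one diagonal of the comparison: extending it by one base
to the left or to the right *in both sequences simultaneously* meets a
mismatch, a masked base, or a sequence end. Matches are reported
regardless of uniqueness, on both strands; minus-strand matches carry
the forward-strand interval of $b$ whose reverse complement equals the
$a$ substring. `N` never matches anything — including another `N` — so
masked regions and assembly gaps break matches, and scaffold boundaries
are hard separators.

The implementation hashes every `min_length`-mer of $a$ (rolling
polynomial hash) and scans the `min_length`-mers of $b$: every MEM of
length $\ge L$ begins with an exact $L$-mer anchor, and an anchor pair
is extended and emitted only when it is the left end of its diagonal
run, so each MEM is found exactly once. Candidates are verified
character-by-character, so hash collisions cannot create false matches.
On hard-masked genomes, where long shared words outside genuine elements
are rare, this runs in near-linear time; the test suite proves
equivalence against a quadratic diagonal-scanning oracle on hundreds of
random instances.

### Repeat masking

Two detectors are built in, both exact and therefore fully checkable
against brute-force oracles:

* **Tandem repeats**: an interval is masked when it is covered by at
  least `min_copies` (default 4) consecutive copies of a unit of at most
  `max_period` bp (default 6) spanning at least `min_span` bp (default
  24), detected as maximal runs of the lag-$p$ self-match profile. The
  defaults catch homopolymers and microsatellites while leaving random
  sequence untouched.
* **Low complexity**: the union of all sliding windows (default 64 bp)
  whose mononucleotide Shannon entropy falls below 1.5 bits. A uniform
  random 64-mer has entropy close to 2 bits, so random sequence is never
  masked, while skewed or repetitive windows are.

Exact detection (no mismatches inside an array) is a deliberate choice:
the detectors become oracle-verifiable, and users who need
homology-based or approximate-repeat sensitivity can supply any external
mask as a BED file, which is pooled with the built-in intervals.
Discovered matches are masked *again* (`remask_matches`): each match's
sequence is re-scanned, the match is trimmed to its longest unmasked
run, and dropped if the run falls below the length threshold. Trimming
(rather than discarding any contaminated match outright) retains the
conserved portion of elements that merely touch a repeat.

### Merging into UCRs

Overlap means sharing at least one base; book-ended intervals stay
separate. Merging takes the connected components of the overlap
relation, which makes it an idempotent, order-invariant, base-conserving
fixpoint (all three properties are fuzz-tested). The ≥50 bp and ≥30 bp
tracks are merged separately rather than pooled. Flanks shorter than
50 bp at scaffold ends are kept truncated rather than discarded, which
retains elements near scaffold edges — relevant for fragmented
assemblies.

### Similarity graph and MCL

Every pair of UCR sequences (with flanks) is aligned locally
(Smith–Waterman) forward–forward and forward–reverse-complement, and the
better strand is kept, so partially reverse-complementary elements still
attract each other. Scoring defaults mimic classic blastn (+2/−3, gap
open 5, extend 2) with Karlin–Altschul parameters $\lambda = 0.625$,
$K = 0.41$; the bit score is $(\lambda S - \ln K)/\ln 2$ and the E-value
$mn\,2^{-\mathrm{bit}}$. An edge exists when the E-value is at most
$10^{-5}$ — a gate that on random desk-scale sequences essentially never
fires by chance — and its weight is the score density (bit score per
alignment column), which normalizes for the wide length range of UCRs.

MCL iterates expansion (squaring the column-stochastic matrix) and
inflation (entrywise power 2.0, then column renormalization) to a
fixpoint, with self-loops set to each node's maximum incident weight,
per-column pruning at $10^{-5}$ and convergence at $10^{-6}$ on the
maximum entry change. Clusters are the connected components of the
converged matrix's support, which assigns every node exactly once and is
invariant to node order. Disconnected graph components can never merge —
expansion cannot create probability across a zero cut — and that
property, along with the weak-bridge clique benchmark, is tested
directly.

### Non-centered MCE

Each UCR is represented by its normalized forward-strand 5-mer
frequency vector (windows containing `N` are skipped). Euclidean
distances between profiles feed a minimum spanning tree; the *minimum
curvilinear kernel* is the matrix of pairwise geodesic distances along
that tree, and coordinates come from the top singular vectors of the
kernel — decomposed *without* centering — scaled by the square roots of
their singular values. Following paths through the MST instead of
straight lines lets elongated, sparse structures separate in few
dimensions. Two numerical notes: MST ties are broken lexicographically
by edge index so the embedding is deterministic, and each axis is
sign-flipped so its largest-magnitude loading is positive. One property
of the non-centered variant worth knowing when reading the plots: the
kernel is entrywise non-negative, so its leading singular vector is a
near-constant "centrality" axis, and group separation appears from the
second dimension onward — assess structure in the top two or three
dimensions together, not in dimension 1 alone.

### Domain enrichment

For a cluster, the species pool is every gene of every species
represented in the cluster, $G$ is the pool size, $g$ the number of
unique genes whose interval lies within 100 kb of any member UCR
(gap distance; overlap is 0; the boundary is inclusive), and $D$ and $d$
count genes *carrying* a domain in the pool and the nearby set. Counting
carriers rather than domain copies keeps $D \le G$ and the urn model
coherent. The p-value is the upper cumulative hypergeometric

$$P = \sum_{i=d}^{\min(D,g)} \frac{\binom{D}{i}\binom{G-D}{g-i}}{\binom{G}{g}},$$

computed in log space. Clusters with fewer than 10 nearby genes are
skipped; the display flag marks rows with raw $p < 0.05$ and $d \ge 3$,
and Benjamini–Hochberg-adjusted values are emitted per cluster as an
extra column for users who prefer adjusted inference.

### Motif overrepresentation

Each cluster's representative is a center-star consensus: the member
with the highest summed pairwise alignment score is the center, the
others are globally aligned to it and voted per center column (majority
base, alphabetical ties, gap-majority columns dropped; insertions
relative to the center are not voted — for the low-divergence clusters
this consensus serves, such columns would be gap-majority and dropped
anyway). The background is a 10 kb mosaic of 100 bp segments sampled
uniformly from the unmasked portion of each genome, with species shares
equal to the cluster composition (largest-remainder rounding makes the
length exact). For each 8-mer occurring in the representative, $x$ is
its overlapping forward-strand count, $n = L - 8 + 1$ the number of
sliding windows, and the background probability uses add-one smoothing,
$p = (c+1)/(N-7+1+1)$, because a 10 kb background undersamples the
65,536 possible 8-mers and an unsmoothed $p = 0$ would degenerate the
tail. The p-value is the upper cumulative binomial
$F(x\,|\,n,p) = 1-\sum_{i=0}^{x-1}\binom{n}{i}p^i(1-p)^{n-i}$; rows
below $10^{-4}$ are flagged. Forward-strand counting matches the
single-sequence trial model; reverse-complement pooling is available as
an option but off by default.

### Phylogeny

Pairwise distances are maximum-likelihood branch lengths under the
rate-normalized JTT amino-acid model (uniform rates across sites,
pairwise deletion of gap/ambiguous columns), found by bounded 1-D
optimization on $[0, 10]$ substitutions/site; saturated pairs return the
bound with a warning. The tree is Saitou–Nei neighbor joining, which is
exact on additive matrices; negative branch estimates are clamped to
zero with the excess moved to the sibling edge so tip-to-tip path
lengths are preserved. Bootstrap support resamples supermatrix columns
with replacement (families are concatenated first — the standard choice
when a single tree is wanted), recomputes distances and tree, and
reports the percentage of replicates containing each internal
bipartition. The default is 500 replicates; the test suite uses 100,
which is ample for the well-separated synthetic trees it checks.

## What the synthetic data does and does not emulate

`simulate_study()` builds the standard test-bed: i.i.d. background
genomes with a single GC parameter, planted elements written *over* the
background (replacement, not insertion, so coordinates stay fixed) for
random species subsets and strands, tandem repeats planted with the same
unit in every species (so that only masking prevents them from surfacing
as fake conservation), and annotations with a domain label placed at
controlled distances from elements. Mutated element copies receive exact
substitution counts; indels are excluded because discovery is gap-free.

Two deliberate design points. First, the background model is zeroth
order: no isochores, no composition heterogeneity, no gene structure —
k-mer statistics stay analytically checkable, which is what makes the
motif calibration test meaningful. Passing tests therefore demonstrate
algorithmic correctness, not robustness to every artifact of real
assemblies. Second, `plant_elements()` *seals* element boundaries by
default: the single background base adjacent to each end of a placement
is set so it differs across all copies (complement-aware on the minus
strand). Without sealing, a maximal match extends past the planted
boundary with probability about 1/4 per side, and planted coordinates
would not be recoverable even by a perfect detector; sealing makes
"recovered with exact coordinates" a meaningful truth condition.

All randomness flows from one global seed, expanded into per-stage seeds
by hashing stage names (`sub_seed`), so any stage can be reproduced in
isolation and reruns are bit-identical.

## Problem sizes and defaults

The shipped study conditions are three species of 1 Mb each with 50
planted elements (50–300 bp, mixed strands and subsets) and 10 planted
repeats; the full pipeline on those conditions runs in a few minutes on
one core. Thresholds default to the standard settings: `min_length` 50
(30 for the short track), `flank` 50, gene `window` 100000 with
`min_genes` 10, MCL `inflation` 2.0, edge gate `max_e` 1e-5, `k` 5 for
embedding and 8 for motifs, 10 kb background, motif flag threshold 1e-4,
and 500 bootstrap replicates.

## Worked example

```{r example, eval = FALSE}
library(ultracons)

cfg <- pipeline_config(
  list(n_species = 3, scaffold_length = 1e6, n_elements = 50,
       element_length = c(50, 300), n_repeats = 10),
  seed = 11, outdir = "ultracons_out")
out <- run_pipeline(cfg)

out$manifest$counts
ep <- truth_exact_pairs(out$results$truth, 50)
nrow(ep)                      # planted exact pairs at the >= 50 bp threshold
head(out$results$ucrs[, 1:7]) # merged UCRs with partner species
```

## Known limitations

* Exact-only repeat detection: diverged transposon copies are invisible
  to the built-in detectors; supply an external BED mask for
  CENSOR-grade sensitivity.
* Full dynamic-programming alignment in graph building is quadratic in
  the number of UCRs; it is comfortable at desk scale (hundreds to a few
  thousand elements) but is not a BLAST replacement.
* The binomial motif model treats overlapping windows as independent
  trials; for highly periodic 8-mers this overstates significance
  slightly, as it does in the original statistic.
* Uniform-rate JTT without gamma heterogeneity slightly underestimates
  large distances on real proteins; for the synthetic families the model
  is exact by construction.
* Ortholog calling is out of scope: single-copy protein families arrive
  as aligned input or from the simulator.
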