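---
title: "Comparing immune receptor repertoires with summary divergences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing immune receptor repertoires with summary divergences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repsum)
```

## The problem

An annotated AIRR-seq dataset is a table of rearrangement records: aligned
read and inferred germline, V/D/J gene calls, junction (CDR3) nucleotide
and amino-acid sequences, per-end exonucleolytic deletion lengths,
non-templated np1/np2 insertion strings, clonal-family labels, and
sometimes per-clone phylogenies.  Comparing two such datasets directly is
hopeless; comparing them through a battery of one-dimensional summaries is
tractable and interpretable.  `repsum` computes those summaries, equips
each with a divergence suited to its type, approximates the expensive ones
with convergence control, ranks summaries by how well they discriminate
datasets, and scores generative simulators by how faithfully they
reproduce each summary.

The package assumes annotation, clonal clustering and tree inference have
already been done by external tools; its capability ladder
(`alignment_only < annotated < clustered < phylogenetic`) simply records
which columns are present and gates which summaries run.  No annotation is
ever inferred internally.

## Divergences

Scalar summary distributions are compared with the Jensen–Shannon
divergence in natural log, so values live in `[0, ln 2]`.  Empirical
samples are discretized on shared equal-width bins spanning the pooled
range, with the bin count tied to the complexity of both samples:
`B = max(min(m, n), 2)` where `m` and `n` are the numbers of distinct
values.  Bins occupied by only one sample would contribute an infinite KL
term and are discarded from both sides, after which the retained masses
are renormalized.

Numerical conventions the definition leaves open, fixed here once:

* bins are left-closed/right-open with the last bin closed
  (`findInterval(..., rightmost.closed = TRUE)`), over pooled-range
  endpoints;
* when the two samples share *no* occupied bin, every bin is one-sided and
  the rule above would leave nothing; totally disjoint samples are
  maximally divergent, so `ln 2` is returned with a warning;
* two point masses at the same value compare as identical (JSD 0) without
  binning, since the pooled range is degenerate.

A consequence worth knowing: for continuous-valued samples whose values
are all distinct, `B` grows with the sample size and the per-bin counts
stay at order one, so the JSD between two samples from the same continuous
distribution does *not* decay with `n`.  For the integer-valued summaries
that dominate this domain (lengths, counts, edit distances) the support
saturates, the binning stabilizes, and the JSD decays as expected; the
test suite demonstrates this with Poisson samples.

Categorical counts (gene usage, amino-acid k-mers) use the ℓ1 divergence
over the union of categories, missing categories counting as zero.
Repertoire-level comparisons normalize counts to relative frequencies by
default so that repertoires of different sizes are comparable; the raw
form is available everywhere (`normalize = FALSE`).  Transition matrices
are compared by ℓ1 over their 16 row-normalized cells, per-gene rate
profiles and Hill-number profiles by raw ℓ1, and scalar summaries by
absolute difference.

## Subsampled approximation

Exhaustive pairwise-distance distributions cost `n(n-1)/2` edit distances.
`approximate_distribution()` draws batches of `batch_size = 30` records,
applies the summary per batch, appends the values to a rolling vector, and
stops when the JSD between successive iterates drops below
`tolerance = 0.001`; at least two batches are always drawn, and a
`max_iterations` cap (default 10⁴) guards the otherwise unbounded loop.
The convergence check reuses exactly the divergence module's JSD so there
is a single JSD definition in the package.

Nearest-neighbor distances violate the assumption that a subsample's
summary follows the full-data distribution: removing sequences can only
leave each minimum unchanged or larger, so a subsample-only estimate is
biased upward.  `approximate_nn_distribution()` therefore computes, per
batch, the *exact* `d_NN` of each sampled sequence against the full
repertoire — every emitted value is a member of the exact multiset — and
uses a tighter default tolerance of `10⁻⁴`, since each batch is costlier
and the quantity converges slowly in distribution.

On small inputs (`n ≤ 2 × batch_size`) both routines return the exact
distribution and record `mode = "exact"`; approximating is pointless when
two batches already cover the data.

Sampling is without replacement within a batch and independent across
batches, which keeps the "rolling average of empirical distributions"
interpretation.

## String distances

The default string metric is the Levenshtein edit distance, with Hamming
available for equal-length inputs.  Distances are computed by a blocked
bit-parallel (Myers/Hyyrö) kernel in C++, which processes 64 dynamic
programming cells per machine word; on the ~350 nt reads the generator
produces, the half-million pairwise distances of a 1,000-read repertoire
take a few seconds.  The kernel is validated in the test suite against
`utils::adist` on thousands of random string pairs, including lengths
crossing the 64- and 128-bit block boundaries.

IMGT gap characters (`.` and `-`) are stripped before any distance is
computed.  For sequence/germline pairs the degapping is pairwise
consistent — positions gapped in either string are dropped from both — so
positional correspondence survives for mutation calling.

## Summary conventions

* **Gene calls** keep only the first entry of comma-separated lists and
  collapse alleles (`*NN` suffix) to the gene level before counting, so
  usage distributions are comparable across annotation tools; both
  behaviors can be disabled.
* **CDR3 summaries** operate on the AIRR `junction`/`junction_aa` fields
  as provided (the junction includes the conserved anchors); the package
  does not re-extract CDR3s.
* **Ambiguity**: N bases are excluded from the GC denominator and from
  mutation calling, match nothing in motif search, and break adjacency in
  transition counting.  Amino-acid records containing letters outside the
  standard 20 are skipped by the physicochemical summaries.
* **Motifs** default to the canonical AID hotspots (WRC, GYW, WA, TW) and
  coldspots (SYC, GRS), counted on the given strand with overlapping
  matches, summed over motifs.  Both sets are arguments.
* **Physicochemical scales**: Kyte–Doolittle (GRAVY), Grantham polarity,
  Zimmerman bulkiness, Atchley and Kidera factor tables are embedded as
  documented constants (`aa_property_scales`); basicity/acidity/aromaticity
  are residue-class fractions; charge is Henderson–Hasselbalch at pH 7.4
  with the EMBOSS pKa set including the termini; the aliphatic index is
  Ikai's mole-percent formula with coefficients 2.9 and 3.9.  Factor
  aggregation over a sequence is the arithmetic mean per factor, giving
  one scalar per sequence per factor.
* **Positional mutation distances** are gaps between *consecutive* sorted
  mutated positions, not all pairs — "distance between mutations" read as
  spacing along the sequence.
* **In-frame percentage** uses the tool-independent criterion: junction
  length divisible by three.
* **Tree indices**: Sackin is the sum of leaf depths in edge counts;
  cophenetic is the sum over leaf pairs of the MRCA depth; the
  Colless-like index follows Mir et al.'s generalization with
  `f(n) = ln(n + e)` and mean-deviation dissimilarity, both configurable.
  Trees with fewer than two leaves are skipped.

## Informativeness ranking

The design matrix stacks per-sequence summary values over datasets, with
dataset identity as a multinomial response.  Only sequence-level summaries
qualify (a pairwise-distance distribution has more values than sequences
and cannot fill a column); nearest-neighbor distances, though one per
sequence, depend on the whole set and are excluded from the default
covariates.  Kidera and Atchley factors are excluded by default (they are
linear combinations of the same composition information and crowd the
ranking) and re-includable by flag.  Columns are standardized; constant
columns are dropped with a warning; rows with any missing value are
dropped rather than imputed — the simplest defensible contract.

The ℓ1-penalized multinomial path is fit by `glmnet` over 100 log-spaced
lambdas down to `10⁻³ λ_max` (the conventional path).  For class `d` and
summary `s`, the branch-off point `t[d, s]` is the largest grid lambda at
which the coefficient is nonzero *and stays nonzero for all smaller
lambdas* — the stable entry point into the active set, matching the idea
of coefficients "branching off" from zero; coefficients that are inactive
at the smallest lambda never branched and get `t = ∞`.  Within a class,
earlier branch-off means a better (smaller) rank and never-branched
summaries rank last.  Final scores rank the per-summary medians across
classes.

Two randomization details matter.  Coefficients below `10⁻⁸` in absolute
value count as zero (solver noise).  And covariates are presented to the
solver in seeded random order: coordinate descent resolves exactly
collinear columns in favor of whichever it sees first, so without the
permutation duplicated summaries would be ranked alphabetically — the
artifact the tie randomization exists to avoid.  Exact ties in `t` are
additionally broken by seeded random ranks.

## Simulator validation

For `k ≥ 2` observed/simulated pairs and a summary `s`,

```
LRAD-data(s) = ln( mean over distinct observed pairs of D_s(R_i_obs, R_j_obs)
                 / mean over i of D_s(R_i_obs, R_i_sim) )
```

and `LRAD-sim` replaces the numerator with simulated-simulated pairs; the
two modes share the denominator.  Since `D_s` is symmetric, the mean over
ordered cross-pairs equals the mean over unordered pairs, which is what is
implemented; the hand-checkable case (`k = 2`, cross-pair divergence 4,
within-pair 2) gives exactly `ln 2`.  Degenerate cases are reported
explicitly rather than propagated as NaN: zero denominator with positive
numerator is `+Inf` (a perfect simulator), zero numerator with positive
denominator is `-Inf`, both zero is `NA` (undefined).

Divergence matrices are computed once per unordered pair and mirrored,
and embedded with classical (Torgerson) MDS — deterministic and seed-free,
with missing dimensions of rank-deficient configurations padded with
zeros.

## The synthetic generator

`generative_spec()` defines a fully known generative model so every
summary can be tested against ground truth without downloads:

* germline pools of 10 V (300 nt), 5 D (20 nt), 6 J (50 nt) random
  sequences — realistic lengths, synthetic content — drawn reproducibly
  from a `pool_seed` kept separate from the sampling seed so different
  repertoires can share germlines;
* non-uniform but fixed usage probabilities (geometric decay with ratio
  `2^(-1/2)`, so the most- and least-used V genes differ about 20-fold,
  as real repertoires do);
* per-end deletion lengths geometric with `p = 0.2` capped at 8–12 nt
  (mean ≈ 3.7 nt) and insertion lengths geometric with `p = 0.2` capped
  at 15 (mean ≈ 4), typical of IGH rearrangements;
* insertion nucleotides from a first-order Markov chain with a fixed,
  mildly GC-biased transition matrix — exactly the object the
  transition-matrix summary estimates;
* clone sizes `1 + Geometric(0.5)` capped at 21, and star-genealogy
  mutation: each descendant receives i.i.d. point substitutions at
  `mutation_rate = 0.03` per site, a mid-range somatic hypermutation
  load;
* the junction spans the last 3 nt of the trimmed V through the first
  3 nt of the trimmed J, with `junction_aa` translated for in-frame
  records and missing otherwise, and `productive` requiring in-frame and
  stop-free.

What it deliberately does **not** emulate: SHM hotspot targeting (mutations
are uniform, so motif-count summaries have no mutation signal), selection,
indels within reads, tree-structured clonal evolution (phylogenetic
summaries are exercised on explicit Newick fixtures instead), allelic
diversity, and IMGT gap structure.  Passing tests therefore certify the
*statistical machinery* — not that any simulator reproduces real biology.

`perturb_repertoire()` changes exactly one targeted property
(junction-length shift, marginal-preserving gene shuffle, mutation boost,
junction composition scramble) so divergence, LRAD-sign and
ranking-recovery tests can be built with known structure.  The
composition scramble redraws `junction_aa` from a strongly
hydrophilic-biased residue distribution: the generator's junctions are
already near-random nucleotide translations, so an unbiased redraw would
barely move physicochemical summaries, and the point of the knob is a
simulator that decisively distorts them.

## Problem sizes and tolerances in the tests

The suite checks oracle equivalence on 50-record repertoires
(bit-for-bit for integer summaries, 10⁻¹² for floats), nearest-neighbor
unbiasedness on 200 sequences over 50 seeds against a three-standard-error
bound, subsampling convergence on 1,000 sequences over 20 seeds (JSD to
the exhaustive distribution below 0.01), parameter recovery at 10⁴
records drawn one-per-clone so draws are i.i.d. (transition rows within
ℓ1 0.05 at ≥10⁴ pooled transitions, V usage within ℓ1 0.03), LRAD sign
contracts over 20 seeds, and ranking recovery at a 3-standard-deviation
class separation over 50 seeds.  These sizes make each stochastic bound
comfortably attainable under sampling theory while keeping the full suite
around three minutes.

## Known limitations

* The JSD binning rule ties `B` to support sizes; for genuinely continuous
  summaries on large samples it over-resolves and divergence estimates
  between same-distribution samples plateau (see above).  Integer-valued
  summaries are unaffected.
* Hamming distance requires equal-length inputs and errors otherwise; no
  alignment is attempted.
* The amino-acid scales for polarity/bulkiness/basicity/acidity are
  embedded published tables, documented in `?aa_property_scales`; other
  toolkits may embed different constants for the same names, which shifts
  absolute values but not comparisons made consistently within this
  package.
* LRAD values for stochastic (approximated) summaries inherit Monte-Carlo
  noise; fix the seed in `approx_config()` when reproducibility across
  runs matters.
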