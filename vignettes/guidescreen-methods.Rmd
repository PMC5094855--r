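---
title: "Models and methods behind guidescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind guidescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

guidescreen implements a complete desk-scale pipeline for CRISPRi/CRISPRa
sgRNA design and pooled-screen analysis: hybrid TSS annotation from CAGE
peaks and transcript models, candidate enumeration and feature engineering,
an elastic-net activity model with kernel-smoothed positional effects,
tiered off-target filtering, rule-based library selection with matched
negative controls and synthesis-ready oligos, and screen quantification
(growth phenotypes, Mann-Whitney gene calls, ROC/precision-recall
benchmarks). A seeded synthetic-world generator makes every stage testable
without any external downloads.

This vignette explains the models, their assumptions, the tunable
parameters and the design decisions taken where the design was genuinely
open. It states no empirical result that the package's tests do not
themselves compute.

# TSS annotation

CRISPRi represses and CRISPRa activates transcription only when dCas9 is
recruited close to the transcription start site actually used by the cell,
so annotation quality directly bounds library quality. The hybrid rule set,
applied strictly in order per gene, is:

1. **Matched CAGE peaks** — same-strand peaks labeled `p1@gene` / `p2@gene`
   within 30 kb of any transcript TSS for that gene. Among multiple
   matches the peak closest to a known transcript TSS wins (ties break by
   lower genomic coordinate).
2. **Primary peaks** — otherwise, any same-strand peak labeled "p1"/"p2"
   within 500 bp.
3. **Robust / permissive peaks** — otherwise an unlabeled CAGE peak within
   200 bp, robust tier preferred.
4. **Annotation** — otherwise a 1-bp range at the 5'-most transcript TSS.

A p1 and p2 pair is merged into one "P1P2" range when the peaks are at
most 1 kb apart; farther pairs are targeted separately, each by its own
full guide allotment. Decisions the conventions above leave open, resolved here once:

* *Distance measurement*: all "within X bp" tests measure from the nearest
  peak edge to the transcript TSS coordinate — the conservative reading.
* *Secondary peaks*: a p2 peak is used only if it passes the robust tier;
  a gene with a robust p2 but no p1 is annotated from the p2 alone.
* *Coordinates*: 0-based half-open everywhere internally, matching BED.

# Candidate enumeration and features

Candidates are 19-nt protospacers followed by an NGG PAM on either strand.
The position of a guide is the genomic coordinate of the 3' G of its PAM,
expressed relative to the gene's transcriptional direction (positive =
downstream). CRISPRi enumerates sites between −25 and +500 bp of either
edge of each TSS range; CRISPRa between −550 and −25 bp. Expression
sequences are the protospacer with a 5' G prepended (20 nt), ensuring
robust U6 transcription regardless of the genomic base.

Per guide the feature roster comprises:

* **Position** (4): signed distances to the upstream/downstream edges of
  the primary and secondary TSS ranges; missing secondary ranges are
  flagged, never zero-filled.
* **Sequence** (~560): per-position base one-hots over a 4-nt 5' flank,
  the protospacer, the PAM N position and a 3-nt 3' flank; dinucleotide
  one-hots at every adjacent pair of that context; base counts, GC
  fraction, longest homopolymer run per base (a single tested definition,
  the run anywhere within the protospacer), and protospacer length. The
  exact flank extents are configuration; the roster is data, not code,
  and its hash is stored with every model.
* **RNA structure** (4): minimum free energy and paired-base count for the
  20-nt guide alone and for guide + constant region. Because no
  thermodynamic folding library is available in the supported environment,
  folding uses an in-package dynamic program over a base-pair energy model
  (GC −3, AU −2, GU −1 kcal/mol, minimum loop 3 nt, no stacking or loop
  entropies). It preserves the interface and the qualitative ordering
  (structured guides score negative; unpairable ones exactly 0) but its
  absolute energies are not ViennaRNA energies. Tests validate it against
  exhaustive structure enumeration at small lengths.
* **Chromatin** (one per track): mean signal over the 22-bp site including
  the PAM, from BigWig or bedGraph tracks (e.g. MNase-, DNase-, FAIRE-seq).
  Sites with no data are marked missing; chromatin features are optional
  (e.g. for mouse designs).

# Activity model

Empirical activity scores come from screens: per hit gene, each sgRNA's
phenotype is divided by the mean of the gene's top-3 guides by absolute
value, so the best guides score ≈ 1. Hit genes satisfy
|z × log10 p| ≥ 20 in at least one screen (a relaxed threshold of 7 is
used when collecting empirical evidence for library selection).

Features are linearized before regression:

* **Binning** — each numeric feature is cut into fixed-width bins over its
  range (default: range/15), with sparse edge bins (< 5 points) merged
  inward; each value then contributes a single indicator.
* **Position curves** — activity is regressed on each signed distance with
  a radial-basis-function kernel regressor; the fitted curve evaluated at
  a guide's position becomes its transformed parameter. The supported
  environment ships no SVM implementation, so the regressor is RBF kernel
  ridge regression written in-package. It keeps the same hyperparameter
  surface (C = inverse regularization, gamma = kernel bandwidth; grids
  10^−2..10^3 and 10^−7..10^−2), 3-fold cross-validated grid search inside
  the training set, and is deterministic given the seed. The position
  window defaults to ±1500 bp; predictions outside clamp to the window
  edge. At toy scale the secondary-TSS distances rarely reach the 200-pair
  minimum; the linearizer then degrades to a presence indicator with a
  warning rather than fitting an unsupported curve.
* **Binary passthrough** — one-hot features enter unchanged.

All linearized parameters are z-standardized with training-set statistics
(stored exactly in the model) and fit with elastic-net linear regression;
the l1/l2 ratio (grid 0.1/0.25/0.5/0.75/0.9) and the regularization
strength (glmnet's lambda path) are chosen by seeded cross-validated grid
search — choosing the ratio by CV is the established convention; the
strength search is this package's choice, reusing CV since a strength
must be chosen somehow. Train/test splits are **always by gene** (80/20 for
CRISPRi-style designs, 67/33 for CRISPRa-style), never by sgRNA, to
prevent leakage between guides of the same promoter. Predicted scores are
left unclipped; a clamp is trivial for callers that want one.

Model evaluation labels guides with empirical activity > 0.75 as highly
active and reports trapezoidal ROC-AUC over the full prediction ranking.
Per-category contributions are the 95th-minus-5th percentile of each
guide's summed weighted parameters within the category.

# Off-target filtering

Every NGG-adjacent site in the genome is scored with a position-weighted
mismatch score: the sum of per-position penalties at mismatched
protospacer positions (perfect match 0; non-NGG sites are not alignments).
Published per-position weight vectors exist but are not bundled here, so the
default is `round(seq(1, 12, length.out = 19))`, increasing toward the
PAM, chosen so that one mismatch never reaches the genome-wide threshold
(21), two PAM-proximal mismatches do, and three exceed the TSS-proximal
threshold (31) — preserving the semantics that near-perfect duplicates of
a target site are disallowed. The vector is configuration and a published
vector can be substituted verbatim.

Alignments are found by exhaustive scan (an indexed comparison of every
genomic NGG site), which gives exact recall at desk scale with the same
score semantics as a sensitivity-tuned aligner. TSS-proximal space is the
merged union of 1-kb windows around every annotated TSS range and every
transcript 5' end. Stringency tiers, strictest first:

| tier | condition |
|------|-----------|
| T0 | ≤ 1 alignment < 31 proximal AND ≤ 1 alignment < 21 genome-wide |
| T1 | ≤ 1 alignment < 31 proximal |
| T2 | ≤ 1 alignment < 21 genome-wide |
| T3 | ≤ 2 alignments < 31 proximal |
| T4 | ≤ 3 alignments < 31 proximal |
| FAIL | none of the above |

Tier assignment is a pure function of the two count statistics, so adding
an off-target site can never improve a guide's tier (property-tested).

# Library selection, controls, oligos

Per TSS, up to 10 guides are selected: first up to 2 empirically
validated guides (activity ≥ 0.75, within 5 kb of the TSS, tier T0, no
extra restriction sites, ≥ 3 bp shifted from previously selected sites);
further qualifying empirical guides instead receive +0.2 on their
predicted score; remaining slots fill by descending predicted score under
the same filters, relaxing the tier T0→T4 only as needed; a TSS that
cannot reach 10 guides at T4 is reported untargeted. Ties break by lower
genomic coordinate, then + strand; the 3-bp shift applies only between
same-strand sites.

Negative controls are sampled per-position from the library's base
frequencies and kept only with zero alignments under 31 in proximal space
and zero under 21 genome-wide. Oligos follow the 84-bp template: 18-nt 5'
adapter, BstXI arm `CCACCTTGTTG`, the 20-nt expression sequence, BlpI arm
`GTTTAAGAGCTAAGCTG`, 18-nt 3' adapter. The restriction filter flags
BstXI/BlpI/SbfI recognition sites anywhere outside the two intended arm
positions, scanning the full assembly so junction-spanning sites are
caught (all three sites are palindromic, so one strand suffices).

# Screen quantification

Counts from T0 and endpoint samples (per replicate) yield growth
phenotypes γ: guides under 50 reads in **both** samples are excluded;
counts are depth-normalized to equal totals (pseudocount 1.0, both
choices configurable — the original values are unstated); the log2 ratio
is centred on the median of the non-targeting guides (so their median γ is
exactly 0 per replicate) and divided by the cell doublings; replicates are
averaged.

Gene scores per TSS: phenotype = mean of the top-3 guides by |γ|; p =
two-sided Mann-Whitney of all the TSS's guides against all non-targeting
guides (exact for small tie-free groups, tie-corrected normal
approximation otherwise; the attainable p floor is reported since strong
genes saturate it). Multi-TSS genes collapse to the lowest-p TSS.
Negative-control pseudo-genes — 10 non-targeting guides sampled with
replacement — are scored identically and define both the z-scale and the
empirical FDR. Hits satisfy |z × −log10 p| ≥ threshold; the default
threshold is calibrated to a pseudo-gene pass rate of 0.21% (the observed
operating point; the original threshold value is never printed).
Benchmarks: guide-level ROC over the γ ranking of essential- vs
non-essential-targeting guides; gene-level precision-recall with
recall-at-95%-precision; active fraction = essential-targeting guides with
z < −2 against the non-essential-targeting distribution.

# The synthetic world

`make_toy_reference()` builds a two-contig random genome whose genes cycle
through every annotation-support case, with a nucleosome-like chromatin
track (sinusoid of period 190 bp decaying over 1 kb downstream of each
TSS). `simulate_activity_dataset()` plants activity = positional term
(same periodicity and decay) + small sequence effects (GC, G-after-PAM) +
Gaussian noise (sd 0.1), renormalized per gene to the top-3 convention.
`simulate_screen_counts()` draws negative-binomial counts (overdispersion
0.05) around endpoint expectations ∝ 2^(γ·doublings), with lognormal T0
abundances, 500× mean depth and 10 doublings — values a growth screen of
this type would consider routine. These defaults are the stated world of
the tests and are not revisited.

What a green test does establish: the estimators recover what the
generator planted (positional curve r ≥ 0.9, sparse coefficients r ≥ 0.9,
essential-gene recall ≥ 0.9 at 95% precision, null p-values uniform).
What it does not: real human sequence composition, real nucleosome maps,
batch effects, or the absolute AUC/recall figures reported for genome-scale designs, which
require the real genome and datasets.

# Numerical choices and limitations

* Bin edges, standardization statistics and kernel support vectors are
  stored in the model (serializable to versioned JSON), so prediction is
  a pure function of (model, features); a roster-hash mismatch is an
  error, never a silent coercion.
* Degenerate inputs: constant features are dropped; constant activities
  yield a flat position model with a warning; single-class evaluation sets
  raise errors rather than returning NaN AUCs.
* The folding energies and mismatch weights are simplified stand-ins (see
  above) — both are configuration points where published parameter sets
  can be dropped in.
* The exhaustive off-target scan is exact but quadratic in practice; at
  genome scale a seed-and-extend accelerator would be an optimization,
  not a semantic change.
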