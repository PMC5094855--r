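# guidescreen

Design and scoring of CRISPRi/CRISPRa sgRNA libraries and pooled screens.

## The problem

CRISPR interference (dCas9-KRAB) and activation (dCas9-SunTag-VP64) act by
parking dCas9 near a gene's transcription start site, so their guide RNAs
succeed or fail on three things: how well the TSS is annotated, where the
guide sits relative to it (nucleosome phasing makes this sharply
periodic), and the guide's own sequence and structure. guidescreen is for
functional-genomics groups building or analyzing such screens. It
implements, end to end:

* **Hybrid TSS annotation** — CAGE peaks (FANTOM-style `p1@gene`/`p2@gene`
  BED) reconciled with transcript models through a strict matching
  hierarchy (matched peaks within 30 kb → labeled peaks within 500 bp →
  robust/permissive peaks within 200 bp → the annotation itself), with
  P1/P2 merging at ≤ 1 kb.
* **Guide enumeration and features** — all 19-nt + NGG sites within
  −25..+500 bp (CRISPRi) or −550..−25 bp (CRISPRa) of the TSS-range
  edges; positional distances, one-hot sequence context, RNA-structure
  metrics, chromatin-track means.
* **Activity model** — features are linearized (fixed-width bins; RBF
  kernel position curves fit by cross-validated grid search over C and
  gamma), z-standardized, and fit with elastic-net regression
  (`score = β₀ + Σᵢ βᵢ zᵢ`, l1/l2 ratio and strength by seeded CV),
  always with gene-wise train/test splits.
* **Off-target tiers** — every genomic NGG site scored by a
  position-weighted mismatch score (perfect match 0); stringency tiers T0
  (≤ 1 alignment < 31 TSS-proximal and ≤ 1 < 21 genome-wide) through T4,
  relaxed only as needed.
* **Library selection** — per TSS up to 10 guides: empirically validated
  guides first (activity ≥ 0.75, ≤ 5 kb, T0), a +0.2 predicted-score
  bonus for the rest, then predicted-score order with restriction-site
  (BstXI/BlpI/SbfI) and 3-bp-shift filters; composition-matched
  non-targeting controls; 84-bp synthesis oligos.
* **Screen scoring** — growth phenotype γ = depth-normalized log2
  enrichment, centred on non-targeting guides, per cell doubling; gene
  phenotype = mean of the top-3 |γ| guides; Mann-Whitney p against the
  non-targeting set; hits by |z × −log10 p| with an empirical FDR from
  negative-control pseudo-genes; ROC and precision-recall benchmarks
  against gold-standard gene sets.
* **Synthetic fixtures** — seeded generators for toy genomes, CAGE peaks,
  chromatin tracks, activity datasets and screen counts with planted
  truth, so the whole pipeline is testable offline.

## Worked example

```r
library(guidescreen)

# 1. a seeded toy world: genome, transcripts, CAGE peaks, chromatin
ref <- make_toy_reference(seed = 1, n_genes = 10, contig_len = 50000)
ann <- assign_tss_table(ref$transcripts, ref$peaks)
head(ann[, c("gene", "strand", "primary_start", "primary_end", "support")], 4)
#>     gene strand primary_start primary_end            support
#> 1 GENE01      +          9641        9961 cage_matched_peaks
#> 2 GENE02      -          9659        9679 cage_matched_peaks
#> 3 GENE03      +         17292       17312 cage_matched_peaks
#> 4 GENE04      -         17601       17621 cage_primary_peaks

# 2. enumerate CRISPRi candidates and compute features
fz <- featurize_genes(ref$genome, ann, "CRISPRi", tracks = ref$tracks)
nrow(fz$candidates)   #> 861 candidate guides
ncol(fz$features)     #> 575 features each

# 3. train the activity model on (here: simulated) activity scores
act <- simulate_activity_dataset(fz$candidates, fz$features, ref$truth, seed = 2)
mod <- fit_activity_model(fz$features, act, seed = 3, nfolds = 3)
te  <- act[act$gene %in% mod$test_genes, ]
fte <- fz$features[match(te$sgrna, rownames(fz$features)), ]
attr(fte, "kind") <- attr(fz$features, "kind")
attr(fte, "roster_hash") <- attr(fz$features, "roster_hash")
evaluate_model(mod, fte, te$activity)$auc
#> 0.947        # held-out ROC-AUC for calling guides with activity > 0.75

# 4. off-target tiers and library selection (10 guides per TSS)
prox  <- proximal_reference(ann, ref$transcripts)
idx   <- genome_site_index(ref$genome)
tiers <- offtarget_report(fz$candidates, proximal = prox, index = idx)
lib   <- select_sgrnas(fz$candidates, predict_activity(mod, fz$features),
                       tiers, expand_tss_units(ann))
table(lib$tier)
#>  T0
#> 120          # 12 TSS units x 10 guides, all at the strictest tier

# 5. an 84-bp synthesis oligo for the top-ranked guide
format_oligo(lib$expression_seq[1],
             "GTGGAAAGGACGAAACAC", "CAAGGTCTTCTCGAAGAC")$oligo
#> "GTGGAAAGGACGAAACACCCACCTTGTTGGGGAGCTATTAATGAGGCCAGTTTAAGAGCTAAGCTGCAAGGTCTTCTCGAAGAC"
```

The held-out AUC says the model separates highly active from weak guides
in genes it never saw during training; the tier table says every selected
guide has at most its own target site among near-matching genomic
alignments; the oligo string is adapter + BstXI arm + G-prepended
protospacer + BlpI arm + adapter, ready for array synthesis.

Screen analysis runs the other direction — see `compute_gamma()`,
`score_genes()`, `call_hits()` and `evaluate_screen()`, and the methods
vignette (`vignettes/guidescreen-methods.Rmd`) for the statistics.

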