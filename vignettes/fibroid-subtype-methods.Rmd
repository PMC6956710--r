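---
title: "Methods: methylation-based fibroid subtyping and integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-based fibroid subtyping and integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrointegra)
```

This vignette is the package's account of its models and the choices behind
them: what each stage computes, which thresholds matter and why they have
the defaults they do, what the synthetic cohort generator does and does not
emulate, and where the design was genuinely open.

## Data model

The pipeline works on plain base-R containers. A **beta matrix** holds
methylation fractions β ∈ [0, 1] (probes × samples) with `NA` marking
masked, non-detected measurements — masking, never imputation, is how
missingness propagates, mirroring how array preprocessing flags unreliable
probes. Before any logit transform, β is clipped to [ε, 1 − ε] with
ε = 1e-3 so M-values, M = log2(β/(1 − β)), stay finite; clipping moves a
value by at most ε. Coordinates are 0-based half-open internally and BED
convention on disk, which keeps the 100-kb bin arithmetic unambiguous.

## Subtype discovery

**Variable probes.** Per-probe standard deviation across all samples
(masked cells excluded) ranks CpG probes; the top 1% are retained
(`ceiling(fraction * P)`, exactly 200 of the generator's 20,000 CpGs).
Ties fall back to lexicographic probe-id order so the selection is
deterministic. The fraction-versus-absolute-count ambiguity familiar from
published analyses (a "top 1%" rule versus a round "10,000 probes" figure)
is resolved by accepting either a `fraction` or an `n_probes` argument,
with the fraction as default.

**Clustering.** Ward linkage (`ward.D2`) on Euclidean distance over β.
No linkage or metric is canonical for methylation heatmaps; Ward's
compact-cluster behaviour best matches the block structure such heatmaps
display, and both are arguments if an analyst prefers otherwise.

**Consensus clustering.** Each of 1,000 iterations draws
⌊0.8 · n⌋ samples without replacement and clusters them at the requested
k; the consensus value of a sample pair is its co-clustering count over
its co-sampling count. The 0.8 subsampling fraction is the convention of
the resampling-based consensus method this follows; 1,000 iterations makes
a never-co-sampled pair a ~(1 − 0.64)^1000 event, and if it ever occurs
the entry is reported missing and treated as 0.5 (maximal uncertainty) in
the final cut. k is user-supplied: the package reports stability across k
on request but makes no automatic choice, because the cohort design (one
normal group plus three fibroid subtypes, hence k = 4) is a scientific
input, not a statistic.

**Stability scores.** The score of sample *s* against cluster *C* is the
mean consensus between *s* and the members of *C*, excluding *s* itself
when *s* ∈ *C*. The published definition ("average consensus value
between a sample and members of a consensus cluster") is ambiguous about
self-pairs; including the guaranteed consensus(s, s) = 1 would inflate
every member's score by 1/|C|, so self-exclusion is used and tested. A
singleton cluster has no pairs; its score is defined as 1 and flagged
rather than `NaN` so downstream tables stay rectangular.

**Classification rule.** MED12 exon 1/2 mutation dominates; otherwise
HMGA2 fold change > 5 calls `HMGA2hi`, then HMGA1 fold change > 2 calls
`HMGA1hi`, else `unclassified`. The precedence (HMGA2 before HMGA1) is a
design decision: a sample exceeding both thresholds is called by the
stronger criterion. Thresholds are strict inequalities, as stated
("expression > 2-fold and > 5-fold").

## Differential methylation and TFBS enrichment

DMCs are called by a per-probe Welch t-test on M-values — testing on the
variance-stabilised scale while reporting the effect as Δβ, because the
decision rule thresholds the β scale (|Δβ| ≥ 0.2, p < 0.05). This is a
deliberately simple per-probe test standing behind the module surface
where the original analysis used a region-aware limma-based caller; it is
documented as a defined simplification, not a reimplementation, and the
rule's unadjusted p is kept (the Δβ filter carries the multiplicity
burden) with BH q-values reported alongside. Probes with fewer than two
unmasked values in a group are untestable and leave the universe.

"Unmethylated in normal" for fibroid-specific probes is quantified as all
normals ≤ 0.2 — the source rule gives only the tumour-side threshold
(β ≥ 0.3 in at least one sample) — and both numbers are config entries.

TFBS enrichment uses the hypergeometric distribution over the distal
universe (probes beyond ±2 kb of a TSS that carry at least one TF label):
p_enrich = P(X ≥ k), p_deplete = P(X ≤ k). The two tails share the
P(X = k) term, so p_enrich + p_deplete ≥ 1 — a property test. BH runs
separately within the enrichment family and the depletion family across
TFs; whether the original correction family spanned directions is not
stated, so both q columns are reported and the per-direction family is
the default. The 1e-6 FDR cutoff is kept as published.

## Expression and integration

Differential expression filters genes to CPM ≥ 1 in ≥ 3 samples of the
contrast, then applies Welch t on log2(CPM + 0.5) with BH FDR < 0.05.
The pseudo-count 0.5 keeps zero counts finite and bounded; library sizes
are the observed column sums (no between-sample normalisation beyond CPM,
which is out of scope). As with the DMC caller, this is a defined
stand-in with the published filter and FDR rules, not a moderated
negative-binomial model.

Starburst integration summarises a gene's promoter methylation by the
probe with the largest |Δβ| (a mean summary is selectable); the
max-|Δβ| default reflects that one silenced-promoter probe is
biologically sufficient and matches how starburst plots highlight genes.
Categories need joint significance: |Δβ| > 0.25 with p < 0.05 on the
methylation side and FDR < 0.05 with the opposite sign on the expression
side; `hyper_down` and `hypo_up` are mutually exclusive by sign, so the
categories partition genes.

The DEG-overlap test compares up- and downregulated sets separately over
the genes tested in **both** contrasts — the shared-universe definition is
this package's, since the original does not state one — using Pearson
chi-square with 1 df and no continuity correction (expected counts in
intended use are in the tens to hundreds).

## Clonality from X inactivation

One X chromosome is silenced at random early in development; tumours from
one founding cell therefore express the same allele at every heterozygous
chromosome-X locus, and independently arisen tumours disagree wherever
their inactive X differs. The caller keeps loci heterozygous in DNA in
both tumours (depth ≥ 10, alt fraction in [0.2, 0.8]), calls the
expressed allele where RNA depth ≥ 10 and the major allele reaches 0.9,
and computes concordance over loci monoallelic in both tumours. Verdicts:
`shared_origin` at concordance ≥ 0.9, `independent_origins` at ≤ 0.1,
otherwise (or below 5 informative loci) `indeterminate`. The published
analysis describes this logic without numeric cutoffs; all five numbers
are package policy, exposed in the config, and chosen so that binomial
noise at depth ~30 with 2% allelic leakage essentially never crosses the
bands. The methylation-profile correlation between the two tumours is
reported as corroboration only and never overrides the allelic verdict.
Skewed X inactivation in bulk normal tissue is out of model: verdicts
apply to tumour pairs.

`deletion_effect` translates the original and deleted CDS with the
standard code up to the first stop, so an in-frame deletion whose junction
fuses into a stop codon reports the full truncation, not just the deleted
span (flagged `premature_stop`). A 24-nt codon-boundary deletion removes
8 residues; a 45-nt one removes 15.

## A/B compartments

β values of CpG probes are averaged in 100-kb half-open bins (bins with
fewer than 3 probes are masked to stabilise the mean); the bin–bin Pearson
correlation matrix across samples is eigendecomposed and the first
eigenvector, sign-oriented to correlate positively with per-bin probe
density (open, A-type chromatin is probe- and gene-dense), splits bins
into A (positive) and B (negative). The `flip` option reproduces the
plotting convention of multiplying the eigenvector by −1; because labels
follow the final sign, flipping swaps A and B, so recovery against a known
pattern should be read at `flip = FALSE`. Whether compartments should be
computed per sample group jointly or separately is not fixed anywhere;
the function computes whatever sample set it is given, so a per-group
analysis is a per-group call.

## The synthetic cohort generator

`paper_profile()` encodes the study conditions: 10 normal myometria and
24 fibroids (16 MED12mt, 4 HMGA2hi, 4 HMGA1hi); 20,000 CpG, 200 CpH and
59 SNP probes; planted marker log2 fold changes of 11.6 (HMGA2 in
HMGA2hi) and 3.2 (HMGA2 in MED12mt), 4.4 and 3 for HOXA13, and 3 for
HMGA1 in HMGA1hi (the classification rule only requires > 2-fold, and no
published value pins this one); tumour purity uniform on [0.7, 0.9] read
out through marker-promoter methylation; two patients with two fibroids
each, one sharing the inactive X and one not.

Noise models: β ~ Beta(μκ, (1 − μ)κ) with κ = 50 (κ = 200 for the
tri-modal SNP probes) — within-group array dispersion is not published,
so κ is an exposed config choice giving a per-probe SD of ~0.05–0.07,
realistic for array replicates, with closed-form means that make
group-mean recovery testable. Counts are negative binomial with
dispersion 0.1 (standard bulk RNA-seq noise) and per-sample library
factors spanning a deterministic 3-fold range so the CPM filter is
genuinely exercised; 50 near-silent genes (0.02 CPM) exercise the filter
from below. Planted marker effects are defined on the CPM + 0.5 scale so
the estimator's pseudo-count arithmetic is unbiased for the planted
value. Thirty "coupled" genes carry promoter hypermethylation (Δβ 0.4)
with expression log2FC −2 in all fibroids for starburst and DEG-overlap
recovery; 300 distal probes hypermethylated in all fibroids (Δβ 0.35)
form the planted DMC set, half of the planted TF's 300 binding sites
sitting on them so its hypergeometric enrichment is decisive while 19
null TFs draw uniformly from the universe. One chromosome carries four
alternating 500-kb blocks whose bins follow a per-sample latent factor
with opposite signs (A blocks probe-dense with 8 probes/bin, B with 4),
giving the ±1 block correlation structure the compartment eigenvector
needs. RNA allelic counts at heterozygous X loci are binomial with
monoallelic fraction 0.98 and sequencing error 0.01.

What the generator does **not** emulate: probe-level genomic
autocorrelation and CpG-island structure, cell-type mixtures beyond the
two-component purity read-out, copy number, batch effects, or
sequence-level reads. Passing recovery tests therefore demonstrates that
the estimators are correct under the stated statistical structure — not
that they are robust to every artefact of real array and sequencing data.

## Problem sizes and numerical choices

Tests and the acceptance script run at the full profile (20,259 probes ×
34 samples; 2,000 genes): consensus clustering at 1,000 iterations takes
well under a minute, and the 50-seed clonality power study and 10-seed
effect-size recovery each run in tens of seconds. The type-I calibration
of the DMC caller is simulated at 10 vs 10 samples, where the Welch test
on Beta-noise M-values is nominal; at 4 vs 4 it is conservative (~0.03
observed), which is why the calibration check fixes the larger group
size. Degenerate inputs fail loudly rather than silently: constant binned
matrices, zero library sizes, zero-variance correlation inputs,
all-missing genotype columns and cross-patient clonality requests all
raise typed errors.

## Known limitations

The DMC and DEG procedures are intentionally simple per-feature tests
behind stable interfaces — they do not borrow strength across features
and will be less powerful than moderated models at small n. Purity is a
two-component linear mixture read-out, not reference-based deconvolution.
Compartment calls at 100 kb cannot see sub-bin structure, and the
density-based sign convention can flip on chromosomes with atypical probe
density. The clonality caller assumes diploid X and no copy-number
distortion of allelic fractions.
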