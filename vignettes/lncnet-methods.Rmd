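---
title: "lncnet: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncnet: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

This vignette documents the statistical models behind `lncnet`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the methodology was genuinely
open. The package targets bulk RNA-seq studies with a small
tissue × developmental-stage × replicate design (the motivating setting is
two neuroendocrine tissues sampled at three ovarian stages in triplicate)
and covers lncRNA identification, threshold-based differential expression,
lncRNA target assignment, ceRNA network inference and gene-set enrichment.

## lncRNA identification and classification

Candidate novel transcripts pass a structural filter (summed exonic length
≥ 200 bp and ≥ 2 exons) and a coding-potential consensus: three independent
assessors (two ab initio predictors and a protein-database search, supplied
as boolean verdicts; `orf_heuristic()` ships as a built-in stand-in that
calls a sequence coding when its longest forward-frame ORF reaches 100
codons) must all agree a transcript is noncoding. The candidate set is
therefore the intersection of the three noncoding sets — the conservative
choice, trading sensitivity for a low false-lncRNA rate.

Positional categories are assigned against a gene annotation with a fixed
priority order, because a locus can satisfy several geometric rules at
once:

| priority | category | rule (defaults) |
|---|---|---|
| 1 | antisense | ≥ 1 bp exonic overlap, opposite strand |
| 2 | sense_overlapping | exonic overlap, same strand |
| 3 | intronic | span inside a single intron, no exonic overlap |
| 4 | bidirectional | divergent TSS within 1,000 bp, non-overlapping |
| 5 | intergenic | gap to nearest gene > 5,000 bp |
| 6 | other | everything remaining |

Only the category *names* are standard; the geometry is a declared
convention of this package, with both distances configurable
(`bidirectional_window`, `intergenic_min_distance`). The residual *other*
class holds loci that sit near a gene (≤ 5 kb) without satisfying any
specific rule. Coordinates follow the Bioconductor convention (1-based,
inclusive, `GRanges` end to end); GTF input is therefore ingested without
coordinate shifts, and the distance between disjoint features is the gap
length in bp (`GenomicRanges::distance()`). Category percentages are
rounded half-up to one decimal, matching how such tables are conventionally
printed.

## Differential expression

Counts are normalized to FPKM,
$\mathrm{FPKM}_{ij} = c_{ij} \cdot 10^9 / (N_j \ell_i)$ with $N_j$ the
per-sample total and $\ell_i$ the feature length. Fold changes are computed
on group-mean FPKM with a pseudocount of 1 (configurable); the direction
convention is *later stage relative to earlier stage*, so `IV_vs_V` means
stage V relative to stage IV.

The per-feature test is pluggable. Two methods are registered:

* **moderated** (default): a two-group t-test on `log2(FPKM + 1)` whose
  per-feature pooled variance is shrunk toward the mean variance across all
  features with a prior weight of 10 pseudo-degrees of freedom. With three
  replicates per group a per-feature variance estimate has four residual
  degrees of freedom and is too unstable to rank genes: simulations at the
  package's default conditions (baseline mean 100, NB dispersion 0.05,
  planted log₂FC 2) show a plain Welch test leaves the median
  truly-changed feature near p ≈ 0.004 while its BH rejection boundary
  requires ≈ 0.006, so most planted features are missed. Sharing variance
  information across features — the same idea the count-based DE packages
  in this field rely on — restores near-complete sensitivity while keeping
  the null calibration intact (the type-I error of both methods is checked
  against the 0.05 nominal level in the test suite). The log-scale NB
  variance is approximately constant across the abundance range when the
  dispersion term dominates the shot-noise term, which makes the shared
  prior appropriate here.
* **welch**: Welch's t per feature, kept as the reference method and for
  data where homogeneity across features cannot be assumed.

Calls use the published thresholds with *strict* inequalities:
|log₂FC| > 1 and BH q < 0.05 for mRNA and lncRNA, |log₂FC| > 1 and raw
p < 0.05 for miRNA. A feature at log₂FC = 1.0 exactly is *not* called.
Cross-comparison totals are reported under two conventions: the sum of
per-comparison counts (the convention used in headline totals, which
double-counts the intersection) and the deduplicated union, labeled
separately; both obey |A∪B| = |A| + |B| − |A∩B|, which the pipeline report
re-verifies. `ddct_relative_expression()` implements
$2^{-\Delta\Delta C_t}$ for qPCR validation arithmetic.

## Target assignment

* **antisense**: ≥ 1 bp of opposite-strand exonic overlap; evidence is the
  total overlapping length.
* **cis**: non-overlapping spans separated by strictly less than 10 kb
  (evidence = gap). Overlapping pairs belong to the antisense/sense domain
  and are excluded from cis by construction.
* **trans**: Pearson |r| ≥ 0.9 — inclusive, unlike the strict ceRNA
  thresholds, following the printed "≥" — computed across all samples of
  one tissue (stages × replicates pooled). The threshold is read as a
  correlation coefficient; a p-value read would make a ≥ 0.9 criterion
  nonsensical for target selection.

By default only DE lncRNAs and DE mRNAs are paired (the network of
interest links differentially expressed features); `targets_de_only =
FALSE` lifts this. Duplicate (lncRNA, gene) pairs with different mechanisms
are retained as parallel labeled edges.

## ceRNA inference

The sponge model: an mRNA and a lncRNA compete for a shared pool of
miRNAs. Pairs are screened by co-expression — miRNA–target Spearman
SCC < −0.7 (strict; mid-ranks for ties) with targeting required by the
input miRNA–target table, and mRNA–lncRNA Pearson PCC > 0.9 (strict) — and
the overlap of their retained miRNA sets is tested with the upper-tail
hypergeometric distribution, p < 0.05 (strict, no multiple-testing
correction by default, matching the raw-p filtering convention; a BH
option exists).

Two quantities needed by the test are not dictated by the model and are
explicit choices here:

* the universe $M$ is the set of miRNAs present in the miRNA expression
  matrix (alternative: all miRNAs in the target table; configurable via
  the `universe` argument);
* $K$ and $n$ are counted *after* the SCC filter, i.e., they are the
  retained-pair miRNA counts per feature, since the test asks about shared
  sponges among already-correlated partners.

The hypergeometric tail is evaluated by `stats::phyper`; the test suite
verifies it against full enumeration of all $\binom{M}{n}$ draws for
$M \le 12$ and checks monotonicity in $k$. The same engine backs the ORA
p-values.

## Enrichment

ORA is the upper-tail hypergeometric on the overlap of a DE list with each
gene set, within a configurable universe (default: expressed genes). Raw p
at 0.05 is the filtering scale, with BH q reported alongside.

GSEA ranks genes by signal-to-noise,
$(\mu_A - \mu_B)/(\sigma_A + \sigma_B)$, with each $\sigma$ floored at
$\max(0.2\,|\mu|,\ 0.2)$ — the Broad convention. The ranking is computed on
**natural-scale** expression (FPKM), not log: the floor is calibrated for
natural-scale values, and on log₂ data (means around 12) the floor (~2.4)
dwarfs the actual residual spread (~0.35), collapsing signal-to-noise into
a bare mean difference. That degradation is not cosmetic: it keeps
phenotype relabelings that differ from the true labeling by one sample
almost as extreme as the observed statistic and inflates the attainable
permutation p.

The enrichment score is the weighted Kolmogorov–Smirnov running statistic
(hit increments $\propto |s|^p$ with $p = 1$, miss decrements
$1/(N - |S|)$; ES is the signed maximum deviation), cross-checked in the
test suite against an independent implementation (`fgsea::calcGseaStat`).
Significance uses phenotype permutation, not gene-set permutation, because
the replicate structure lives in the samples. All relabelings are
enumerated exhaustively (minus the observed one) when at most 1,000 exist,
otherwise 1,000 random relabelings are drawn. With 3-versus-3 groups only
19 non-identity relabelings exist and the add-one permutation p-value
$(1 + b)/(1 + m)$ can never reach 0.05, so enrichment contrasts pool the
two tissues into 6-versus-6 groups ($\binom{12}{6} = 924$ relabelings,
within the exhaustive limit). NES divides ES by the mean |null ES| of
matching sign; FDR q follows the standard positive/negative tail-area
normalization. Significance requires |NES| > 1, nominal p < 0.05 and
q < 0.25, all strict.

## The synthetic-data generator

`simulation_config()` defines the study conditions; the defaults *are* the
conditions every recovery property is measured under:

| parameter | default | meaning |
|---|---|---|
| `n_tissues × n_stages × n_reps` | 2 × 3 × 3 | design (18 samples) |
| `n_genes / n_lncrna / n_mirna` | 80 / 40 / 15 | catalog sizes |
| `baseline_mean` | 100 | expected NB count |
| `nb_dispersion` | 0.05 | NB dispersion (var = μ + μ²φ) |
| `planted_log2fc` | 2 | DE effect size |
| `frac_de` | 0.25 | fraction of features planted DE |
| `category_mix` | 0.40/0.15/0.10/0.20/0.15 | intergenic/bidirectional/intronic/antisense/sense-overlapping |
| `n_cerna_triplets` | 5 | planted (mRNA, lncRNA) sponge pairs |
| `mirnas_per_triplet` | 2 | shared miRNAs per pair |
| `corr_strength` | 0.9 | planted co-expression strength ρ |
| `decoy_rate` | 0.05 | non-planted miRNA-target rate |

The design mirrors a triplicate two-tissue, three-stage study; library
sizes are modulated by per-sample factors uniform in ±20% to make FPKM
normalization non-trivial; catalog sizes, `frac_de` and the decoy rate are
chosen to give each downstream stage a realistic mix of signal and nulls at
desk scale. Dispersion and library sizes are not reported by typical study
write-ups, so these are stand-ins exposed in the configuration.

Geometry is deterministic: genes sit on a 200 kb grid with three 1 kb
exons, and each lncRNA is placed relative to a host gene so that it
satisfies exactly one category rule by construction (divergent TSS at
800 bp for bidirectional; a 7 kb gap for cis-planted intergenic loci —
intergenic by the > 5 kb rule yet cis by the < 10 kb rule; mid-grid
placement, > 80 kb from any gene, for non-cis intergenic loci).
Bidirectional loci are also cis pairs (gap < 10 kb), and the planted truth
records them as such.

DE effects are *step* profiles: a feature planted for a comparison keeps
the shifted mean from the later stage onward, so it is differential in its
designated comparison only. Planted ceRNA triplets follow a shared latent
profile $z_s \sim N(0,1)$: mRNA and lncRNA means are
$\propto 2^{\,a(\rho z_s + \sqrt{1-\rho^2}\,\varepsilon)}$ and the miRNA
uses the negated exponent, with amplitude $a = 1$ log₂ unit per latent SD
(larger amplitudes let a handful of heavy-tailed planted rows dominate the
per-sample totals and contaminate every feature's FPKM). These rows are
emitted deterministically — rounded to three decimals, with no NB
resampling and no library-size modulation — so that at $\rho = 1$ the
Spearman correlations are exactly −1 and the Pearson correlation exactly
+1 *on the count scale*. This is also why the noiseless-limit recovery
property is measured on counts: FPKM re-division by per-sample totals
(which carry the library factors and the NB noise of all other features)
adds rank noise that the planted rows, by design, do not contain. Each
planted pair shares two miRNAs: with a single shared sponge the
hypergeometric tail is $1/M$ (≈ 0.067 at the default universe of 15),
which can never pass p < 0.05, while two shared sponges give
$1/\binom{M}{2} ≈ 0.0095$; multi-miRNA sponging is also the biologically
typical case.

What the generator does **not** emulate: sequence content (no FASTQ, no
alignment), isoform structure beyond one transcript per gene, GC or length
biases, batch effects, compositional (TMM-style) normalization artifacts
beyond what random DE directions induce, and correlated null features.
Passing recovery tests therefore demonstrates correctness of the
implemented inference chain under its own model assumptions, not
performance on real libraries.

## Numerical conventions and degenerate inputs

* Strictness mirrors each printed inequality exactly: SCC < −0.7,
  PCC > 0.9, sponge p < 0.05, |log₂FC| > 1, q < 0.05, |NES| > 1 are
  strict; trans |r| ≥ 0.9 is inclusive.
* Ties: Spearman uses mid-ranks; signal-to-noise ties keep stable feature
  order; a degenerate test row (constant in both groups) gets p = 1 when
  the means agree, 0 when they differ.
* Zero-variance profiles are skipped with a warning in correlation
  screens; a zero library or a missing feature length aborts FPKM with the
  offending sample or feature named.
* Fold change of two zero means with pseudocount 0 is a flagged `NA`.
* All randomness flows from explicit seeds: the generator derives its
  streams from `config$seed`, and a fixed configuration reproduces
  byte-identical fixtures and pipeline reports.

## Problem sizes

The shipped tests and the acceptance script run the full study design
(18 samples) with the default catalog (80 genes, 40 lncRNAs, 15 miRNAs),
20 simulation replicates for the DE sensitivity/FDR estimate, and
exhaustive 924-relabeling GSEA — sizes chosen so the whole suite exercises
every stage end to end at desk scale while remaining statistically
meaningful (1,200 planted DE feature-calls pooled across replicates for
the sensitivity estimate).

## Known limitations

* The moderated test assumes log-scale variances are exchangeable across
  features; strongly heteroscedastic data should use `method = "welch"` or
  a registered count-based alternative.
* FPKM's total-count normalization carries compositional bias when DE is
  strongly unbalanced; the generator plants balanced directions, and no
  TMM-style correction is provided.
* The ceRNA screen is marginal-correlation-based; conditional or
  sensitivity-correlation formulations are out of scope.
* The classifier's *other* category and all category distances are
  conventions; results at non-default windows are not comparable across
  runs with different settings.
* ORA treats gene sets as flat; no ontology-graph propagation is
  performed.
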