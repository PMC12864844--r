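---
title: "Models and methods behind glorimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glorimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model of each analysis stage, the
design choices taken where the methodology was genuinely open, the
assumptions of the synthetic-data generators, and the numerical details a
user would need to interpret or reproduce results.

## The scoring model

GLORI chemistry converts unmethylated adenosines to inosines, which reverse
transcribe and sequence as G; m⁶A is protected. At a reference adenosine
covered by `n_A + n_G` informative reads, the score `n_A / (n_A + n_G)`
estimates methylation stoichiometry `s` with expectation

$$E[\text{score}] = s + (1 - s)(1 - e),$$

where `e` is the conversion efficiency. At `e = 0.99` the additive bias for
an unmethylated site is 0.01; the score is otherwise a binomial proportion,
so its standard error is `sqrt(score (1 - score) / (n_A + n_G))`. Positions
with fewer than 10 informative reads are discarded — below that the score is
too unstable to rank against the 0.1 call threshold.

**Background and test.** The per-sample background is the *pooled*
`sum(A) / sum(A + G)` over all reference-A positions, not the mean of
per-position ratios: pooling weights positions by coverage and is stable
when many positions have low counts. Site calling tests each position's
`(n_A, n_G)` against the pooled `(A, G)` totals with a one-sided Fisher
exact test (alternative: A-enriched). One-sided is a deliberate choice — the
chemistry only ever protects adenosines, so depletion below background has
no biological reading. The p-value is computed as a hypergeometric tail
(`phyper`), which is algebraically identical to `fisher.test(...,
alternative = "greater")` on 2×2 tables and vectorises over thousands of
positions; the equivalence is asserted in the test suite.

**Filter chain.** A position is retained in a sample when score > 0.1,
`n_A + n_G ≥ 10`, and p < 0.05, and a site is emitted when it passes in at
least `replicate_support` samples (default 1, the "any sample" rule).
No multiple-testing correction is applied by default: the raw-p design
relies on the score and coverage co-filters to control false calls, and the
methylation-free null simulation in the acceptance suite confirms that the
full chain yields zero calls at ~100× coverage and efficiency 0.99. A
Benjamini–Hochberg switch (`bh = TRUE`) is available for users who want
FDR control at the Fisher stage. Replicates are aggregated by the median,
which is robust to a single discordant library with three replicates.

## Transcript topology

Metagene analysis rescales positions by `1000 / length` and bins position
`p` of a length-`L` transcript into `floor(10 p / L) + 1`, clamped to bin
10 — exhaustive and exclusive, so bin counts always sum to the number of
retained sites. EIJ distance is the minimum absolute distance to any
junction, `NA` for single-exon transcripts. The per-gene spacing statistic
takes the highest-scoring site (ties broken 5′-most, an arbitrary but
deterministic rule) and reports its distance to the nearest other site.
Adjacent-score correlation collects all within-gene pairs separated by at
most 40 nt — the same window as the linkage analysis, since no window is
inherent to the question — and reports a Pearson correlation; fewer than
three pairs yields `NA` with a warning rather than a meaningless estimate.
The 3′-bin contrast is a Student two-tailed t test of the 10th bin's scores
against all other bins pooled.

## Single-molecule linkage

Whether methylation at one site changes the probability of methylation at a
nearby site *on the same molecule* is read directly from molecules spanning
both sites. Pairs are eligible when ≤ 40 nt apart, both condition-median
scores lie in [0.4, 0.7] (scores near 0 or 1 leave almost no joint
variance to test), and one member is the gene's *dominant* site. The
dominant-site criterion is under-determined in general use; this package
implements it as the gene's highest-median-score site and flags that as an
interpretation, not a fact about the assay.

Spanning reads are tallied into the four {A,G}×{A,G} states. Reads showing
C or U at a reference adenosine are counted separately (`n_other`) and
excluded from the 2×2 table: under deamination chemistry such bases are
uninterpretable, and the simulator (which has no sequencing-error model)
never produces them. The test is a chi-square test of independence without
continuity correction — the Yates correction is conservative exactly in the
small-table regime that the `min_spanning = 10` guard already excludes. A
zero margin (a site fully methylated or fully converted among spanning
reads) leaves the test undefined and returns `NA`. Under the simulator's
independent-methylation model the p-values are asymptotically uniform; the
acceptance suite checks the empirical type-I error at depth 200 against the
99% binomial interval around 0.05, and the comonotone-coupling positive
control (all sites on a molecule share one latent uniform) is detected in
every pair at that depth.

## Sequence-context model

The ±6 nt context of each site is one-hot encoded (13 positions × 4 bases =
52 binary features; N pads at transcript ends encode as all-zero blocks).
Sites with median control coverage below 40 reads are dropped — below that
the regression target itself is too noisy to learn from. The regression is
gradient-boosted trees (xgboost, squared-error objective) with 300 rounds,
depth 3 and learning rate 0.1; these hyperparameters are deliberately
modest — one-hot inputs make deep trees redundant — and are recorded in the
model report for reproducibility. The fit is single-threaded with a fixed
seed, so a given seed reproduces the model exactly. The train/test split is
80/20 (unspecified in the original methodology; both the fraction and seed
are arguments). R² is reported on the held-out split and on the full data;
the held-out value is the honest one and is what the acceptance criteria
use. Feature importances are xgboost gain values renormalised over all 52
features so absent features contribute exactly 0 and the vector sums to 1.

Predictions are ranked on the full filtered dataset; the top 1% by
predicted score are split by *observed* score into "coherent" (> 0.8) and
"low score" (< 0.1) groups and compared on EIJ distance. With
junction-proximal suppression planted in the generator, the low-score group
sits closer to junctions — the direction, not the magnitude, is the tested
claim, because the magnitudes depend on transcript geometry.

## Conservation scanning

Each 13-nt site context is slid across the full homolog sequence and scored
by matches; the best window wins. Matching is indel-free by construction —
an indel near the site shifts every downstream base and the match simply
fails retention, which is documented behaviour rather than a limitation to
repair. A match is retained only when unambiguous (a unique best window)
and within Hamming distance 3. Sequences are U/T-normalised before
scanning so DNA- and RNA-alphabet inputs mix freely.

The per-position conservation test compares position *i*'s match proportion
against the pooled proportion of the other 12 positions with a two-sample
proportion test, Bonferroni-adjusted by exactly `min(1, 13 p)`. When both
proportions are degenerate (all matches perfect), the test statistic is
undefined and the p-value is reported as 1 — no evidence of positional
difference. The substitution-rate contrast splits positions by reference
base class (C/G vs A/U) and tests the class difference per position; in a
low-GC genome the C/G class substitutes faster, which by itself depresses
conservation at C-rich positions such as +1 — the analysis exists to
separate that mutational explanation from selection.

## Resampling statistics

**Expression-matched bootstrap.** m⁶A detectability rises with expression,
so a naive comparison of DE rates between m⁶A and non-m⁶A genes is
confounded. After filtering to `baseMean ≥ 200`, setting missing adjusted
p-values to 1 and defining DE as `padj < 0.05`, the `log10(baseMean)` range
is cut into ten quantile bins, and each iteration draws equal numbers of
genes per bin from both groups with replacement, totalling 0.8 × the
smaller group per side. Per-bin quotas are allocated proportionally to
pooled bin occupancy (largest-remainder rounding keeps the total exact);
the alternative flat 1/10 allocation is available behind `flat_bins =
TRUE` — the original wording is ambiguous between the two, and
occupancy-proportional avoids over-sampling sparse tails. Bins empty in one
group are skipped with their quota redistributed and a warning. The
empirical two-sided p doubles the smaller tail of the bootstrap
distribution around zero (clipped to [0, 1]); the raw distribution is kept
on the object so users can apply other rules. `matching_quality` — the mean
absolute difference in mean `log10(baseMean)` between the sampled groups —
verifies the matching actually worked; it is always far below the unmatched
expression gap on confounded tables. Note that the bootstrap distribution
estimates the *matched* difference while `observed_diff` is the unmatched
group difference; on confounded data the two differ by the confound, which
is the method's point.

**Overlap permutation.** The Jaccard test draws both sets uniformly without
replacement from the universe each iteration and counts permuted overlaps
at least as large as observed, with the add-one rule `(1 + k)/(n + 1)` so
p is never exactly zero. For disjoint draws from a common universe the
permuted overlap is exactly hypergeometric, and the acceptance suite checks
the permutation p against the closed-form tail. The hypergeometric lineage
test is the inclusive upper tail `P(X ≥ k)` via `phyper`.

## The synthetic-data generators

The generators encode the study conditions the statistics assume, as
defaults chosen once:

| parameter | default | rationale |
|---|---|---|
| `gc_content` | 0.32 | low-GC transcriptome typical of planarian genomes (30–35%) |
| `conversion_efficiency` | 0.99 | near-complete deamination of unmethylated A |
| `stoich_high` | Beta(20, 2) | +1 C sites: mean ≈ 0.91, matching the high, switch-like stoichiometry of C-followed sites |
| `stoich_mid` | Beta(6, 6) | +1 U/+4 U sites: moderate stoichiometry centred at 0.5 |
| `eij_exclusion_nt` | 100 | junction-proximal suppression window |
| `three_prime_bias` | 2 | placement weight `(pos/len)^2`; no quantitative 3′ law is established, so the bias is an explicit tunable exponent rather than an asserted distribution |
| `site_prob` | 0.15 | ceiling placement probability per eligible adenosine, yielding a few sites per gene at default lengths |

Methylation events are independent across sites and molecules by
construction, which is what makes the linkage type-I calibration meaningful;
the `coupling` flag exists solely to build positive controls (all sites on
a molecule share one latent uniform, the strongest possible coupling at
given marginals). Homolog simulation substitutes per position with
class-specific rates and no indels, so homologs are Hamming-comparable by
design; `site_offset_rates` plants positional substitution signals (for
example a 3× elevated +1 rate) for calibrating the conservation test.

What the generators deliberately do *not* model: sequencing errors, indels,
splice isoforms, PCR duplicates, quality scores, strand ambiguity (all
simulated reads are sense-strand; the SAM reader reverse-complements
minus-strand records on ingestion), and genome-space coordinates (the
pipeline lives in transcript space; alignment is upstream of its scope).
Passing tests therefore demonstrate statistical correctness of the methods
under clean-read assumptions, not robustness to alignment artefacts or
error-prone base calls.

## Numerical and calibration details

- Coordinates are 0-based, half-open, transcript-space everywhere; FASTA is
  written with T and converted back to U on read; 1-based site tables are
  shifted on ingestion with `one_based = TRUE`.
- Degenerate simulation ranges (`length_range` with equal endpoints) are
  handled explicitly to avoid R's scalar `sample()` expansion.
- Calibration problem sizes, chosen to give stable statistics: score
  recovery uses 600 sites at ~300× flat coverage (transcript length equals
  read length so coverage is uniform); the null chain uses ~12,000
  adenosine positions at ~100×; linkage uses 500 independent and 200
  coupled pairs at depth 200; the context model uses ~1,200 sites for the
  planted-rule fit and ~7,000 for the noise fit (at smaller sizes boosted
  trees overfit noise enough to push held-out R² visibly below 0); the
  bootstrap calibration repeats the whole procedure 200 times at 500
  iterations each; conservation uses ~240 retained matches.
- For the planted-rule model calibration the targets are the deterministic
  rule-class means (0.909 / 0.5) plus Gaussian noise (sd 0.05) rather than
  Beta draws: Beta sampling noise is not a function of sequence and no
  model can explain it, which would cap attainable R² at ~0.76 regardless
  of fit quality. The Beta defaults remain the generating conditions for
  every other analysis.

## Interfaces

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; `run_pipeline()` executes the synthetic
end-to-end flow and writes each stage's tables, a resolved-config snapshot
and a log to an output directory, and each stage is independently re-runnable
from prior outputs through its function. The package deliberately ships no
shell entry point: its users work in R, and the exported functions plus
`scripts/acceptance.R` are the scripted surface.

## Known limitations

- The "dominant site" criterion in pair selection is an interpretation
  (gene's top median-score site); other readings would select different
  pair sets.
- The Fisher-stage background includes methylated positions, so on heavily
  methylated transcriptomes the background is conservatively high; the
  score threshold dominates calling in practice.
- `n_other` preserves non-A/G evidence at linkage sites but no error model
  interprets it.
- Conservation retention confounds true divergence with indels near the
  site; both simply fail the Hamming window.
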