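---
title: "Partitioning androgen receptor output into coregulator-dependent fractions"
author: "coregdep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning androgen receptor output into coregulator-dependent fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregdep)
```

## The scientific problem

The androgen receptor (AR) is a ligand-activated transcription factor and
the central driver of prostate cancer. When activated, AR binds androgen
response elements (AREs) genome-wide and regulates target genes with the
help of coregulator proteins recruited to DNA-bound AR. A central question
for therapy is whether AR's transcriptional output can be decomposed into
fractions that depend on *different* coregulators — so that blocking one
coregulator silences only the clinically harmful part of AR's program.

`coregdep` implements the computational chain for that question:

1. **Target nomination.** Direct AR target genes are nominated by
   integrating AR binding sites (ARBSs, from ChIP experiments) with
   transcription start sites (TSSs): a peak whose midpoint lies within
   300 kb of any TSS of a gene links the peak to the gene, and nominated
   genes must additionally appear in published androgen-regulated gene
   lists.
2. **Knockdown contrasts.** For each coregulator, expression is profiled
   under a 2 x 2 design — (control siRNA vs coregulator siRNA) x
   (androgen vs vehicle) — with replicates, and three per-gene contrasts
   are computed: the androgen response under control siRNA (`c1`), under
   knockdown (`c2`), and their interaction (`c3 = c2 - c1`).
3. **Four-way classification.** Genes whose interaction passes a dual
   FDR + fold-change rule are classified by what knockdown did to their
   androgen response: magnitude increased (`+`) or decreased (`-`), and
   direction of regulation preserved (`co`) or flipped (`op`).
4. **Set statistics.** Coregulator-dependent gene sets are compared by
   upper-tail hypergeometric overlap tests, directionality-consistency
   percentages, Pearson correlation of interaction effects (pairs with
   r >= 0.25 may be merged), and average-linkage clustering on
   1 - Pearson distance.
5. **Motif selectivity.** ARBS sequences, extended by 1 kb on each side,
   are scanned with position weight matrices (PWMs); motifs
   over-represented in at most 2 signatures are flagged as *selective* —
   candidate partners of a coregulator-specific transcriptional code.

## Statistical model

### Moderated contrasts

For a contrast between groups A and B (sizes $n_A$, $n_B$) the per-gene
effect is $\hat\beta_g = \bar y_{gA} - \bar y_{gB}$ on log2 intensities,
with residual variance $s_g^2$ pooled within groups on
$d_g = n_A + n_B - 2$ degrees of freedom. Under the scaled-F
empirical-Bayes model the gene variances share a prior
$s_g^2 \sim s_0^2 \, F(d_g, d_0)$; the posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}$$

yields a moderated t with $d_0 + d_g$ degrees of freedom. The
hyperparameters are estimated by method of moments on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$:
$\psi'(d_0/2) = \mathrm{Var}(e) - \psi'(d_g/2)$, solved for $d_0$ by
bisection on the (monotone) trigamma function, and
$\log s_0^2 = \bar e + \psi(d_0/2) - \log(d_0/2)$.

Two numerical choices deserve mention:

* **The degenerate branch.** When the observed spread of the
  log-variances is at or below its sampling noise
  ($\mathrm{Var}(e) \le \psi'(d_g/2)$), the moment equation has no
  positive solution: the data are consistent with a single shared
  variance. We then set $d_0 = \infty$ and take the prior variance to be
  the geometric mean of the observed $s_g^2$, which makes shrinkage a
  fixed point — genes with identical variances keep exactly that
  variance. The bias-corrected moment formula is applied only in the
  non-degenerate branch.
* **Infinite prior df.** R's t distribution accepts `df = Inf` directly,
  so the infinite-shrinkage limit is represented exactly rather than by
  a large finite cap.

The interaction contrast `c3` is estimated as the difference of the two
cell-mean differences, with its residual variance pooled over all four
design cells ($d = \sum_i (n_i - 1)$ df) and moderated the same way. We
read the design's third comparison as an interaction contrast within one
model, not as a comparison of two DE lists: the interaction has a proper
sampling distribution, gives calibrated p-values, and reduces exactly to
`c2 - c1` in the estimate. Each of the three comparisons is
Benjamini-Hochberg adjusted across genes *within* the comparison, matching
per-comparison DE lists.

### Calls and classification

A gene is *differentially expressed* in a contrast when `fdr < 0.05` and
`|log2fc| >= 1` (2-fold). A (gene, coregulator) pair is *affected* when
the interaction passes the same dual rule **and** the gene is
androgen-regulated in at least one arm (`max(|c1|, |c2|) >= 1`); the last
gate prevents labelling never-regulated genes when the function is applied
to an unrestricted gene universe rather than a pre-filtered regulated
panel. Tie-breaks are deterministic: an exact magnitude tie
`|c2| = |c1|` (measure zero under noise) takes the `+` suffix, and a zero
sign counts as direction-preserving, so `op` requires a strict sign flip.

### Overlap statistics

Overlap significance is the upper-tail (enrichment) hypergeometric
probability $P(X \ge k)$ with the *nominated target panel* as the default
universe — not the genome. The universe choice materially changes the
p-values and is an explicit argument everywhere. Directionality
consistency between two signatures is reported as four conditional
percentages (e.g. of genes with increased androgen response after losing
coregulator A that are also members of set B, the percentage with
increased response in B), conditioning on membership of the other set so
the quantity is a property of the shared genes.

### Motif scanning

PWMs are additively smoothed with pseudocount $10^{-3}$ and scored as
$\sum_j \log_2(p_{j,b}/q_b)$ over both strands; the default hit threshold
is 80% of the motif's maximum achievable score. These defaults are
package choices (the scanning tools used historically for such analyses
do not publish their thresholds) and are configurable. Sequence-level
enrichment uses the upper-tail binomial against the background hit rate
(an exact hypergeometric is available by flag), BH-adjusted across motifs
within a signature. Backgrounds can be user-supplied or generated by an
Altschul-Erickson dinucleotide-preserving shuffle of the foreground.

## The synthetic-data generator

No public raw data accompanies the design the package implements, so the
generator is the package's test bed. It emulates:

* a miniature genome (default three 50 Mb chromosomes) with one TSS per
  gene placed uniformly (a configurable fraction of genes get a second
  TSS), a small exon structure, one binding-site peak within the 300 kb
  window for 80% of genes, and decoy peaks placed only where genome
  space lies beyond every TSS window;
* a knockdown x treatment intensity matrix with one sample per
  (siRNA, treatment, replicate) cell. Log2 intensities are
  `baseline + effect + N(0, noise_sd)` and the matrix is `2^` of that, so
  the additive model is exact after the log2 transform;
* planted ground truth: every gene carries a +-2.0 log2 androgen response
  under control siRNA; each (gene, coregulator) pair draws a class from
  (co+ 15%, co- 15%, op+ 5%, op- 5%, unaffected 60%) and moves its
  knockdown response by +-1.5 log2 units accordingly (co preserves the
  sign, op flips it).

Defaults follow the three-replicate design and the 2-fold / 1.5-fold
planted effects of the study design; the noise SD (0.25 log2 units) and
per-gene baseline spread (SD 1.0 around mean 8.0) are stand-ins chosen as
realistic for log-scale array intensities, since no noise model is
published for the original arrays. The class mix encodes two qualitative
facts of the domain: coregulators affect minorities-to-halves of the
panel, and direction-preserving dependence (`co`) is far more common than
direction-flipping (`op`).

Determinism: all stages derive their RNG streams from one master seed via
`(seed * 7919 + stage) mod (2^31 - 1)`, so any stage can be regenerated
independently and two runs with the same configuration are byte-identical.

What the generator does **not** emulate: probe-level structure (one row
per gene), array spatial artifacts, batch effects, scanner-scale column
distortions, correlated noise between genes, and any real genome sequence
(peak sequences are i.i.d. uniform with motifs embedded by sampling from
the PWM). Passing recovery tests therefore demonstrates correctness of
the statistical machinery under the stated model, not robustness to real
microarray pathology.

## Why the pipeline default skips quantile normalization

`quantile_normalize()` implements the standard rank-mean map (ties share
the mean of the reference values at their occupied ranks) and is applied
before log2 transformation for raw array data. The *pipeline default* for
simulated data, however, is `quantile_normalize = FALSE`: quantile
normalization assumes most genes are unchanged between samples, while the
simulated panel deliberately makes every gene androgen-responsive —
normalizing such a matrix forces all columns onto one distribution and
visibly compresses the planted effects. Real panels assembled the same
way (all members pre-selected to be regulated) raise the same caveat,
which is why the toggle is surfaced in the configuration rather than
buried.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `window` | 300000 | bp | peak midpoint-to-TSS assignment radius (inclusive) |
| `pad` | 1000 | bp | peak extension before motif scanning |
| promoter window | [-3000, +500] | bp around TSS | pie-chart category; strand-oriented, configurable |
| `fdr_max` | 0.05 | — | BH-FDR gate for DE and affected calls |
| `min_abs_log2fc` | 1.0 | log2 | 2-fold rule for DE |
| `min_abs_delta_log2` | 1.0 | log2 | 2-fold rule on the interaction |
| `min_regulated_abs_log2fc` | 1.0 | log2 | androgen-regulation gate on `max(abs(c1), abs(c2))` |
| `r_min` | 0.25 | — | Pearson threshold for combining signature pairs |
| `max_signatures` | 2 | sets | selectivity rule for motifs |
| `score_min` | 80% of max | log2-odds | PWM hit threshold |
| `pseudocount` | 1e-3 | probability | PWM smoothing before log-odds |

The promoter window and the midpoint convention for peak-to-TSS distance
are genuinely open choices (gene tables do not define "enhancer", and the
assignment rule could equally use the nearest peak edge); both are
documented arguments, the midpoint was chosen for symmetry, and distal
"enhancer" peaks fall into intergenic/intronic categories here.

## Degenerate inputs and tie-breaking, collected

* Zero-noise data give zero residual variance: a non-zero effect is
  reported with `t = +-Inf`, `p = 0`; a zero effect with `t = 0`,
  `p = 1`. This makes the zero-noise limit exactly recoverable.
* Empty peak set A in `overlap_fraction()` returns 0 with a warning.
* Zero-variance columns in `effect_correlation()` get r = 0 with a
  warning, keeping the `r >= 0.25` combination rule total.
* Constant gene profiles in `cluster_genes()` are assigned distance 1 to
  every other gene and flagged.
* Clustering ties are broken by input index via the deterministic
  agglomeration in `stats::hclust`.
* Peaks on chromosomes missing from the annotation are skipped with a
  warning, not an error.

## Problem sizes used in the packaged checks

The test-suite and the acceptance script run the generator at 2,000 genes
x 17 coregulators x 3 replicates (the design-scale panel), with smaller
instances (60-500 genes, 1-3 coregulators) for unit and property tests
and exhaustive enumeration up to universes of 15 genes for the
hypergeometric oracle. These sizes were chosen to make every check
reproducible on a laptop-class machine while keeping Monte-Carlo
tolerances tight (binomial error at n = 2,000 is well under the asserted
margins).

## Known limitations

* No chromatin-looping assignment: regulation across distances beyond the
  window is invisible by construction.
* Enhancer categories cannot be reproduced from a gene table alone.
* The motif stage does not attempt de novo discovery, and absolute motif
  counts depend strongly on the motif library and thresholds supplied.
* The linear model uses fixed effects only; an array-level random effect
  is out of scope.
* GSEA and commercial pathway analyses are out of scope.

## A worked micro-example

```{r example}
cfg <- sim_config(n_genes = 200, n_coregulators = 2, seed = 11)
sim <- simulate_expression(cfg)
study <- normalize_study(sim$study, quantile = FALSE)
calls <- dependence_calls(study)
summarize_calls(calls)

sets <- calls_to_signed_sets(calls)
pairwise_overlap_matrix(sets, unique(calls$gene))$p
directionality_consistency(sets[[1]], sets[[2]])$n_overlap
```
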