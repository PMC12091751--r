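---
title: "Classifying stress-ready ortholog expression: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying stress-ready ortholog expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressready)
```

This vignette is the package's own account of the science it implements: the
statistical model behind each stage, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the choices we made where the design was genuinely open.

## The comparison the package makes possible

Two species — a stress-sensitive cultivar ("species A") and a
drought-adapted wild relative ("species B") — are profiled by RNA-seq under
control and drought conditions. The question is not only *which genes
respond* in each species, but whether the wild species is **constitutively
pre-adapted**: whether, for some orthologs, its control-state expression
already sits at the level the cultivar only reaches under stress (or vice
versa). Such genes are called *stress-ready*.

Answering this requires expression values that are comparable across
species. Orthologs differ in transcript length, and length biases estimated
counts; we therefore work with the discrete quantification

$$ Q = \mathrm{round}(E / L), $$

where $E$ is the per-sample expression estimate (e.g., estimated counts
from a pseudo-aligner) and $L$ the species' own transcript length in
kilobases. Each species uses its own length for the same ortholog pair —
that is the entire point: the ratio of lengths is exactly the bias the
normalization removes. Rounding is half-to-even by default; the convention
is configurable (`rounding = "half_up"`) and immaterial at typical counts.
A `normalization = "none"` switch reproduces the non-normalized variant for
sensitivity analysis.

## Orthology

Orthology is operationalized as the **best bidirectional hit**: $a$ and $b$
are paired iff $b$ is $a$'s best alignment hit against the other proteome
and $a$ is $b$'s best hit back. "Best" is not fully determined by that
phrase, so we fix a deterministic chain: maximal bit score, ties broken by
minimal e-value, then by lexicographically smallest subject id. The
tie-break ordering is a package choice made for reproducibility; any
reasonable chain pairs the same genes except on exact score ties. One-way
best hits against a reference proteome transfer gene symbols, and the
paired partner inherits the same symbol. One-to-many and many-to-many
relationships are deliberately out of scope: downstream expression models
need a one-to-one pairing to be interpretable.

## Differential expression: a small negative-binomial contrast

Counts are modelled as negative binomial with variance $\mu + \alpha\mu^2$.
For a two-group contrast the package computes:

* **Size factors** by median-of-ratios over genes expressed in every
  sample, normalized to geometric mean 1. Inter-species contrasts use
  factors computed jointly across all samples of both species — legitimate
  only because of the length normalization above.
* **Dispersion** per gene by method of moments on normalized counts, using
  the within-group pooled variance, floored at $10^{-8}$.
* **Effect** $\widehat{\mathrm{lfc}} = \log_2\frac{m_2 + 0.5}{m_1 + 0.5}$
  with a delta-method standard error under the NB variance function.
* **A Wald statistic referred to a t distribution** with $n_1 + n_2 - 2$
  degrees of freedom, then Benjamini–Hochberg adjustment at 0.05.

The t reference is a deliberate design decision. With five replicates per
group, the plug-in dispersion makes a normal-reference Wald test visibly
anticonservative (in our simulations, a false-positive rate of about 8.7%
at nominal 5%), which would contaminate every "non-significant" branch of
the classifier below; with the t reference the measured rate is 5.0% and
power at a planted four-fold change, baseline 100, $\alpha = 0.05$, remains
above 95%. This estimator is intentionally simple — no dispersion
shrinkage, no fold-change moderation, no outlier handling — because the
classifier consumes only the significance flag and the sign of the fold
change, and the tests assert exactly that contract (null calibration and
planted-signal recovery) rather than agreement with any particular larger
framework.

Six contrasts are computed per run, with `log2fc = log2(group2/group1)`:

| label | group1 | group2 | reading of positive lfc |
|---|---|---|---|
| A | A control | A drought | species A induced by drought |
| B | B control | B drought | species B induced by drought |
| C | A control | B control | higher baseline in B |
| D | A drought | B drought | higher drought level in B |
| E | A control | B drought | B under drought above A's baseline |
| F | B control | A drought | A under drought above B's baseline |

D is reported for completeness but unused by the classifier.

## The decision tree

Each ortholog receives exactly one of fifteen cases by first-match rules on
`(sig, lfc)` of contrasts {A, B, C, E, F}:

1. **Both species respond** (`sigA & sigB`): same sign → *shared* (case 1
   up, 2 down); opposite signs → *opposite* (case 1: A up/B down, case 2:
   the reverse).
2. **Only B responds**: if the cross contrast E is *not* significant (B's
   drought level indistinguishable from A's control) *and* the baselines
   differ in the consistent direction (`sigC` with `lfcC < 0` for a rising
   B, `lfcC > 0` for a falling B) → *stress-ready* case 1 or 2; otherwise
   *unique* case 3 (up) or 4 (down).
3. **Only A responds**: symmetric via F and C → *stress-ready* case 3 or 4,
   else *unique* case 1 or 2.
4. **Neither responds**: *no response*, split by the baseline contrast
   (case 1: higher in B; case 2: lower in B; case 3: indistinguishable).

Two subtleties deserve emphasis:

* **"Matching levels" is read as failure to reject equality** of the cross
  contrast at the same padj threshold. This is the binary-rule reading the
  model definitions imply, and it is a known statistical weakness (absence
  of evidence is not evidence of absence): low-powered genes drift toward
  "matching". We keep it because the classification is defined by the
  rules, not by an equivalence test, and we record every fired predicate in
  `rule_trace` so any assignment can be audited. A TOST-style equivalence
  mode can be built by recomputing `sigE`/`sigF` from an equivalence test
  before calling `classify_orthologs()`.
* **The baseline requirement** (`require_baseline_difference`, default
  `TRUE`) demands `sigC` with a consistent sign for a stress-ready call; a
  gene whose species-B level rises to "match" a baseline it never differed
  from is not meaningfully pre-adapted and is demoted to *unique*. Setting
  the flag to `FALSE` recovers the laxer reading in which only the cross
  contrast decides.

An `lfc` of exactly 0 on a significant contrast is classified as
non-positive (the down cases) — a documented tie-break for an event of
probability zero under continuous effect sizes.

The suite checks the tree against an independently written flat-conditional
oracle on the full truth table of significance/sign patterns, verifies that
all fifteen cases are reachable, and that species-swap relabelling maps the
cases onto each other as the definitions require.

## Enrichment stages

**Terms.** Per expression-model case, a one-sided hypergeometric
over-representation test against the all-orthologs background (flat,
pre-propagated annotations; no ontology-graph propagation), BH FDR < 0.05,
and the *purified-term filter*: terms under-represented in the case
(`k/n <= K/N`) are reported but never retained. The negative control draws
size-matched random gene sets in triplicate; on null annotations it retains
essentially nothing.

**Motifs.** Promoters are the 2 kb upstream of the strand-aware gene start,
clipped at contig edges. Scanning scores every position on both strands as
the log-odds sum $\sum_j \log_2(p_{b_j j}/q_{b_j})$ in bits; per-column
scores are discretized to $10^{-3}$ bits (configurable) and the *exact*
null distribution of the total score under the 0-order background is
obtained by dynamic programming, giving an exact p-value per position —
the tests hold the DP to exhaustive $4^w$ word enumeration at
$|\Delta p| < 10^{-9}$. q-values are BH across all scanned positions of a
motif, computed from the tally of discretized scores (algebraically
identical to BH on the full per-position p-value list, without storing it);
reported hits satisfy p ≤ 1e-4 and q < 0.05. Group-versus-rest motif
enrichment uses the one-tailed Fisher exact test on presence/absence with
**no multiplicity adjustment** — the stated convention of this analysis,
chosen to avoid discarding weak but consistent regulatory signal — which is
why the triplicate random-set control matters: motifs significant in
exactly one of three replicates are flagged as the signature of chance
enrichment. Positions containing N are skipped; zero motif probabilities
score $-\infty$ (such positions can never be hits) and a zero *background*
probability against a positive motif probability is an error with
pseudocount advice.

## Networks

Per species, a GENIE3-style tree ensemble (random-forest regression via
`ranger`; 1000 trees by default, 100 at desk scale; `mtry = floor(sqrt(p))`;
impurity importance, normalized to sum 1 per target) predicts each gene from
all candidate TFs except itself, on size-factor-scaled `log2(x+1)` counts
from both conditions. Candidate TFs with under 10 raw reads summed over all
samples are excluded beforehand (a per-sample-mean mode exists). Edges are
then thinned twice:

1. **Top fraction**: the `ceiling(0.10 * |E|)` highest-importance edges;
   ties at the cutoff are all kept. The stated retention is "top 10%" of
   TF–target pairs; a per-TF variant is possible but the pair reading
   matches the way the resulting networks are counted, so pairs are
   filtered.
2. **Motif filter**: an edge survives only if the target's promoter holds a
   retained hit of one of the TF's motifs; TFs with no motif in the library
   lose all edges.

Stages are nested (`motif_filtered ⊆ top_fraction ⊆ raw`) and the invariant
is asserted on every run. For the cross-species comparison both edge sets
are mapped into the ortholog namespace (unmapped endpoints are
species-tagged so they can only enlarge the union) and compared by the
directed-edge Jaccard index; bookkeeping (nodes, nodes acting as TF, edges,
intersection, union) is emitted for both the before- and after-filter
stages.

## What the synthetic generator emulates — and what it does not

`generate_truth()` fixes the study conditions: by default 3,000 orthologs,
planted |log2 fold change| 2, NB dispersion $\alpha = 0.05$, baselines
log-uniform on 50–500, five replicates per (species, condition), ±15%
library-size jitter, and a case mix chosen once to emulate the motivating
system — about 63% no-response, with responders split roughly 43% unique,
35% shared, 20% stress-ready (its four cases in the 217:230:570:537 ratio
of the motivating system) and 2% opposite. "Matching" levels are planted as
*exact* mean equality (noise supplies the realism), and every record's mean
pattern is machine-validated against its claimed case definition before
counts are drawn. Transcript lengths are drawn log-uniformly on 0.5–10 kb
independently per species, and the emitted estimates are $E = Q \cdot L$,
so the length normalization is exercised with genuinely discordant ortholog
lengths. Motif libraries are near-consensus PWMs of width 12 with 1%
per-base leak — the informativeness of a typical plant TF matrix — because
a much weaker motif cannot clear a genome-scale q < 0.05 anywhere, in
synthetic or real data. Hit tables encode the true pairing with optional
weaker decoy paralogs; annotations are per-(gene, term) Bernoulli with
planted 5× over-representation.

What passing tests on this generator show: the statistical machinery is
calibrated, the decision tree implements its definitions exactly, planted
structure at realistic effect sizes is recovered (≥95% of orthologs get
their planted case), and every file format round-trips. What they do not
show: robustness to features of real data the generator omits — isoform
mixtures, GC and mappability bias, correlated genes, batch effects,
incomplete or biased annotation, motif co-occurrence and chromatin context,
and regulatory relationships that are nonlinear or condition-specific.
Conclusions about any real species pair still depend on the quality of its
inputs.

## Numerical choices and degenerate inputs

* Score discretization $10^{-3}$ bits; DP and scanner share the identical
  integer scores, so reported p-values are exact for the discretized model.
* Median-of-ratios requires at least one gene expressed in every sample;
  otherwise the error suggests a pseudo-reference fallback rather than
  silently switching.
* Genes with zero counts in both groups get `log2fc = 0`, `p = 1`, `se = NA`.
* Dispersion floor $10^{-8}$; fold-change shrinkage constant $+0.5$ on both
  means.
* `summarize_models()` reports percentages of the total and of responders;
  with no responders the shares are `NA` and flagged, not zero.
* All randomness flows from one master seed through named substreams
  (`derive_seed`), so any stage can be reproduced in isolation; tree
  ensembles get per-target derived seeds, making network inference
  reproducible end to end.

## Problem sizes used by the tests and the acceptance script

The suite and `scripts/acceptance.R` run at desk scale, chosen as the
smallest sizes at which the statistical claims are still sharply testable:
3,000 orthologs × 5 replicates for case recovery; 1,000 genes for DE
calibration and power; widths 3–6 for the exhaustive scanner oracle; 100
random 50×50 tables for the pairing oracle; 5 true TFs × 20 targets + 50
decoys × 60 samples with 100 trees for network recovery; 300 motifs × 1,000
genes for the control false-positive rate. The full pipeline at these
defaults completes in a few minutes on one CPU.

## Known limitations

* The stress-ready call inherits the non-significance reading of
  "matching"; genes with noisy cross contrasts drift toward stress-ready,
  and the baseline-difference requirement only partly compensates.
* The NB contrast is a calibrated small surrogate, not a full GLM framework;
  multi-factor designs, batch covariates and outlier moderation are out of
  scope.
* Flat annotations mean enrichment inherits whatever propagation the
  annotation source applied.
* Motif q-values are BH over scanned positions, a ranked-transform
  surrogate of the conventional scanner's q-values, declared as such.
* The per-TF "top 10%" reading and a column-shuffled-PWM control are not
  implemented; random gene-set controls stand in for both negative-control
  wordings.
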