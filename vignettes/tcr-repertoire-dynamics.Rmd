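---
title: "Methods: repertoire diversity and clonal dynamics in tcrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire diversity and clonal dynamics in tcrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tcrdyn analyzes bulk TCR-β CDR3 immunosequencing data sampled repeatedly
from the same subject. This vignette documents the statistical model behind
each stage, the parameters that matter, the numerical and design choices
made where more than one defensible option existed, and what the synthetic
data generator does and does not emulate.

## Data model

The atomic observation is a unique nucleotide rearrangement with a template
count. The nucleotide CDR3 is the primary clone key: several distinct
rearrangements can converge on one amino-acid CDR3, and the analysis needs
both levels — nucleotide identity to decide whether a clone is *new*, and
amino-acid identity to aggregate convergent variants and to measure
similarity. `repertoire()` therefore stores one row per nucleotide clone and
`aa_clonotypes()` derives the amino-acid aggregation on demand.

Only productive rearrangements (in frame, no stop codon) enter diversity
and dynamics calculations; non-productive rows are parsed and retained so
totals are auditable, but `filter_productive()` renormalizes frequencies
over the productive subset before analysis. Whether non-productive clones
should ever be included is genuinely ambiguous in practice; productive-only
is the default here and the reader can skip the filter to change it.
Sequences are uppercased on input; rearrangements containing ambiguous
nucleotides (N) are kept but flagged rather than dropped, so library totals
are never silently altered. Sample metadata (patient, timepoint) always
comes from a sample sheet, never from file names, because exported file
names are not a reliable provenance record.

## Diversity

Diversity is summarized with the Rényi family over amino-acid clonotype
frequencies $p_1,\dots,p_S$:

$$H(\alpha) = \frac{1}{1-\alpha}\,\ln \sum_{i=1}^{S} p_i^{\alpha}.$$

$\alpha$ tunes abundance sensitivity: $H(0)=\ln S$ counts clonotypes,
$H(1)$ is the Shannon index $-\sum p_i \ln p_i$ (the $\alpha\to 1$ limit,
not covered by the formula itself), and $H(\infty)=-\ln\max_i p_i$ reflects
only the dominant clone. The default grid
$\{0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, \infty\}$ is the conventional
profile scale used by ecological diversity software, and is configurable.
All values are natural-log units (nats).

Two numerical details matter:

* For large $\alpha$, $\sum p_i^\alpha$ underflows; the implementation
  computes $\ln\sum p_i^\alpha = \alpha\ln p_{max} +
  \ln\sum (p_i/p_{max})^\alpha$, which is exact and stable up to
  $\alpha = 64$ and beyond.
* $H(0)$ is returned as $\ln S$, not $S$. The Rényi formula at $\alpha=0$
  yields $\ln S$; describing it as "the number of unique clones" refers to
  what it measures, not its scale. Profiles therefore remain monotone
  non-increasing in $\alpha$, which the tests assert as an invariant.

### Rarefaction

Observed richness and (to a lesser degree) Shannon diversity grow with
sequencing depth, so raw diversity values from libraries of different sizes
are not comparable. `subsampled_renyi()` draws a fixed depth of 70 000
reads *without replacement* from the sample's read pool — the classical
rarefaction semantics; a draw is one multivariate hypergeometric sample on
the clone counts — computes the profile on the drawn counts, repeats 500
times, and averages the $H$ values arithmetically. "Average the per-draw
$H$" and "average the drawn count vectors, then compute $H$" are both
defensible readings of a permutation-averaged rarefaction; the per-draw
average is implemented because it is the mean of the rarefied statistic
itself and has the cleaner interpretation (the alternative converges to the
exact hypergeometric expectation of the counts, which at these depths is
nearly indistinguishable).

The draw is implemented exactly, not approximately: read indices are
sampled with `sample.int(total, depth)` and mapped back to clones through
the cumulative count boundaries, so every permutation sums to exactly the
requested depth and can never draw more reads from a clone than it has.
At `depth == total` the draw is the identity and the subsampled profile
equals the exact profile to machine precision — a property the tests pin
at 1e−12.

Samples smaller than the depth are a policy decision: the default errors
(comparing a rarefied value to an unrarefied one is usually a mistake), and
`on_short = "full"` computes on the full sample with a warning for
exploratory use.

### Change calls

Per patient, Shannon values at each timepoint (computed at identical depth
and permutations) are compared to the first available timepoint:
relative deviation $|H_t - H_0|/H_0 \le 1\%$ is `unchanged`, otherwise the
sign decides `increased`/`decreased`. The boundary case (exactly 1%) is
assigned to `unchanged`, the conservative choice: a change call should
require the deviation to exceed the threshold. When a subject lacks a true
baseline sample the earliest available sample serves as the reference.

### Seeds

One master seed governs the whole run. Each sample's subsampling stream is
seeded by a 31-bit hash of (master seed, sample id), so a sample's rarefied
values do not depend on how many other samples were processed before it —
reports are reproducible under re-ordering, subsetting or parallel reruns
of the sample sheet.

## New-clone classification

For each follow-up sample the 100 most abundant *nucleotide* clones are
classified against baseline with a strict precedence:

1. `increased_nt` — the identical nucleotide rearrangement was detected at
   baseline (at any count);
2. `new_nt` — nucleotide sequence new, amino-acid CDR3 present verbatim at
   baseline (convergent recruitment toward an already-recognized antigen);
3. `new_similar_aa` — amino-acid CDR3 within Levenshtein distance 1 of some
   baseline CDR3 (single-residue neighbors very likely bind the same
   antigen);
4. `new_aa` — otherwise; an unrelated receptor.

Ranking is at the nucleotide level because categories 1–2 are only
well-defined on nucleotide rows; the headline "number of new TCRs" is
counted at the amino-acid level (distinct CDR3s in categories 3–4), and
both are reported. "New" is pure presence/absence with no abundance floor;
the known caveat — a rare pre-existing clone can appear new when the
baseline library is shallow — is surfaced as a monotonicity property in the
tests (downsampling the baseline can only increase the new count) rather
than hidden behind an arbitrary threshold. Ties at the rank-$n$ boundary
break deterministically (count descending, then sequence lexicographic).

Frequency attribution sums $\max(\Delta f, 0)$ per category: the quantity
of interest is the total *increase* in top-clone mass, so clones that
shrank contribute nothing rather than canceling gains.

Clone tracking selects the $k=7$ most abundant clones (optionally: most
abundant *new* clones) at an anchor timepoint — by default `cycle7`, the
configurable mid-treatment sample — and reports their frequency at every
timepoint, 0 when undetected. A fall to zero counts is "disappeared"; a
≥10-fold drop between consecutive timepoints is flagged as a dramatic
decrease (the fold is configurable; any specific number here is a
convention, not an estimate).

## Similarity machinery

`levenshtein()` is the standard unit-cost edit distance (computed through
base R's C implementation). The performance-sensitive operation is "does
any baseline CDR3 lie within distance 1 of this query": `neighbors()` and
the vectorized screen behind classification use a symmetric-deletion index
— two strings are within distance 1 only if their single-deletion
neighborhoods (including the strings themselves) intersect — followed by
exact verification of candidates, because the deletion rule alone
over-generates (e.g. `AB` vs `BA`). The tests hold this path to exact
agreement with a brute-force dynamic-programming oracle on hundreds of
random pools, plus the metric axioms on 10 000 random pairs.

Networks connect amino-acid clonotypes at distance exactly 1, over nodes
with frequency ≥ 0.001 (a clonotype exactly at the threshold is included;
the exclusion rule is "below 0.001"). Distance-0 pairs cannot occur since
nodes are distinct clonotypes. Networks are built per sample by default;
merging a patient's timepoints first is possible by concatenating clone
tables, but per-sample networks keep the frequency threshold meaningful.
Graphs are `igraph` objects, exported as edge/node TSVs.

## The synthetic generator

`simulation_scenario()` + `simulate_baseline()` + `simulate_timecourse()`
generate time courses with known truth. What is emulated, with defaults
chosen to resemble a treated-patient course at this assay's scale:

* **Heavy-tailed clone sizes.** Weights from a discrete power law with
  exponent 2.2 (log-normal available), scaled to a 200 000-template
  library over 20 000 baseline clonotypes — top clones land in the percent
  range, as real repertoires' dominant clones do.
* **Convergent recombination.** Clonotypes carry 1–3 distinct synonymous
  nucleotide variants (binomial with small per-variant probability),
  reverse-translated by uniform codon choice under the standard genetic
  code; CDR3s are length 10–20, C…F-framed.
* **Dynamics.** A 10-fold expansion of the 200 most abundant clones from
  the second timepoint on; optional contraction; 8 new clones planted at
  the second timepoint at 0.5–2% target frequency — 15% at distance 1 from
  an existing CDR3, 15% as new nucleotide variants of existing clonotypes,
  the rest unrelated (verified at distance ≥ 2 from every baseline CDR3) —
  decaying 20-fold per later timepoint, emulating transient
  treatment-induced clones. At a timepoint labelled `progression`,
  expansions revert.
* **Sequencing noise.** Multinomial resampling of the expected frequencies
  at each timepoint's library size. No PCR/sequencing *error* model: the
  analysis under test operates on clone tables, not reads, and an error
  model would blur the planted truth without exercising additional code.

Consequently, passing tests demonstrate that the pipeline recovers planted
events under realistic abundance structure and sampling noise; they do not
demonstrate robustness to upstream artifacts (PCR bias, sequencing errors
creating spurious distance-1 variants, contamination) or to biological
features the generator lacks (V/D/J-biased CDR3 composition, shared public
clones between subjects).

## Problem sizes in the test suite

The acceptance checks run the generator at its default scale (20 000
clonotypes, 200 000-template libraries, 70 000-read rarefaction) across 20
seeds for event recovery and change calls, with 25 rarefaction permutations
per sample — enough that the Monte-Carlo error of the averaged Shannon
value is far below the 1% decision threshold, while keeping the whole
suite's runtime modest. Unit tests use smaller repertoires (hundreds to a
few thousand clones) where the property under test does not depend on
scale. The paper-scale 500-permutation default remains the pipeline's
runtime setting.

## Known limitations

* Diversity has no bias correction (no Chao-type richness estimation, no
  coverage-based rarefaction) and no confidence intervals; values are
  rarefied point estimates, which suffices for within-patient comparison
  at a common depth but understates uncertainty between patients.
* The new/pre-existing distinction is bounded by baseline sampling depth;
  the package quantifies the direction of that bias but cannot remove it.
* Levenshtein distance 1 is a proxy for shared antigen specificity, not a
  measurement of it; no antigen-specificity inference is attempted.
* No statistical testing across patient groups is provided — the outputs
  are descriptive per-patient tables by design.
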