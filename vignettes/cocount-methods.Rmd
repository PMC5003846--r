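---
title: "Methods: reference-gene anchored analysis of targeted count panels"
author: "cocount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-gene anchored analysis of targeted count panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocount)
```

# Why not global normalization

Targeted count panels measure a few hundred hand-picked genes. When the
experimental treatment — here, exposure of melanoma cells to cytotoxic
T lymphocytes (CTLs) or their cytokines IFNγ and TNFα — changes the
expression of a large, non-random fraction of those genes, any
normalization that assumes "most genes do not change" (total-count,
global-median, quantile) is biased by construction. The alternative is to
anchor between-sample normalization on a small set of *reference genes*
demonstrated to stay flat under the treatment. Commonly used housekeeping
genes are not safe anchors in this setting: *B2M* is IFNγ-responsive,
*GAPDH* participates in networks deregulated in cancer cells, and *HPRT1*
is among the less stable classics. This package therefore couples the
normalization itself with a data-driven stability screen for replacement
reference genes (genes such as *ALG12*, *GUSB*, *RPLP0*, *KRBA2* and
*ADAT2* emerge as suitable anchors in this system).

# The normalization model

For raw counts \(C_{gj}\) (gene \(g\), sample \(j\)):

1. **Background.** \(b_j\) is the arithmetic mean of sample \(j\)'s
   negative-control probes; it is subtracted from all endogenous and
   housekeeping counts. Corrected values may be \(\le 0\) and are carried
   forward untruncated. A `pooled_background` switch subtracts one global
   negative-control mean instead; per-sample means are the default because
   lane-to-lane background differences are real on this platform, and the
   two options bracket the reasonable choices.
2. **Log transform with masking.** \(x_{gj} = \log_2(C_{gj} - b_j)\) where
   the argument is positive; all values \(\le 0\) become missing (`NA`).
   Masking at \(\le 0\) rather than only at exactly zero is a mathematical
   necessity: a negative background-corrected count has no logarithm any
   more than a zero one does. The missing mask is monotone — no later step
   ever un-misses an entry.
3. **Reference-gene shift.** With \(m_g\) the mean of reference gene
   \(g\) over the samples where it is defined, the per-sample shift is
   \[ d_j = \operatorname{mean}_{g \in R,\; x_{gj}\ \mathrm{defined}}
      \left( x_{gj} - m_g \right), \]
   the unique least-squares solution of the additive model
   \(x_{gj} \approx m_g + d_j\) ("simple regression with the mean as
   offset"). \(d_j\) is subtracted from **all** probes of sample \(j\),
   including housekeeping probes, so their post-normalization behaviour
   can be inspected. On linear scale this is a per-sample multiplicative
   rescaling by \(2^{-d_j}\). Reference genes missing in a sample are
   dropped from that sample's shift; a sample in which every reference
   gene is missing is an error, not a silent zero.

The shift is computed in closed form rather than by iterative fitting; the
test suite verifies it against an independent numerical minimization of
the same least-squares objective. When every reference gene is defined in
every sample the shifts sum to zero and the cross-sample mean of each
normalized reference gene equals \(m_g\) (both to \(10^{-9}\), asserted as
invariants). Per-sample scale factors of geometric mean 1 are absorbed
exactly; a common factor across all samples moves the anchor \(m_g\) with
it, leaving all *contrasts* invariant. Positive-control probes are parsed
and carried but take no part in normalization.

# Fold-changes and the consensus filter

Normalized linear values \(2^{x'_{gj}}\) are averaged per condition within
each cell line — missing values enter as zero counts, since they arise
precisely from counts at or below background, i.e. undetected transcripts —
and the log2 ratio is taken after adding a pseudocount \(k\) (default 10
counts) to both means. Adding \(k\) before or after averaging is identical
because a constant commutes with the mean; the implementation averages
first. The pseudocount is on the **linear** count scale (a pseudocount on
log2 values would be meaningless) and bounds the fold-change of a gene
that is absent untreated: a treated mean of 10 against an untreated mean
of 0 yields \(\log_2(20/10) = 1\), not infinity. `logFC` is computed as
`log2(mt + k) − log2(mu + k)` so that swapping the condition labels negates
every value bit-exactly.

The **consensus fourfold filter** calls a gene up (down) when its logFC is
\(\ge \log_2 4\) (\(\le -\log_2 4\)) in *every* cell line. This is the
conservative reading of "fourfold in all cell lines"; `mode = "any"` and
`mode = "average"` implement the alternative readings (threshold in at
least one line, or on the cross-line mean), and the sensitivity of the DE
count to this choice is worth reporting whenever the filter is used. Note
a structural property of any sharp threshold: effects planted *exactly* at
the threshold are recovered with probability near \(0.5^{L}\) for \(L\)
cell lines under symmetric estimation noise, because each line's estimate
falls on either side of the boundary with equal probability. The
acceptance script measures this boundary behaviour directly
(`consensus_recall_at_fourfold`); recovery is essentially complete one
noise standard deviation above the threshold, as the end-to-end test with
effects of 3 log2 units shows.

# Reference-gene discovery

`stability_screen()` computes each gene's SD (denominator \(n-1\)) of log2
expression over all non-missing samples, pooling every condition and cell
line — stability must hold *across* treatments to be useful for
normalization, which is why the SD is not computed within groups (a
`per_group` report is available for exploration only). A gene is stable
iff SD \(< 0.25\) log2 units, strictly; 0.25 log2 units means roughly
±19% expression wobble, small against the fourfold effects of interest.
Reports are sorted by ascending SD with ties broken by descending mean
expression then gene name, so output is fully deterministic. Genes seen in
fewer than 2 samples, or missing in more than half, are excluded and
listed with the reason rather than dropped silently.

`expression_screen()` then rejects candidates that the panel cannot
actually measure: missing (at/below background) in any sample, or median
normalized count below the floor. The floor defaults to twice the pooled
negative-control mean — the paper trail behind "too lowly expressed to
normalize on" never includes a number, so the floor is tied to the
measured noise floor and exposed as a parameter.

`design_panel()` spreads targets over a 5×5 (by default) equal-width grid
of mean expression × mean logFC with proportional allocation; every
occupied stratum receives at least one target when the budget allows, with
the remainder going to the densest strata. Normalization genes are drawn
from the stable and flat (|mean logFC| < 0.25) candidates, one per
expression quantile bin, highest expression first — spanning a wide
expression range without responding to treatment. Shortfalls yield a
partial design plus a warning, never a silent substitution.

# Contamination QC and platform concordance

Sorted tumor-cell samples are screened for CTL carry-over on the marker
genes *CD3D*, *CD3E*, *CD3G*, *CD8A*, *CD8B*. The background threshold is
\(B = \text{mean} + 2\,\text{SD}\) of the negative-control counts after
placing them on the normalized scale (each sample's negatives scaled by
\(2^{-d_j}\)); mean + 2 SD is standard practice for this platform and the
multiplier is exposed (`bg_k`). A marker above \(B\) in a sample flags the
sample with the offending marker and its magnitude; there is no
whitelisting of marginal exceedances — interpretation (probe
cross-reactivity, low-level expression by the tumor cells themselves) is
left to the analyst.

Cross-platform concordance of fold-changes (e.g. genome-wide microarray
versus count panel) is summarized by the Pearson correlation and the
**compression slope**: the OLS slope of platform-a logFC on platform-b
logFC. A slope below 1 means platform a systematically underestimates
fold-changes relative to platform b, the well-known compression of
microarrays against hybridization counting. The slope is reported, not
tested against a fixed value, because its true value is a property of the
platforms at hand.

# The synthetic-data generator

`simulate_panel()` draws endogenous and housekeeping counts from a
negative binomial with mean
\(f_j\,(\mu_g 2^{\delta_{gc} t_j}(1-\pi_j) + \pi_j s_g)\) and dispersion
\(\phi\) (variance \(\mu + \phi\mu^2\)): \(f_j\) lane factors, \(\mu_g\)
base means, \(\delta_{gc}\) per-cell-line treatment effects, \(\pi_j\) a
contamination fraction mixing in the contaminant's marker signature
\(s_g\) at the mean level, and Poisson negative controls with rate
\(\lambda_j\). `simulate_expression_matrix()` emulates a processed log2
array: \(\log_2\mu_g + \delta_{gc} t_j + N(0, \sigma_g)\) with
\(\sigma_g = 0.05\) for stable genes and log-normal(median 0.6, sdlog
0.15) for variable genes, plus missing-completely-at-random entries.

Defaults mirror the study conditions: 3 melanoma cell lines ×
{untreated, CTL co-culture, cytokines}; 185 target genes with log-normal
base means; 8 housekeeping candidates of which 3 are planted at background
level (the situation where candidates must be rejected as too low); CD3/CD8
markers expressed only by the contaminant (signature 2000 counts);
\(\phi = 0.1\) (typical panel overdispersion); \(\lambda = 8\) counts;
lane factors log-normal with sdlog 0.25. The expression preset uses 100
stable among 900 variable genes over 12 samples. The sdlog of 0.15 for
variable-gene noise keeps "variable" a well-separated class so that
stability-screen operating characteristics measure the method, not
boundary luck of the draw. All generators are bit-reproducible from their
seed, and the truth record round-trips through YAML.

What the simulation does **not** emulate — and hence what passing tests do
not demonstrate about real data: probe-specific hybridization efficiency
and cross-reactivity, cartridge/batch structure, RNA-quality degradation,
correlated gene modules (noise is independent across genes), read-level
contamination, and the heavy, structured missingness of real arrays. The
contamination model in particular is a mean-level linear mixture,
sufficient to exercise the QC screen but not a cell-level model.

# Numerical choices and degenerate inputs

* Corrected counts \(\le 0\) are masked, never floored; downstream code
  treats the resulting `NA`s explicitly (zero contribution to condition
  means, exclusion from per-sample shifts, pass verdicts in QC).
* A single sample gets shift 0 (each \(m_g\) is the only observation).
* Shifting twice is idempotent; tolerances of \(10^{-9}\) are asserted
  where exact-arithmetic identities hold up to floating point.
* Stability ties are broken deterministically (mean expression, then
  name); the strict `<` at the SD threshold follows the defining rule
  "SD below the threshold".
* Degenerate panel-design axes (e.g. all fold-changes identical) collapse
  to a single bin instead of failing on non-unique breaks.
* `consensus_fourfold` rejects fold thresholds \(\le 1\); a gene with a
  missing logFC in any line cannot enter a consensus set.
* RCC parsing is fail-fast: unknown CodeClass values, non-integer counts,
  missing sections and gene-set mismatches between lanes are errors that
  name the offender, and no probe is ever dropped silently.

# Problem sizes

The test suite and the acceptance script run entirely on simulated data at
the study's own scale: panels of ~200 probes × 9–18 samples, expression
matrices of 1,000 genes × 12 samples, 150-gene platform comparisons, and
50 random 20 × 6 instances for the least-squares cross-check. The whole
suite completes in a few seconds.

# Known limitations

* The shift model assumes reference genes share a single per-sample
  offset; probe-specific scale distortions are not modeled.
* With very few reference genes the shift inherits their counting noise
  (\(\operatorname{Var}(d_j) \approx \overline{(\phi + 1/\mu)} /
  (R \ln^2 2)\) for \(R\) reference genes), which is why candidates are
  screened for expression before use.
* The DE criterion is a pure fold-change filter; no variance moderation,
  p-values or FDR are computed, matching the screening character of the
  upstream assay.
* Batch/cartridge covariates are not modeled.
* The genome-wide half of the workflow consumes an already-processed log2
  matrix; raw array preprocessing is out of scope.
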