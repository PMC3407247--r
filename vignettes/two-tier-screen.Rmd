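---
title: "The two-tier expression/drug-response screen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-tier expression/drug-response screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoscreen)
```

## The problem

Cytotoxic nucleoside analogues show strikingly heterogeneous activity across
tumor cell lines, and intracellular drug accumulation often fails to explain
it. A productive alternative is to ask which *transcriptional* states travel
with sensitivity or resistance. chemoscreen implements a two-tier design for
that question: a statistically powerful but biologically broad screen across
a large cell-line panel, a biologically focused but small paired
sensitive/resistant comparison, and a deliberately stringent intersection of
the two. Genes surviving both tiers are associated with response in two
independent datasets measured on two different platforms — a far stronger
claim than either screen supports alone.

## Tier 1: panel correlation screen

For each probe the screen computes the Pearson correlation \(r\) between
log2 expression and \(\log_{10}(\mathrm{GI}_{50})\) across the panel, then
the exact conversion

\[ t = \frac{r\sqrt{df}}{\sqrt{1-r^2}}, \qquad df = n_{\text{used}} - 2, \]

and the two-tailed Student-\(t\) tail probability. With a complete 60-line
panel, \(df = 58\). Probes with \(P < \alpha\) (default
\(\alpha = 0.05\)) are split by the sign of \(r\): positive correlations
mark *resistance-associated* transcripts (expression rises with
\(\mathrm{GI}_{50}\)), negative ones *sensitivity-associated* transcripts.

Numerical and policy choices:

* **Pairwise-complete observations.** Missing cells are dropped per probe;
  \(df\) follows \(n_{\text{used}}\). The source datasets do not document
  their missingness handling, so this is the package's own convention.
* **Degenerate probes** (zero variance, or fewer than three complete pairs)
  are skipped and reported, never scored as \(r = 0\); silent zeros would
  contaminate downstream multiplicity counts.
* **\(|r| = 1\)** makes \(t\) infinite; the tail probability is reported as
  the smallest representable positive double and flagged, keeping
  \(P \in (0, 1]\).
* **Ranking** is by descending \(|r|\) with ties broken lexicographically by
  probe identifier; published ranked tables carry no tie rule, and a
  deterministic one keeps reruns byte-identical.
* **Collapse to genes**: distinct symbols per direction; a gene whose probes
  reach significance in *both* directions is excluded from both sets and
  logged. The case is undocumented in the source analyses; exclusion is the
  conservative, testable choice.

The screen computes the correlation directly rather than through a fitted
regression — the estimand is identical and the contract simpler.

## Tier 2: paired differential screen

The paired tier compares replicated expression profiles of drug-sensitive
versus drug-resistant cell lines, organized in pairs (by default an MM-like
and an MCL-like pair, three replicates per group).

* **Detection filter.** A probe is kept if its detection P value is below
  0.01 in at least one sample. Published probe-level counts do not specify
  the per-sample rule; "present in ≥ 1 sample" is the package's explicit
  choice.
* **Normalization** is concretely log2 followed by full quantile
  normalization (via limma). The original platform pipeline is proprietary
  and underspecified; full quantile normalization is the closest widely
  understood equivalent. This is a documented divergence.
* **Moderated statistics.** Per probe, the residual variance \(s^2\) pooled
  across all design groups (df \(d\)) is shrunk toward a prior:
  \(\tilde v = (d_0 s_0^2 + d s^2)/(d_0 + d)\). The hyperparameters
  \((d_0, s_0^2)\) are estimated by moment-matching the observed log
  variances against the scaled-F sampling model, inverting the trigamma
  function by Newton iteration. If the observed spread of log variances does
  not exceed the pure chi-square sampling spread, the prior is degenerate:
  \(d_0 = \infty\), \(s_0^2\) = the mean variance (every probe then uses the
  common variance). At the other limit \(d_0 = 0\) the statistic reduces to
  the ordinary pooled-variance t test — both limits are exercised by tests.
* **Per-pair contrasts, intersection-union combination.** Each pair's
  sensitive-minus-resistant contrast is tested on \(d_0 + d\) df. The
  combined P is the *maximum* over pairs: the union of the pairwise nulls is
  rejected only if every pair rejects, matching the requirement that changes
  be directionally congruent in every pair. FDR (Benjamini–Hochberg,
  delegated to `stats::p.adjust`) is computed on the combined P. Whether the
  original analysis applied FDR jointly or per pair is unknown; the joint
  max-P convention is conservative.
* **Congruence filter.** A probe passes iff in every pair the change has the
  same direction with linear fold change strictly greater than 1.5 (or below
  1/1.5) and raw \(P < .01\), and the combined q is below .05. "Greater than
  1.5-fold" is read as strict: a fold change of exactly 1.5 fails.

## Tier 3: integration

Pure set intersection of the directional gene sets, matching on gene symbol
after whitespace stripping and case folding — symbols are the only key the
two array platforms share. No significance re-weighting occurs at this
stage. Invariants (overlap ⊆ each parent; the two directional overlaps
disjoint; commutativity; idempotence) are asserted in the test suite.

## Assay-level calculations

* `kinetic_rate()`: ordinary least-squares slope of a fluorescence trace
  (signal units/min) over the full 31-point, 30-minute window; no windowing
  or lag detection, since the assay protocol reports none.
* `g6pd_specific_activity()`: total (G6P + 6PG) minus 6PG-alone NADPH
  production rate; isolates glucose-6-phosphate dehydrogenase activity from
  the downstream 6PGD contribution. Negative differences are returned with a
  warning, not clamped.
* `normalize_cell_death()`: \(100 - 100\,f_T/f_U\) for treated/untreated
  viable (DAPI-negative) fractions; untreated-vs-itself is exactly 0%, and
  "protective" treatments yield negative values, flagged but preserved.
* `genorm_factor()`: geometric mean of ≥ 2 reference-gene quantities. The
  geNorm stability ranking of candidate references is out of scope; only the
  normalization factor is used.

## What the synthetic data emulate — and what they do not

`simulate_panel()` draws a standard-normal phenotype \(z\), sets
\(\log_{10}(\mathrm{GI}_{50}) = -5.5 + 0.75 z\) (centering the panel in the
\(10^{-7}\)–\(10^{-4}\) M range typical of cytotoxic screens), and builds
planted probes as \(x = \rho z + \sqrt{1-\rho^2}\,\varepsilon\), giving an
exact population correlation \(\rho\) with a simple Fisher-z oracle. Null
probes are independent Gaussian log2 noise.

`simulate_paired_experiment()` plants log2 fold changes in the sensitive
groups of *every* pair over Gaussian log2 (log-normal intensity) noise
(default SD 0.25, baseline mean 8 ± 1.5 — ordinary microarray magnitudes),
with per-probe detection P values. Probes flagged "absent" (default 25% of
null probes) draw detection P uniformly *above* the 0.01 detection
threshold, so a detection filter at that threshold removes exactly the
absent set; this makes planted detectable counts exactly recoverable, at the
cost of ruling out borderline detection calls that real bead arrays do
produce.

Neither generator models probe-level bead effects, batch/chip structure,
inter-gene correlation, or heavy-tailed noise. Passing tests therefore
demonstrate the statistical machinery (calibration, power, shrinkage,
thresholding, set logic) under the assumed noise model — not robustness to
real-array artifacts.

Default problem sizes in the tests and the acceptance script (panels of
2,000 probes × 60 lines, ten replicate panels; 1,000 panels for power;
200 paired experiments of 400 probes for null FDR; 5,007-probe datasets for
end-to-end recovery) were chosen to make Monte-Carlo error small relative to
the tested effects while keeping a full run in the order of a minute.

## Determinism

Every generator takes an explicit seed and restores global RNG state;
pipelines rerun byte-identically on identical inputs, and the run manifest
records input/output checksums and thresholds but deliberately no
timestamps.

## Known limitations

* Replicate structures of real paired-line experiments vary and are often
  undocumented; the default 2-pairs × 2-groups × 3-replicates design is an
  assumption, though the code accepts any ≥ 1 pairs with ≥ 2 replicates.
* Real-data gene identities and counts (e.g. how many unique transcripts
  pass tier 1 on the real panel) depend on the external datasets and are
  out of the package's reproducibility claims; the pipeline only guarantees
  the schemas and the statistical behavior verified on synthetic data.
* Symbol-level integration inherits all the ambiguity of gene-symbol
  curation across platforms; probe-level cross-references would be stronger
  but are not available as a common key.
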