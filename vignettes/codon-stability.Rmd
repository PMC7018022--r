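---
title: "Coding-sequence determinants of mRNA stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding-sequence determinants of mRNA stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonstab)
library(dplyr)
```

## The problem

In organisms from budding yeast to mammals, the coding sequence itself is a
determinant of mRNA half-life: transcripts enriched in "optimal" codons —
codons decoded quickly because their cognate tRNAs are abundant — tend to be
more stable, and in mammalian cells the encoded amino acid content carries
an additional, partly independent signal. codonstab implements the
quantitative toolkit for this kind of analysis: composition statistics of
coding sequences, per-codon and per-amino-acid stability coefficients
against a half-life table, tRNA-seq-based codon optimality, reporter design
by synonymous codon flipping, half-life estimation from metabolic-labeling
decay timecourses, and the downstream regression and rank-test machinery.
A synthetic-data module generates every input with known ground truth so
the full pipeline is testable without external downloads.

## Stability coefficients

The **codon stability coefficient (CSC)** of codon $c$ is the Pearson
correlation, across transcripts, between the codon's length-normalized
frequency and transcript half-life:

$$\mathrm{CSC}_c = \mathrm{cor}\big(f_c(t),\ t_{1/2}(t)\big),$$

computed over the 61 sense codons. Codon frequencies are counted on
non-overlapping frame-0 triplets; stop codons and triplets containing N are
excluded from both numerator and denominator so that every transcript's
frequencies sum to 1 over the same 61-codon universe. The initiator ATG is
included in the denominator: it is a genuine decoded codon, and excluding it
would perturb frequencies of short ORFs most. Frameshifted profiles
(frames +1/+2, skipping one or two leading nucleotides) serve as negative
controls — effects that survive frameshifting are compositional rather than
translational.

The **amino acid stabilization coefficient (AASC)** is the analogous
correlation for the 20 canonical amino acid frequencies of the translated
ORF. Translation uses the standard genetic code; codons containing N
translate to "X" (tracked separately, excluded from the 20 frequencies) and
internal stops are retained as "*" so frameshifted sequences can still be
profiled. Each coefficient carries a two-sided p-value and a 95% Fisher-z
confidence interval. Significance tiers default to p < 0.01 for CSC and
p < 0.001 for AASC, with a genome-wide flag at p < 5e-8; all thresholds are
arguments. Zero-variance frequencies produce NA coefficients, never a
silent zero. Joins between profiles and half-life tables are inner joins
with the attrition count reported — silent identifier mismatch is the most
common reproduction bug in this kind of analysis.

Transcript-level scores are frequency-weighted sums,
$\mathrm{avgCSC}(t) = \sum_c f_c(t)\,\mathrm{CSC}_c$ (and analogously for
AASC). NA coefficients are dropped with the remaining weights renormalized,
and the number of excluded terms is reported; renormalization avoids biasing
scores of transcripts rich in NA-coefficient codons.

## Codon optimality from tRNA-seq

Relative tRNA availability per codon is summarized by a tRNA adaptation
index computed from tRNA-seq read counts. Counts are aggregated by
anticodon after per-gene counting (isodecoders pooled), converted to reads
per million, and combined over the anticodons able to decode each codon:

$$W_c = \sum_{a \in \mathrm{dec}(c)} (1 - s_{a:c})\, \mathrm{RPM}_a,
\qquad \mathrm{tAI}_c = W_c / \max_{c'} W_{c'}.$$

The wobble penalties $s$ default to the classical selective-constraint
values (Watson-Crick pairs 0; G:U 0.41; I:C 0.28; I:A 0.9999; U:G 0.68,
with anticodon position-34 A treated as inosine) and are fully configurable
through `default_wobble_weights()`, so alternative conventions can be
reproduced. Selenocysteine and initiator-methionine genes are excluded by
gene-id pattern before RPM computation; the SeC anticodon would otherwise
leak signal into Trp.

A codon is **optimal** when its tAI is strictly greater than the median of
the 61 values; ties at the median are non-optimal. With 61 distinct values
this yields exactly 30 optimal codons, and it forces the margins of the
GC3-by-optimality contingency table (31 GC3 / 30 AT3 sense codons by 30
optimal / 31 non-optimal), which `fisher_gc3_vs_optimality()` tests
exactly.

## Reporter design by codon flipping

`flip_to_target_optimality()` rewrites an ORF toward a target percent
optimal codons while preserving the protein exactly and altering as few
codons as possible: eligible positions are shuffled once with a
caller-supplied seed, consumed until the running count crosses the target,
and the stopping point nearer the target is kept; replacement synonyms are
drawn uniformly from the desired side of the median. Methionine and
tryptophan are never flip-eligible, which (with other single-sided synonym
families) bounds the achievable range — `optimality_range()` reports the
theoretical minimum and maximum, and out-of-range targets fail with that
range in the message.

```{r flip-example}
tai <- tai_from_counts(generate_trna_counts(depth = 1e6, seed = 2))
cds <- generate_transcriptome(sim_config(n_transcripts = 3, seed = 3))$cds[1, ]
optimality_range(cds$seq, tai)
flip_to_target_optimality(cds, tai, target = 60, seed = 1)[, c("percent_optimal", "n_flips")]
```

## Half-life estimation from decay timecourses

Metabolic-labeling chases measure the labeled pool at timepoints 0-12 h
(default grid 0, 0.5, 1, 2, 3, 4, 6, 8, 10, 12 h). Two normalizations
precede fitting. First, spike-in normalization: each timepoint's factor is
the mean of the two spike-in read counts over the total, and each column is
divided by its factor relative to t0 — this removes the apparent
amplification caused by the shrinking labeled pool at late timepoints.
Second, each transcript is scaled to 100 at t0, so abundances read as
percent remaining. Transcripts with raw t0 FPKM below 1 are flagged.

The decay model is
$y(t) = A \exp\{-(k + \ln 2 / T_d)\,t\}$, fitted by least absolute
deviations in linear abundance space; $\ln 2 / T_d$ subtracts the apparent
decay contributed by cell growth (doubling time $T_d$, default 15 h), and
the half-life is $\ln 2 / k$. LAD rather than least squares makes the fit
robust to single corrupted timepoints (a property the test suite checks
against an L2 reference on 200 seeded trials).

Two numerical choices deserve note. The optimizer is deterministic — a
coarse 200-point grid on $k \in [0, 10\ln 2]\ \mathrm{h^{-1}}$ (log-spaced
above the floor) followed by local refinement — so repeated runs are
identical without a stochastic optimizer. And the amplitude $A$ is
estimated by default rather than pinned at 100: the t0 point is a
measurement like any other, and pinning the curve to it propagates t0 noise
directly into the rate. In our simulations at 10% multiplicative noise the
pinned variant's median relative half-life error is about half again larger
than the free-amplitude fit's (≈0.10 vs ≈0.07); `free_intercept = FALSE`
restores the pinned convention. Fits hitting the $k = 0$ boundary are
flagged non-decaying with infinite half-life rather than reported as
numbers.

`filter_estimates()` applies the standard post-fit hygiene: estimates with
half-life above 18 h or mean absolute residual above 20 (interpreted on the
percent-remaining scale, the only scale on which 20 is a sensible
magnitude; the t0 residual is included in the mean's denominator) are
rejected, with every violated rule counted separately in the report.

## Association models

Half-life distributions are right-skewed, so the transcript-level model
uses the reciprocal transform $y = -1/t_{1/2}$ (strictly increasing, all
negative) and fits

$$-1/t_{1/2} \sim \mathrm{avgCSC} + f_{GC3}$$

by ordinary least squares via `lm()`, with per-term 95% CIs, adjusted
R-squared and the overall F-test exposed through `tidy()`/`glance()`.
Constant or collinear regressors fail with the offending term named.

The codon-level model `csc ~ tai + concentration` asks whether tRNA
availability and free amino acid concentration jointly predict CSC. Codons
encoding cysteine and glutamate are excluded (free concentrations
unmeasurable or extreme outliers in cell lysates), leaving 57 rows; the
model is optionally restricted to codons whose amino acids have moderate or
extreme stability effects. The partition rule is |AASC| > 0.10 and
p < 1e-30; with the canonical six extreme amino acids (V, I, Y stabilizing;
S, H, Q destabilizing) the subsets have 38 and 19 codons. Note that
synonymous codons share one free-amino-acid value, which strains the
independence assumption of the codon-level model — a caveat inherited from
the design, not repaired here.

Stratified comparisons use equal-width bins over the covariate's observed
range by default (edges are configurable; no canonical edges exist for
these analyses) with a Kruskal-Wallis omnibus test, and two-group
comparisons use the two-sided Wilcoxon rank-sum test — exact for small
tie-free samples, mid-rank normal approximation otherwise, as implemented
by `stats::wilcox.test()`. Highly stable transcripts that pass depth
filters but defeat curve fitting can be assigned a stated ceiling
half-life (default 24 h) by `impute_max_halflife()`, an explicit and
logged step rather than a silent drop of the most stable genes.

## The synthetic-data generator

`sim_config()` pins every knob of the generative model; all randomness
derives from one integer seed through R's default Mersenne-Twister
generator with inversion sampling, so outputs are byte-identical across
runs and platforms.

* **Transcriptome** — per-transcript codon compositions drawn from a
  Dirichlet over the 61 sense codons (concentration `codon_alpha`,
  default 5: visible between-transcript usage variation), ORF lengths
  lognormal (median 180 codons), initiator ATG prepended. Sampling sense
  codons only means no internal stops by construction, keeping the
  translation and profile invariants clean.
* **Half-lives** — log-linear in the realized composition:
  $\eta = \sum_c \beta_c f_c + \sum_a \beta_a f_a + \varepsilon$,
  $t_{1/2} = e^{\eta - \mathrm{med}(\eta)} \cdot m$ with median $m = 4$ h
  and lognormal noise (default $\sigma = 0.25$). Exponentiation guarantees
  positivity and right skew; the log-linear form is the simplest under
  which CSC sign recovery is well-defined. It is an artifact of the
  generator, not a biological claim.
* **Timecourse** — signal $t_0\mathrm{FPKM} \cdot e^{-(\ln 2/t_{1/2} +
  \ln 2/15)t}$ at the 10 standard timepoints, multiplied by a
  per-timepoint spike distortion (lognormal, $\sigma = 0.2$, 1 at t0) that
  the spike-in read counts track exactly so normalization can invert it;
  multiplicative lognormal noise ($\sigma = 0.1$) applied last. Spike read
  counts are expected (real-valued) counts so the noiseless round trip is
  exact to machine precision.
* **tRNA counts** — either drawn from lognormal anticodon abundances (the
  implied tAI is returned as truth) or solved from a target tAI vector by
  non-negative least squares under the wobble model, then sampled
  multinomially at the requested depth. Unrealizable tAI vectors are
  rejected with a feasibility error.

What the generator does **not** emulate: real human codon-usage tables, GC
isochore structure, UTR-mediated decay, count noise in FPKM estimation, or
correlations between expression level and half-life. Passing tests
demonstrate that the estimators recover the structure the generator plants
under realistic noise — not that any particular biological dataset will
show that structure.

## Problem sizes and tolerances in the test suite

The suite validates estimators at sizes chosen to make the statistical
properties sharp while keeping a full run in well under a minute of compute:
planted-effect CSC recovery on 2,000 transcripts (planted log-scale codon
effects of magnitude 3-4, noise $\sigma = 0.25$), half-life recovery on 500
trajectories spanning 0.5-12 h at $\sigma = 0.1$ (median relative error
required < 10%), 200-trial LAD-vs-L2 robustness comparisons, 100-permutation
CSC null checks, and exact-enumeration cross-checks of the Fisher and
Wilcoxon paths on tables small enough to enumerate completely. Exact
algebraic identities (Pearson vs covariance formula, OLS vs normal
equations, noiseless decay inversion) are asserted at 1e-9 or 1e-6.

## Known limitations

* tRNA-seq counts are taken as given; no modification-aware quantification
  or alignment is performed, and isodecoder aggregation happens after
  per-gene counting (whether to aggregate before or after RPM is a
  convention; this package aggregates after).
* The wobble decoding table is the classical one; organisms with unusual
  decoding (mitochondria, some protists) need a custom table.
* The codon-level regression inherits the shared-free-amino-acid
  pseudo-replication noted above.
* Only the two fixed significance thresholds printed in the coefficient
  tables are applied; no multiple-testing correction is layered on top.
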