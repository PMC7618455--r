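---
title: "Models and methods behind resistrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind resistrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental design being modeled

`resistrace` analyzes sister-cell lineage-tracing experiments. A cell
population is transduced with expressed barcodes ("lineage labels" of 20
random bases embedded in a fixed anchor construct), synchronized, and allowed
to divide exactly once, so each barcode marks a pair of sister cells. The
population is then split at random: one half is profiled by scRNA-seq (the
*pre-treatment* sample), the other half is drug-treated at a dose chosen to
kill roughly 70% of cells. Surviving cells regrow and are profiled (the
*post-treatment* sample). Because sisters share a label, a label detected
among survivors annotates its sister in the pre-treatment sample as
*pre-resistant*; labels absent from the survivors mark *pre-sensitive* cells.
A vehicle-control arm (DMSO) treated the same way yields *pre-fit* /
*pre-unfit* classes that capture growth fitness rather than drug resistance,
and is used to subtract fitness effects from the resistance signature.

The package implements every computational stage of this design — barcode
extraction and error correction, fate partitioning, QC and normalization,
sister-concordance testing, signature derivation, connectivity-based drug
nomination, and dose-response synergy scoring — together with a synthetic-data
generator that reproduces the design with known ground truth, so the whole
pipeline is testable without sequencing data.

# The synthetic generator

`simulate_experiment()` draws, per arm:

* a latent **resistance score** $r_\ell \sim N(0,1)$ and **fitness score**
  $f_\ell \sim N(0,1)$ per lineage;
* gene baseline abundances $w_g$ from a log-normal (sd 1.5 on the log scale),
  normalized to relative abundances;
* per-cell log-expression
  $x_{cg} = \sigma_b\left(\sqrt{h_g}\, Z_{\ell(c)g} + \sqrt{1-h_g}\,
  \varepsilon_{cg}\right) + \ln 2 \,\beta_r r_\ell [g \in R]
  + \ln 2\, \beta_f f_\ell [g \in F]$,
  where $h_g$ is the heritability (share of biological variance carried by
  the lineage-shared factor $Z$), $\sigma_b$ the biological log-sd
  (default 0.35), and $\beta_r,\beta_f$ the planted log2 effects on the
  resistance set $R$ and fitness set $F$;
* counts $y_{cg} \sim \mathrm{NB}(\mu_{cg}, \phi)$ with
  $\mu_{cg} \propto w_g e^{x_{cg}}$ scaled to a log-normal per-cell library
  size around `mean_depth`.

Two modeling choices deserve comment:

* **Noise decomposition.** Biological variability is modeled explicitly by
  the log-normal layer (split by heritability), so the negative-binomial
  dispersion represents only technical overdispersion beyond Poisson
  sampling. For UMI-based protocols this residual component is small; the
  default is $\phi = 0.05$. Setting $\phi$ larger double-counts biological
  noise as non-heritable and dilutes every lineage-driven signal.
* **Splitting and survival.** Each lineage contributes exactly two daughters;
  each daughter enters the profiled half independently with probability 0.5,
  so singleton and doubleton pre-lineages arise naturally (as in the real
  design, where most labeled pre-treatment cells are singletons). Treated
  daughters survive a Bernoulli draw with logistic probability in the arm's
  latent score — $r_\ell + 0.5 f_\ell$ in the treatment arm (the 0.5 weight
  makes the pre-resistance signature partially overlap the pre-fitness
  signature, as observed in practice), $f_\ell$ in the control arm. The
  logistic intercept is solved numerically against the realized scores so
  the expected death rate equals `kill_fraction` (default 0.70); the slope
  is a knob (default 2).

What the generator does **not** emulate: ambient RNA, doublets, cell-cycle
structure, clone expansion during regrowth, mutation acquisition, batch
effects. Passing tests therefore demonstrate correctness of the pipeline's
statistics under a clean generative model, not robustness to every artifact
of real droplet data.

The generator also produces barcode reads (`corrupt_reads()`: the full
anchor construct with per-base substitution errors at a configurable rate)
and dose-response plates (`simulate_dose_response()`: 4PL monotherapies,
a named combination null model — Bliss, HSA or Loewe-additive — plus a
planted synergy shift and Gaussian noise, with plate controls anchoring the
viability scale).

# Barcode extraction and error correction

Labels are extracted by exact matching of the anchor sub-pattern
`CANNNNTGNNNNACNNNNGANNNNGTNNNNCT` (five blocks of four informative bases
separated by fixed dinucleotides), searching both orientations; the 20
informative bases are concatenated. Anchors are matched exactly — reads with
corrupted anchors are dropped rather than fuzzily matched, because the
downstream directional correction already absorbs single-base errors in the
informative positions, and fuzzy anchors would admit spurious matches.

Error correction uses the *directional* network method: a directed edge runs
from label $a$ to label $b$ when they differ at exactly one base and
$\mathrm{count}(a) \ge 2\,\mathrm{count}(b) - 1$; components are grown from
the highest-count unassigned node by following these edges transitively
(chains $a \to b \to c$ collapse to the root), and count ties are broken
lexicographically to keep the mapping deterministic. Counts are per-sample
total read counts; the sample-level mapping is then reused per cell. Per
cell, the corrected label with the highest read support wins; ties mark the
cell unlabeled. Labels carried by more than four cells of a pre-treatment
sample are removed entirely, since they cannot identify a single lineage.

# QC, normalization, variable genes

Gene filter first (expressed in at least three cells), then cell filters:
total UMIs and detected genes inside inclusive intervals
([20000, 200000] and [2500, 12000] for pre-treatment samples;
[10000, 100000] and [2000, 10000] for post-treatment samples) and
mitochondrial fraction strictly below 0.15 — the strict/inclusive reading
follows the interval notation of the protocol being modeled.
Normalization is the standard library-size transform
$\ln(1 + 10^4\, y_{cg} / \sum_g y_{cg})$. Variable genes are ranked by a
variance-stabilizing statistic: a loess trend (span 0.3, degree 2) of log10
variance on log10 mean of the raw counts, per-gene standardization by the
trend-expected sd, clipping at $\sqrt{n_\mathrm{cells}}$, and ranking by the
variance of the clipped values. The selector is parameterized because the
upstream tools it mirrors treat it as a default; the trend span and clip are
exposed.

# Sister concordance

Sister pairs are cells sharing a corrected label within one pre-treatment
sample, restricted to lineages with exactly two cells for the concordance
analysis. Pair similarity is the Euclidean distance over the top 1000
variable genes on log-normalized values (the alternative of additionally
scaled values is noted; we use normalized values so distances are
interpretable in log-expression units). Two data-driven quantile filters are
applied: genes whose total normalized expression falls below the 10%
quantile are removed, and sister pairs above the 90% distance quantile are
discarded as likely mislabeled. Both cutoffs are recomputed from each
dataset (R's default type-7 linear interpolation; ties at the cutoff are
kept) — published realizations of these cutoffs are dataset properties, not
constants.

Per gene, the within-pair absolute log2 fold change
$|\log_2\frac{e_a + 1}{e_b + 1}|$ (on normalized-then-unlogged expression;
pseudocount 1 avoids infinities on zeros and is configurable) is compared
between sister pairs and uniformly sampled non-sister pairs by a Welch
two-sample t-test, two-tailed, with BH adjustment across genes; a gene is
*sister-concordant* when adjusted P < 0.05 with the sister mean lower. The
absolute value is used because pairs are unordered, so a signed fold change
is ill-defined; Welch rather than pooled variance because the two pair
populations have no reason to share a variance. The random-pair count
defaults to 100000 — the full set of all pairs (order $10^8$ at realistic
cell numbers) adds nothing statistically and is kept as an option.
Zero-variance genes are recorded with P = 1 rather than dropped.

# Signatures and specificity

Differential expression between pre-resistant and pre-sensitive cells (and
pre-fit vs pre-unfit) uses the two-sided Wilcoxon rank-sum test with
tie-corrected normal approximation and continuity correction, no fold-change
or detection-fraction thresholds, BH adjustment, and
$\log_2\mathrm{FC} = \log_2\frac{\bar e_A + 1}{\bar e_B + 1}$ on unlogged
normalized means — mirroring the de-facto single-cell convention. Only
cells lacking sisters in the same pre-treatment sample enter these
contrasts: a doubleton pre-lineage either marks elevated basal growth or
guarantees a false-negative fate (its treated sister may not exist), so
singletons are the informative cells.

The specificity of a gene for resistance (vs growth fitness) is the contrast
$\Delta = \log_2\mathrm{FC}_{\mathrm{resistance}} -
\log_2\mathrm{FC}_{\mathrm{fitness}}$, tested two ways:

* **bootstrap**: resample cells with replacement within each of the four
  groups, recompute $\Delta$; one-sided P = (1 + #{$\Delta^* \le 0$}) /
  (n + 1), oriented for genes up-regulated in pre-resistant cells (the
  direction of interest);
* **permutation**: shuffle fate labels within each arm, recompute $\Delta$;
  two-sided P = (1 + #{$|\Delta^*| \ge |\Delta|$}) / (n + 1).

Both default to 1000 iterations and are exact under a fixed seed. A gene is
*specific* when the signature's adjusted P < 0.05, both resampling P < 0.05,
and $\Delta > 0$. The exact resampling schemes are this package's documented
constructions — the tests they implement are named but not specified in
detail by the protocol being modeled; one-sided bootstrap with two-sided
permutation is the default, both orientations are options.

The four query variants for drug matching are: (1) the full pre-resistance
log2FC; (2) restricted to raw Wilcoxon P < 0.05; (3) the contrast
$\Delta$; (4) the contrast restricted to bootstrap P < 0.05 — all
intersected with the sister-concordant gene set, so that only heritably
expressed genes (those whose pre-treatment readout is a faithful proxy for
the treated sister) can drive drug nomination.

# Connectivity scoring

A drug profile is scored against a query signature Connectivity-Map style:
the query splits into up (log2FC > 0) and down (log2FC < 0) sets; each set
gets a weighted KS enrichment score against the drug's ranked profile
(weight exponent 1 on the |rank statistic|, configurable); the score is
$(ES_{up} - ES_{down})/2$ when the two enrichment scores have opposite
signs and exactly 0 otherwise. Negative scores mean the drug reverses the
signature. Significance comes from permuting the gene labels of the drug
profile (not the query) with a +1 correction. Genes present in the query
but absent from a profile are dropped per pair, with a minimum-overlap guard
(default 10 genes). A drug is nominated when its score is negative with
P < 0.05 in **all four** variants; candidates are ranked by mean score.
The score depends only on the profile's ranking, so any monotone transform
of a drug library's values leaves results unchanged.

# Synergy scoring

Raw viability plates are anchored to controls:
$\mathrm{inhibition}\% = 100\,(\mathrm{neg} - \mathrm{reading}) /
(\mathrm{neg} - \mathrm{pos})$, averaged over replicates, not clipped (an
out-of-range flag is emitted instead). The linear two-control anchoring is
the standard readout normalization for luminescent viability assays; the
protocol modeled here fixes the controls but not the formula.

Reference models, all reported in percentage points over combination cells:

* **HSA**: excess over $\max(y_1(d_1),\, y_2(d_2))$;
* **Bliss**: excess over $y_1 + y_2 - y_1 y_2$ (fraction scale);
* **Loewe**: excess over the response $y$ solving
  $d_1/D_1(y) + d_2/D_2(y) = 1$, with $D_i$ the inverse of a 4PL fit to
  monotherapy $i$; solved by bisection to $10^{-6}$ on the response scale,
  with non-bracketing dose pairs saturating at the nearer monotherapy
  asymptote (flagged);
* **ZIP**: the average of the two constrained "potency-shift" 4PL refits
  (combination response along one drug's axis with the floor pinned to the
  other drug's fitted effect) minus the Bliss expectation of the fitted
  monotherapy curves; rows/columns whose constrained fit fails fall back to
  observed values.

4PL fitting uses Levenberg-Marquardt least squares with quartile-based
initialization and box constraints (positive slope; asymptotes loosely
bounded), falling back to bounded quasi-Newton on non-convergence; fits on
noise-free 4PL curves recover generating parameters within 5%.

Significance is a replicate bootstrap: resample replicate readings per well,
recompute the mean synergy score, and report twice the (+1-corrected)
fraction of bootstrap means on the opposite side of zero, capped at 1. The
conventional 10 iterations are the default for fidelity to common practice,
with a warning that P-value resolution at n = 10 is coarse (the smallest
attainable value is 2/11); 1000+ iterations are recommended when runtime
allows. The bootstrap unit is the replicate reading — residual resampling
would be the alternative for single-replicate plates, which are rejected
with a pointer to that option. Mean scores of at least 5 points are called
synergistic (inclusive bound).

# Numerical and design choices

* Determinism: every stochastic stage takes an explicit seed and is
  bit-reproducible; the generator guarantees identical output for identical
  config + seed.
* Quantiles use R's default type-7 interpolation throughout; documented
  because quantile conventions differ across toolkits.
* The directional-correction candidate search hashes each label once per
  position (masking that position) instead of enumerating all label pairs,
  which keeps correction linear-ish in the label count; a brute-force
  Hamming-graph oracle in the test suite checks exact agreement on hundreds
  of random instances.
* Degenerate inputs are surfaced, not silently dropped: zero-variance genes
  get P = 1, kill fractions of 0 or 1 warn about degenerate fate partitions,
  empty signature variants raise an error naming the variant, single-replicate
  synergy plates are rejected with advice.
* Cross-arm label collisions are tolerated and handled per arm (the two
  arms' barcode pools overlap in the real design); the simulator assigns
  disjoint label sets per arm for clean ground truth.
* The number of treatment arms is a free parameter of the design: the
  generator produces one treatment plus one control arm, and every
  downstream function takes arms independently, so additional arms are a
  loop at the call site.

# Problem sizes used by the tests

The test-suite simulations are sized to run in minutes on one CPU while
retaining the power the checks need: fate/sister properties at 250-600
lineages and 400-500 genes; concordance calibration at 2000 lineages, 1000
genes and a mean depth of 20000 (about 500 two-cell pre-lineages, matching
the pair count at which power is assessed); signature recovery at 1500
lineages/arm and 2000 genes with a planted 200-gene resistance program of
effect 0.5; connectivity screens at 50 random drugs plus one planted
inverse over 400-2000 genes. Resampling defaults (1000 iterations) are
reduced to 100-500 in tests; P-value resolution remains far below the 0.05
thresholds being asserted.

# Known limitations

* The generator's clean regrowth model (survivors re-profiled once, no
  expansion bias) means post-treatment abundances carry no information;
  only label presence is used, as in the design being modeled.
* The Wilcoxon normal approximation is coarse in the extreme tail for group
  sizes below ~8; the exact-enumeration cross-check in the tests targets
  the moderate-P regime where the approximation is valid.
* ZIP's constrained refits need at least three nonzero doses per axis and
  degrade gracefully (observed-value fallback) on sparse grids.
* Connectivity P-values permute the drug profile's gene labels; they test
  the null of exchangeable gene assignments, not a cell-line-specific
  touchstone null.
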