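---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `switchmir`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where more than one
reasonable option existed.

## The analysis model

The package analyses two paired studies — an in vitro differentiation time
course and an in vivo developmental time course — each profiled for mRNAs
and miRNAs on a log2 intensity scale with replicated samples at a small
number of days (three replicates at five days is the regime the defaults
assume). All screening statistics operate on **day-mean profiles**: the
per-day averages of replicate log2 values, so a profile has as many entries
as the study has time points.

### Expression floor

A feature counts as expressed when its day-mean log2 intensity strictly
exceeds the floor (default 5, log2 units) at one or more time points.
Applying the floor to day means rather than single replicates makes the
filter robust to one noisy replicate; the strict inequality makes the
boundary case reproducible. Both the floor and, via `collapse_probes()`,
the probe-collapsing rule sit upstream of every other stage.

Probe collapsing keeps, per mapped feature, the probe with the highest mean
log2 intensity over all samples (ties broken by probe id). The rule is
deterministic and robust to dropout of an individual probe; a per-sample
maximum would weave probes together and was rejected for that reason.

### Peak detection

A miRNA "genetic switch" candidate is a profile that is high at exactly one
day and at baseline elsewhere. Each profile is correlated (Pearson) with the
one-hot template for every day; the template for day *i* of *n* has a 1 at
position *i* and 0 elsewhere. Properties that matter:

* the score is invariant to positive affine transforms of the profile, so
  absolute expression level does not influence the call;
* the templates are mutually negatively correlated at exactly −1/(n−1);
* each miRNA receives at most one peak day (the argmax; ties go to the
  earliest day and are logged), because the analysis treats per-day peak
  groups as disjoint.

Calls require r ≥ `peak_r_min` (default 0.6). Constant profiles have no
defined correlation and are skipped with a warning rather than erroring, so
batch runs survive degenerate features.

**Day-mean vs replicate-level correlation.** By default the template has
length equal to the number of days and is correlated with the day-mean
profile. A replicate-level mode (template value repeated across a day's
replicates) is available by passing `expression_long()` output to
`call_peaks()` (pipeline option `peak_level = "replicate"`). The two modes
differ sharply in their null behaviour: Pearson r is scale-free, so a flat
miRNA's day-mean profile is pure noise, and with five days the null
distribution of r (df = 3) puts ≈ 14% of mass above 0.6 per template —
flat miRNAs are then called frequently no matter how small the noise is.
At replicate level (15 observations, df = 13) the same threshold has a
null tail below 1% per template. The planted-recovery benchmark in the
test suite therefore runs at replicate level, where a low false-call rate
is achievable; the day-mean default is kept for the main pipeline because
it matches the length-of-time-series template definition, with the caveat
that its calls should be read as shape matches, not significance
statements.

### Differential expression

Each non-reference day is contrasted with the day-0 reference per feature
using a moderated two-sample t: the feature's pooled residual variance s²
(d = nₐ + n_b − 2 df) is shrunk towards a prior s₀² carrying d₀ prior df,

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},\qquad
t = \frac{\Delta\bar x}{\tilde s\sqrt{1/n_a + 1/n_b}},\qquad
\mathrm{df} = d + d_0 ,$$

with d₀ = 0 reducing exactly to the ordinary pooled t and d₀ = ∞ fixing
the variance at s₀². The hyperparameters are estimated per contrast by
method of moments on the log sample variances: with
e = log s² − ψ(d/2) + log(d/2), the excess of var(e) over ψ′(d/2)
identifies d₀ through the inverse trigamma function (solved by Newton
iteration), and mean(e) identifies s₀². Two degenerate branches matter:

* literally identical variances (no sampling scatter at all, as in
  noiseless fixtures) give d₀ = ∞ with s₀² equal to the common value;
* scatter no larger than χ² sampling of one common variance alone explains
  gives d₀ = ∞ with s₀² = exp(mean(e)) — the bias-corrected log-scale
  estimate. Using the raw geometric mean of s² here would under-estimate
  the variance by exp(ψ(d/2) − log(d/2)) (≈ 24% at d = 4) and inflate the
  far tail of the statistic; the correction keeps the null calibrated.

P-values are adjusted per contrast with the Benjamini–Hochberg step-up
rule (own implementation, cross-checked against `p.adjust` in the tests),
and a feature-day is flagged when adjusted p < 10⁻⁵ **and** |log2FC| > 2.
Both inequalities are strict by default and both thresholds and the
strictness are configurable — the analysis convention this follows states
the rule once with strict and once with non-strict wording, so the choice
is deliberately config-neutralised. With exactly replicated values (zero
variance and zero difference) the statistic is defined as a sure null
(t = 0, p = 1); zero variance with a non-zero difference and no prior is
an error for the scalar API and a sure call (p → 0) in the vectorised
pipeline, where the infinite statistic is meaningful.

### Interaction screening and conservation

Candidate miRNA→target tables from several resources (five by default in
the simulator; the last carries experimental evidence) are merged by set
union over (miRNA, gene) pairs, keeping the union of source names and the
strongest evidence class. Merging is associative, commutative and
idempotent. Records whose miRNA or target fails the expression floor are
discarded per study.

Each surviving pair is annotated with Kendall's τ (tau-b) between the
miRNA and target day-mean profiles, computed by exact enumeration of all
n(n−1)/2 pairs with the tie-corrected denominator
√((C+D+Tx)(C+D+Ty)); profiles are short, so the quadratic enumeration is
exact and cheap, and rank correlation is preferred over Pearson for
robustness on five-point profiles. Fully tied vectors have no defined τ
and are skipped with a count message.

Conservation filtering intersects the two studies' annotated pairs, keeps
pairs targeting a designated gene set (a heart-development term's
descendant-closure gene list, supplied as a file — never fetched at run
time), and selects pairs with τ < −0.2 in both studies and
|τ_vitro − τ_vivo| < 0.2. miRNAs are ranked by number of conserved
targets, with the count of targeted transcriptional regulators reported as
a proxy for downstream regulatory reach.

**Boundary semantics.** On an n-day profile without ties τ lies on a
discrete grid (steps of 0.2 at n = 5), so "strictly below the threshold"
meets exact boundary cases routinely. Floating-point representation breaks
these comparisons: |(−0.4) − (−0.6)| evaluates below 0.2 in doubles, which
would leak exact-boundary pairs through a naive `<`. The strict filters
therefore treat values within 10⁻⁸ of a threshold as equal to it. The
guard changes nothing for continuous real data and makes the grid case
exact. Whether the conservation band should be < or ≤ is itself
config-exposed (`strict`), with strict as the default reading of a
"maximal threshold" of 0.2.

### Conditioned enrichment

Ontology terms form a DAG (child→parent edges, multiple parents allowed);
annotations are closed under the true-path rule (a gene annotated to a
term is annotated to all its ancestors). Over-representation of a selected
gene set is tested per term with the upper-tail hypergeometric probability
P(X ≥ k), summed from exact terms on the log-binomial scale. To suppress
cascades of significant ancestors that merely inherit one specific term's
signal, terms are processed children before parents, and when a term is
tested, the gene content of its already-significant immediate children
(conditioned p ≤ 0.01, non-strict) is excluded from the term's gene set,
the selection and the universe — for that test only; nothing is removed
globally. Leaves, and parents without significant children, reduce exactly
to the unconditional test. Results are invariant to which valid
reverse-topological order is used (asserted in the tests by evaluating two
orders). The default universe is every gene in at least one propagated
annotation — standard over-representation practice when the selection
derives from expressed genes — and can be overridden with the full array
universe.

## The synthetic-data generator

`simulate_study_pair()` emulates the statistical structure the analysis
assumes, with planted, machine-readable truth:

* flat per-feature baselines drawn uniformly from `baseline_range`
  (default [3, 12] log2 units, an RMA-like intensity range);
* single-day additive peaks of `peak_amplitude` (default 4 log2 units,
  a 16-fold induction) for a configurable fraction of miRNAs per day, at
  the same day index in both studies;
* repression: miRNAs engaged in true interactions follow a monotone ramp
  of height `peak_amplitude`, centred on their baseline (so their maximum
  stays above the detection floor for any baseline above the range
  minimum — planted features must be detectable for recovery benchmarks to
  measure the method rather than the filter), and each target's day-mean
  profile equals its baseline minus `repression_beta` times the centred
  miRNA profile. Repression acts on profiles; i.i.d. Gaussian noise
  (`noise_sd`, default 0.3 log2 units) is added per sample afterwards, so
  replicate scatter sits on top of the planted structure;
* `frac_conserved` of true interactions are planted identically in both
  studies, the rest in one study only;
* decoy interactions pair random miRNAs with genes that no true
  interaction targets. Restricting decoy genes to untargeted genes is
  deliberate: a decoy sharing a gene genuinely repressed by another miRNA
  could be truly anti-correlated, which would corrupt the precision
  denominator the decoys exist to provide (and, in noiseless fixtures,
  untargeted genes are constant and drop out as undefined correlations,
  making planted-truth recovery exact);
* resources include each candidate independently with probability
  `resource_coverage`; the ontology plants one term annotating exactly the
  "cardiac" gene set (all target genes plus a random tenth of the rest)
  under a single root, plus filler terms with random annotations and
  occasional double parents.

The in vivo day grid defaults to embryonic days 10.5–18.5 — a plausible
fetal heart development window — and is free configuration, since the two
studies never need to share a grid (each study's correlations use its own
profiles). All randomness flows from one integer seed; identical
configurations yield identical fixtures, byte-for-byte when written.

What the generator does **not** emulate: probe-level data, normalisation
artefacts, batch or array effects, correlated noise, heteroscedastic
intensity-dependent variance, secondary regulation (targets responding to
more than one miRNA), or cellular heterogeneity. Passing recovery
benchmarks on these fixtures therefore shows the chain is correct and
calibrated under its own model assumptions — not that real-array effect
sizes or database error rates match.

## Test and benchmark scale

The suite exercises the stages at sizes chosen to keep a full run in the
order of a minute or two while leaving the statistics meaningful: peak
recovery on 200 miRNAs (20 planted per day, amplitude 4, noise 0.3, three
replicates) averaged over 10 seeds; conserved-interaction recovery on 50
planted pairs plus 500 decoys over 600 genes and 150 miRNAs, averaged over
20 seeds; null differential-expression calibration on 5000 features
(3 vs 3) over 400 seeds — enough that the Monte-Carlo error of the mean
false-discovery proportion is small relative to the 0.05 bound it is
compared against; enrichment calibration pooled over 10⁴ term-tests.
Oracle-equivalence checks (brute-force Kendall, sum-formula Pearson,
enumerated hypergeometric tails, pooled-t reduction) run at tolerance
10⁻¹² or exact identity.

## Known limitations

* Day-mean peak calling carries no significance control (see above); use
  replicate-level mode when a bounded false-call rate matters.
* The moderated-t stage fits each day-vs-reference contrast separately
  rather than one linear model across all days; for this contrast
  structure the results coincide, but shared-variance information across
  contrasts is not pooled.
* Conditioning uses immediate children only (the standard parent–child
  algorithm); a significant grandchild shields its parent, and the parent
  in turn its own parent, but no global decorrelation of the DAG is
  attempted, and no multiplicity correction is applied across terms (the
  conditioned raw p is reported).
* Cross-study identity is by shared identifiers; no orthology mapping.
* Per-resource confidence filtering is reduced to an optional score
  threshold in the reader; resource-specific recommended cut-offs must be
  applied upstream.
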