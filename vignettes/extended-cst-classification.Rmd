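---
title: "Extended community state types: the model, its parameters and the synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended community state types: the model, its parameters and the synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagcst)
```

## The classification model

`vagcst` assigns each vaginal microbiome sample — a relative-abundance
vector over canonical taxa, summing to 1 — to one of twelve extended
community state types by a dominance rule. Writing $r$ for the maximum
relative abundance in the sample and $t$ for the dominance threshold
(default $t = 0.5$, inclusive):

* $r \ge t$ with the top taxon among the four canonical species
  *Lactobacillus crispatus*, *L. gasseri*, *L. iners*, *L. jensenii* gives
  the classic CST I, II, III or V;
* $r \ge t$ with *Gardnerella vaginalis*, a *Prevotella*-group taxon, or a
  THPP-group taxon on top gives CST VI, VII or VIII;
* $r \ge t$ with any other taxon on top gives CST IX;
* $r < t$ gives the polymicrobial CST IV, subtyped by the identity of the
  (sub-threshold) top taxon: IV-A for *G. vaginalis*, IV-B for
  *Prevotella*, IV-C for everything else — including a sub-threshold
  *Lactobacillus*.

The model's assumptions are those of the scheme itself: that dominance of a
single organism at half the community is the biologically meaningful
boundary between a named state and a polymicrobial one, and that taxon
identity at the working rank (species for *Lactobacillus* and
*G. vaginalis*, genus elsewhere) carries the relevant signal. The species
split for *Lactobacillus* is not optional — CST I and III are
distinguishable only below genus rank, so a genus-aggregated
*Lactobacillus* entry is never used for the dominance test; if such an
aggregate tops a sample at $\ge t$ the classifier reports `UNRESOLVED`
rather than guess among I/II/III/V. The same label is used for a dominant
non-canonical *Lactobacillus* species (e.g. *L. salivarius*), with a
configuration switch (`fold_unresolved_into`) for users who prefer to fold
these into another state.

Two boundary conventions required a decision. First, the threshold is
inclusive: a top taxon at exactly 50% dominates. The source descriptions
state dominance as "equal or greater than 50%" and the IV subtypes as
"RA < 50%", which is consistent only with the inclusive reading; one
published subtype note mentions *Prevotella* "RA ≤ 45%", which we treat as
an empirical observation about the observed clusters rather than a rule
boundary — the uniform $< 50\%$ cut applies to every IV subtype. Second,
exact ties at the maximum (a measure-zero event in real data, but tests
exercise it) break deterministically by group priority — LACTOBACILLUS >
GARDNERELLA > PREVOTELLA > THPP > OTHER, then alphabetically — and the tie
is recorded in the assignment rationale. One published cluster range
(*G. vaginalis* 25–45% with *L. iners* 37–44%) admits compositions whose
argmax is *L. iners*, which the strict argmax rule files under IV-C rather
than IV-A; we follow the stated argmax definition and note the discrepancy
here. The CST IV total is unaffected.

## The taxon registry

All nomenclature flows through a registry of canonical names, working
ranks and five disjoint functional groups (LACTOBACILLUS, GARDNERELLA,
PREVOTELLA, THPP, OTHER — the last an implicit complement). Synonym
resolution is case-, whitespace-, underscore- and dash-insensitive and
folds species labels to their working rank, so `"Shuttleworthia"`, `BVAB1`
and *Candidatus Lachnocurva vaginae* are one taxon, and `"Escherichia"` and
`"Shigella"` both resolve to the merged amplicon-taxonomy genus
*Escherichia-Shigella*. The default THPP panel carries the genera nameable
from the main published text (*Campylobacter*, *Chlamydia*,
*Enterococcus*, *Escherichia-Shigella*, *Haemophilus*, *Mycoplasma*,
*Neisseria*, *Peptostreptococcus*, *Staphylococcus*, *Streptococcus*,
*Ureaplasma*); the published panel is larger (32 taxa) but enumerated only
in supplementary material, so the registry file format
(`read_taxon_registry`/`write_taxon_registry`, plain TSV) lets users supply
the full panel. *Peptostreptococcus* is THPP for classification purposes —
it is THPP-dominant in one reference cluster — while the panel-total
operation takes an explicit taxon list, so the narrower six-genus
convention used for the published 5.24% overall THPP abundance remains
expressible.

## Summaries, diversity and tests

`group_mean_profile` computes per-cohort arithmetic mean profiles; the
"overall" profile is the *unweighted* mean of the cohort means, because
that is the only convention consistent with the published overall
*Lactobacillus* figure (47.9 = mean of 91.8, 26.1, 45.0, 34.4, 42.4); the
pooled per-sample mean is available as an option. Rarefaction subsamples
counts without replacement (multivariate hypergeometric, delegated to
`vegan::rrarefy`) at a default depth of 80,000 reads, the depth of the
amplicon pipeline this package mirrors; samples below depth are dropped
with a warning. Whether to rarefy before or after computing summaries is
left to the caller — `run_pipeline` rarefies first, but both orders are
reachable through the API.

Alpha diversity is the Shannon index, base 2 by default (bits, the
convention of the mirrored pipeline), with natural log exposed. Beta
diversity is Bray–Curtis, $BC(x,y) = 1 - \sum_i \min(x_i, y_i)$ for
normalized vectors — a semimetric, so no triangle inequality is asserted
anywhere. The published text also used unweighted UniFrac, which requires a
phylogeny and is out of scope here; Bray–Curtis is the implemented beta
metric. Group comparisons follow the published battery: a global plus
pairwise Kruskal–Wallis tests (Benjamini–Hochberg adjusted across pairs —
the source reports pairwise p-values without naming a correction, and BH is
the field default) and one-way PERMANOVA with freely permuted labels,
$p = (1 + \#\{F^{perm} \ge F^{obs}\})/(1 + n_{perm})$, default 999
permutations (minimum attainable $p = 0.001$), seeded.

The correlation workflow gates the method per pair: Shapiro–Wilk on each
variable at $\alpha = 0.05$, Pearson only if both pass, Spearman otherwise
(the published analyses alternate between $r$ and $r_s$ for the same pairs;
making the gate data-driven, with a manual override, is the reproducible
version of that practice). Confidence intervals are Fisher-z for Pearson
and a seeded 2,000-resample bootstrap for Spearman, whose CI method the
source does not state. Strength bands follow the published caption: strong
$|r| \ge 0.50$, moderate $0.30$–$0.49$, weak below.

## The synthetic cohorts

The published raw data live in sequence archives and are deliberately not
required. Two generators stand in for them.

**Constraint fixtures.** Each published cluster description
("*L. gasseri*-dominant 52%, *L. iners* 43%", "*G. vaginalis* 25–45%", ...)
is encoded as numeric assertions on taxon percentages: exact values are
honoured verbatim, bounds are drawn inside their ranges (reserving later
assertions' lower bounds so the total can never exceed 100%), and the
unclaimed remainder is spread over a pool of heterogeneous low-abundance
taxa, each capped below 7% — the published definition of "heterogeneous
bacteria". Descriptions stated relationally ("*G. vaginalis* more abundant
than *Prevotella*, *Atopobium*, ...") are translated at authoring time into
ranges that preserve the stated dominance order (dominant 30–45%,
companions 3–12%); one range pair that would otherwise let the companion
overtake the dominant is narrowed within its published bounds. The built-in
set realizes all 151 samples of the five-cohort reference study; the
fixtures carry no labels, so the published CST tallies (56 IV, 38 III, 33
I, 9 VIII, 7 IX, 6 VI, 1 VII, 1 II) are genuine classifier output, and they
are invariant to the seed because every admissible draw satisfies the same
rule clause. An unsatisfiable constraint (lower bounds over 100%, or a
remainder exceeding the pool's capacity) fails with the violated bound
named.

**Dirichlet-multinomial cohorts.** `simulate_cohort` draws, per sample: a
CST from its cohort's frequency vector; a composition from
$\mathrm{Dirichlet}(c \cdot \pi_{CST})$ around that CST's archetype mean
$\pi$; a read depth from a negative binomial (default mean $10^5$,
dispersion 10); and counts from a multinomial at that depth. This is the
minimal standard generative model carrying the structure the analysis
assumes — single-taxon dominance, heterogeneous tails, count noise. The
default concentration $c = 50$ puts the dominant taxon's standard deviation
near 0.05, comparable to the within-cluster spread of the published
descriptions. Archetype dominant-taxon means sit mid-range of the published
cluster ranges (e.g. CST I *L. crispatus* 0.85, CST IV-A *G. vaginalis*
0.35, CST VIII *Streptococcus* 0.65); each archetype's mean profile
classifies as its own CST. The default cohort specification reuses the
reference study's design: five cohorts of 28, 18, 36, 31 and 38 samples
with the observed per-cohort CST frequencies.

What the generator does *not* emulate: sequencing error and chimeras,
taxonomic misassignment, the long tail of hundreds of rare taxa (the
archetypes span ~30 taxa), compositional correlation beyond the mixture
structure, and longitudinal CST transitions. Passing recovery and
calibration tests therefore demonstrates that the pipeline's statistics are
correct under a well-specified community model — not that classification of
real amplicon data is 95% accurate; real-data accuracy depends on upstream
denoising and taxonomy quality that this package does not model.

## Numerical choices and degenerate inputs

Compositions must sum to 1 within $10^{-6}$ (classifier input) and table
rows within $10^{-9}$ (generator output); relative-mode detection on read
accepts rows near 1 or near 100 (percentages), with an explicit `mode`
override for truncated top-$N$ tables whose rows sum below 100 — the
shipped five-cohort mean table is read that way, undistorted, rather than
renormalized. Zero abundances contribute nothing to Shannon diversity (the
$p \log p$ limit), constant vectors are rejected by the correlation
workflow (normality and correlation are undefined), zero-total samples are
rejected by normalization with the sample named, and an empty cohort
classifies to an empty assignment table. All stochastic entry points take
an explicit seed and restore the caller's RNG state; pipeline outputs carry
no timestamps, so a rerun with the same inputs, configuration and seed is
byte-identical.

## Test problem sizes

The suite exercises the heavy statistical properties at sizes chosen to
make sampling error negligible relative to the tolerances while keeping a
full run under a minute on one core: rule-table equivalence against a
brute-force evaluator on 10,000 random compositions; rarefaction
unbiasedness over 500 replicate draws (3-sigma band); Kruskal–Wallis and
PERMANOVA type-I error over 500 simulated null datasets each (acceptance
band 3–7% at $\alpha = 0.05$); Fisher-z CI coverage over 500 bivariate
normal datasets at true $\rho = 0.5$ (band 93–97%); and CST label recovery
on a 500-sample default-concentration cohort (threshold 95%; the observed
rate is about 99%).

## Known limitations

The classifier is a rule table, not a nearest-centroid model: it will not
reproduce centroid-based reference classifications where those disagree
with argmax dominance. Correlations are computed on relative abundances and
inherit the usual compositional caveats (negative bias among the largest
components);
compositionality-aware estimators are out of scope, as in the source
analyses. The default THPP panel is the main-text subset of the full
published panel. And because Bray–Curtis replaces unweighted UniFrac,
beta-diversity p-values are comparable in kind but not numerically
portable to tree-based analyses.
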