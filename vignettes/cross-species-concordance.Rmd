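---
title: "Cross-species concordance analysis of injury transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species concordance analysis of injury transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xsci)
library(dplyr)
```

## The problem

Animal models of traumatic spinal cord injury respond to the insult with
large transcriptional programs, but those programs are not the same across
species. Rodents scar; salamanders (axolotls) regenerate. A gene whose
injury response points the same way in rats, mice, and salamanders is a
candidate for therapies that should translate across models; a gene whose
response flips sign only in the regenerating species is a candidate
regeneration switch. `xsci` implements the complete comparison as a
reusable, testable pipeline: per-study differential expression, ortholog
harmonization onto a reference organism, direction-of-expression
classification, gene-set over-representation, sequence-conservation
analysis, interaction-network filtering, and immunostain quantification —
all exercisable on synthetic data with known planted structure, so that
every stage has a ground truth.

## Per-study differential expression

Each study is a small two-arm (injured vs. control) microarray experiment
on the log2 scale, already RMA/gcRMA-normalized; `xsci` performs no
normalization. With 3–4 replicates per arm, per-probeset variance
estimates are unstable, so `fit_moderated_t()` uses the empirical-Bayes
moderated t-statistic: the pooled residual variance $s_g^2$ of probeset
$g$ (on $d = n_1 + n_2 - 2$ degrees of freedom) is shrunk toward a prior
$s_0^2$ carrying $d_0$ prior degrees of freedom,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
t_g = \frac{\overline{x}_{g,\mathrm{inj}} - \overline{x}_{g,\mathrm{ctl}}}
          {\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

referred to a Student $t$ on $d_0 + d$ degrees of freedom. The
hyperparameters are estimated by moment-matching on $\log s_g^2$: under
the scaled-$\chi^2$ model the excess of $\mathrm{var}(\log s_g^2)$ over
$\psi'(d/2)$ identifies $d_0$ through a Newton inversion of the trigamma
function, and the mean identifies $s_0^2$. When the observed variances
show no excess dispersion the estimate is $d_0 = \infty$; every posterior
variance then collapses to the common $s_0^2$ and the statistic becomes a
pooled-variance (z-like) test, which is logged. This machinery is
implemented in the package itself — the test suite cross-checks the prior
estimates and statistics against limma to $10^{-8}$ on a heteroscedastic
simulation, but limma is never used as the implementation, because the
pipeline needs knobs it does not expose (pinned priors for validation,
explicit infinite-$d_0$ behaviour, confidence intervals on the posterior
scale).

Fold-changes are oriented injured minus control, so "upregulated after
injury" means $\log_2\mathrm{FC} > 0$. Two-sided p-values are adjusted by
Benjamini–Hochberg (`benjamini_hochberg()`, a validated wrapper over the
standard step-up). Confidence intervals are computed at 95% from the same
posterior scale; the moderated rather than the ordinary standard error is
used, which is the natural choice once the posterior variance is the
object of inference. Probesets mapping to the same gene are collapsed by
`collapse_probesets()`: the probeset with the highest average expression
represents the gene, ties broken by smallest probeset id so the result is
deterministic; probesets with no gene annotation are dropped with a
logged count (keeping them would leave the gene table undefined).

## Ortholog harmonization and concordance classification

`map_to_reference()` resolves each species' gene symbols to
reference-organism (mouse) orthologs using a ranked mapping table,
keeping the rank-1 candidate per source gene. Salamander annotations are
keyed to human orthologs, so they are resolved through a two-hop chain
(salamander → human → mouse), each hop taking rank 1. When two source
genes collide on one reference gene within a study, the record with the
smaller adjusted p represents it; each collision is logged. Symbol case
is preserved up to this point; the ortholog table is the single place
where species are put on a common key.

`intersect_and_classify()` applies two gates in order: an ortholog must
be *present in every species* (species-level gate), and is flagged
significant only if its adjusted p is at or below `alpha` (default 0.05)
in *every study* (study-level gate — with two rat studies these are
different conditions, and both are applied). Significant orthologs are
classified by the sign pattern of their fold-changes:

* **consistent** — one nonzero sign in all studies;
* **opposite_outgroup** — all non-outgroup studies share one nonzero sign
  and every outgroup (salamander) study has the opposite sign;
* **other** — everything else, including any zero fold-change (no
  direction) and within-species disagreement between the two rat studies.

The three classes partition the significant set by construction, and
`partition_summary()` asserts that identity on every run. Over the 16
possible sign patterns of four studies, exactly 2 are consistent (all up,
all down), 2 are opposite (rodents up/salamander down and its mirror),
and 12 are other; this enumeration is a frozen fixture in the tests.

## Over-representation and enrichment scores

`hypergeom_enrich()` tests a query class (e.g. the consistent orthologs)
against GMT gene sets with the hypergeometric upper tail
$P(X \ge k)$ for overlap $k$, set size $K$, query size $n$, universe $N$,
adjusting by Benjamini–Hochberg within each namespace and reporting the
enrichment score $\mathrm{ES} = -\log_{10}(p_\mathrm{adj})$. Two design
choices are deliberate. First, BH is used for the gene-set adjustment;
web services in this space default to their own bespoke corrections, but
BH is reproducible from first principles and is the procedure used for
the differential-expression stage, so one method serves both (the output
metadata records this). Second, the default universe is the set of
orthologs present in all species after mapping — the background actually
tested — and is configurable, since published analyses rarely state
their background. Enrichment runs separately on the consistent and
opposite classes. `top_k_by_namespace()` selects the top terms per
namespace (ties by larger overlap, then term id) and reports per-namespace
query coverage.

## Sequence conservation

`percent_identity()` computes, per taxon against a reference, identical
columns over comparable columns × 100, where comparable excludes columns
gapped in either sequence (terminal and internal gaps alike); the
ambiguity code `X` counts as a comparable mismatch. Identity here is
defined on the *given* alignment: BLAST-style local identities will agree
only approximately, so printed identities from local alignments are
matched qualitatively, not digit-for-digit. `poisson_distance()` uses
pairwise deletion — for each pair, columns with a gap or `X` in either
member are removed — and applies the Poisson correction
$d = -\ln(1 - p)$, in expected substitutions per site; $p \ge 1$ is an
error rather than a silent infinity. `neighbor_joining()` is the classic
Saitou–Nei agglomeration, exact on additive matrices. Two details are
fixed for determinism: ties in the $Q$ criterion are broken by the
lexicographically smallest taxon pair (internal nodes are labelled by the
smallest leaf beneath them), since reference implementations do not
document their tie-breaking; and negative branch lengths are clamped to
zero with the deficit logged. Isoform selection (`longest_isoforms()`)
keeps the longest record per gene, ties by record id.

For heatmap presentation, `order_for_heatmap()` clusters species columns
by average-linkage hierarchical clustering under $1 - \cos$ dissimilarity
and groups gene rows by spherical k-means (k-means on L2-normalized rows
with normalized-mean centroids — the standard realization of "one minus
cosine" k-means), default $k = 4$, 10 seeded restarts keeping the best
inertia. All-zero rows have no direction under cosine; they are assigned
a sentinel cluster 0 and logged rather than erroring.

## Interactome filtering

`filter_network()` keeps edges at or above the confidence cut-off
(default 0.4, the conventional "medium confidence" value, applied
inclusively) whose endpoints are both in the query class, removes
singletons, and orders nodes by descending degree with lexicographic
ties — the ordering a degree-sorted circular layout uses. Self-loops and
duplicate undirected edges are normalized away at read time with logged
counts. No layout or community detection is attempted.

## Immunostain quantification

`area_fraction()` thresholds a grayscale image (pixels ≥ threshold are
stained), with Otsu's method as the default threshold because it is
deterministic and parameter-free — published workflows rarely report
their manual threshold, and a numeric override is available.
`two_way_anova_holm_sidak()` fits `area_fraction ~ group * region` with
Type II sums of squares (identical to the balanced decomposition when
cell sizes are equal, and the sensible default for mildly unbalanced
cohorts such as 5 injured vs. 3 sham animals), then tests the group
contrast within each region using the pooled residual error and adjusts
across regions by the Holm–Šídák step-down
$\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1}$ with running-max
monotonicity. Cells with fewer than two observations are rejected with
the offending cell named.

## What the synthetic generator emulates — and what it does not

`simulate_studies()` reproduces the *structure* of a four-study,
three-species comparison: two rat studies (4/4 and 3/3 replicates per
arm), one mouse study (3/3), one salamander study (3/3), matching the
published designs at the early subacute time point. Planted-consistent
genes receive the injury effect in every study; planted-opposite genes
receive it in rodents and its negative in the salamander; null genes
receive nothing. Each gene gets 1–3 probesets per study sharing the gene
signal with independent Gaussian noise, and one probeset per gene carries
an elevated baseline so the collapsing rule has a known winner. The
ortholog table is emitted with the chained salamander mapping, optional
per-hop dropout, and rank-2 decoys so the rank-1 rule is exercised.
Defaults: effect 2.0 log2 units, noise SD 0.5 log2 units (a clear but not
trivial signal for n = 3–4 per arm), 10% consistent, 10% opposite,
dropout 0 (so planted truth and recoverable truth coincide; raise it to
emulate incomplete ortholog tables).

The noise model is i.i.d. Gaussian on the log2 scale — the standard
post-RMA assumption — with equal variance across genes. Real microarray
data have mean-variance trends, batch effects, correlated probes, and
cross-hybridization; none of these are simulated. Passing the planted
recovery tests therefore demonstrates that the pipeline's logic is
correct and calibrated under its stated model, not that real studies
would yield any particular count. Real headline counts depend on the four
archived datasets, which this package deliberately does not download; a
loader for on-disk tables (`run_config(paths = ...)`) marks where such an
adapter would plug in.

`simulate_alignment()` evolves amino-acid sites as i.i.d. Poisson
substitution processes along a Newick tree (each event replaces the
residue with a uniformly chosen different one), with no indels, so the
Poisson-corrected distance is the matched estimator up to multiple-hit
saturation. Zero-length branches are legal (a star tree yields identical
sequences); negative lengths are rejected. `simulate_image()` plants an
exact foreground pixel count at `round(fraction × pixels)` with intensity
bands (0.65–0.95 vs. 0.05–0.35) that any mid-range threshold separates,
so area-fraction recovery is exact by construction.

## Reproducibility, problem sizes, and numerical choices

Every stochastic function takes an explicit seed and restores the
caller's RNG state; identical configurations give byte-identical outputs,
and the pipeline derives a named substream per stage from one top-level
seed. The validation runs use 500 genes × 4 studies for partition
recovery, 200 probesets for the null calibration of the moderated t,
5000-site alignments over 6 taxa for topology recovery (20 seeds), and a
few hundred ANOVA null simulations — sizes chosen so each check has
clear statistical resolution while the whole suite runs in well under a
minute per stage. Tolerances follow the quantity: exact assertions where
the result is forced (collapsing winners, sign-pattern counts, additive
NJ), binomial 99% bounds for calibration rates, and ±10–20% for planted
count recovery.

Degenerate inputs are errors, not warnings: all-constant expression
matrices, alignments with no comparable columns, saturated distances
($p \ge 1$), empty ANOVA cells, and queries outside the enrichment
universe all abort with named offenders. Quantities that must be clamped
(zero adjusted p-values before $-\log_{10}$, negative NJ branches) are
clamped with a logged record rather than silently.

## Known limitations

* Identity percentages are alignment-based, not BLAST-based; agreement
  with local-alignment identities is approximate by design.
* The enrichment stage's BH adjustment will not reproduce p-values from
  services using bespoke multiple-testing corrections, though rankings
  are typically unchanged.
* Only two-arm, single-time-point designs are supported — no
  multi-factor or time-course modelling, no array quality weights.
* The generator does not simulate batch effects, mean-variance trends,
  or indels; conclusions from synthetic runs are about pipeline
  correctness, not biology.
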