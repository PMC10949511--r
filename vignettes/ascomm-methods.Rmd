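---
title: "Methods: community ecology of activated-sludge microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community ecology of activated-sludge microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascomm)
```

`ascomm` packages the statistical workflow used in multi-plant surveys of
activated-sludge (AS) bacterial communities: 16S OTU tables from several
wastewater treatment plants (WWTPs) sampled monthly are screened, rarefied,
and pushed through diversity analysis, Sloan neutral-model fitting,
consensus co-occurrence network inference, functional-guild accounting,
genome-sequenced-proportion ("microbial dark matter") statistics, and
redundancy analysis against operational parameters. Every stage is exposed
as a plain function over matrices and tibbles, and a seeded synthetic-data
module generates inputs with known ground truth so the whole pipeline is
testable without any sequencing data.

## Table handling

The central container is `otu_table()`, an integer taxa-by-samples matrix
with unique identifiers. Three screens mirror standard amplicon practice:

* `remove_singletons()` drops taxa whose total count over all samples is
  exactly one (a read-quality guard).
* `rarefy(depth = 25000)` subsamples each sample without replacement
  (multivariate hypergeometric) to a fixed depth; samples below the depth
  are dropped with a warning rather than left unrarefied, so the
  neutral-model community size `N` stays constant across samples. The
  alternative — leaving shallow samples untouched — would silently mix
  detection limits.
* `filter_by_mean_abundance(1e-4)` applies the network screen of taxa above
  0.01% mean relative abundance. All thresholds in the package
  (`>0.01%`, `>0.1%`, `>80%`) are strict inequalities.

## The Sloan neutral community model

For a taxon with metacommunity relative abundance $p$, the neutral model
says its abundance in a local community of $N$ individuals that receives
immigrants at rate $m$ is approximately
$\mathrm{Beta}(Nmp,\; Nm(1-p))$ at stationarity. Its expected occurrence
frequency across communities is therefore

$$F(p) \;=\; 1 - I_{d}\!\left(Nmp,\; Nm(1-p)\right),$$

with $I$ the regularized incomplete beta function and $d$ the detection
limit, classically one read, $d = 1/N$. `fit_ncm()` estimates $m$ by
bounded one-dimensional least squares (Brent-type search on
$(10^{-6}, 1]$, tolerance $10^{-8}$) of observed occupancies against
$F$, reports $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ over taxa, percentile
bootstrap confidence intervals from 1,000 resamples of taxa (the
regression's units), and a partition of taxa into those above, within, or
below a 95% band. The band is a Wilson score interval of $F(p_i)$ at the
realized sample count — a pragmatic choice; the literature shows such bands
without naming a formula. $R^2$ is the plain taxon-level
$1-\mathrm{SSE}/\mathrm{SST}$; a binned generalized $R^2$ would give
different (usually higher) values, and the ambiguity is worth remembering
when comparing fits across papers.

### Detection through finite sequencing depth

A subtlety matters once occupancy is measured on sequenced reads. The
threshold form above asks whether the *latent* relative abundance $x$
exceeds $1/N$. But a taxon is *observed* when at least one of the $N$
reads hits it, an event of probability
$1 - \mathbb{E}\left[(1-x)^N\right]$ — for a Beta-distributed $x$, the
beta-binomial tail

$$F_{\text{reads}}(p) \;=\; 1 - \frac{B(Nmp,\; Nm(1-p) + N)}{B(Nmp,\; Nm(1-p))}.$$

The two agree as $N \to \infty$ but differ noticeably for rare taxa at
survey depths: at $x$ just below $1/N$ a read is still drawn with
probability approaching $1 - e^{-1}$, so read-measured occupancy exceeds
the threshold prediction and fitting the threshold form to read-sampled
data inflates $Nm$ by roughly 25–40% in our simulations. Both forms are
available via `predict_occurrence(..., detection =)` and
`fit_ncm(..., detection =)`: `"threshold"` (default) is the
field-standard Sloan fit, and `"reads"` is the consistent choice whenever
occupancy comes from finite-depth counts — in particular for tables drawn
from `simulate_neutral_community()`, whose final step is a multinomial
read draw. The parameter-recovery analyses in the test suite and
`scripts/acceptance.R` use `"reads"` for exactly this reason; recovered
medians then sit within a few percent of the generating $Nm$, versus a
systematic overshoot under the threshold form.

### The neutral simulator

`simulate_neutral_community()` draws metacommunity abundances from a
Fisher log-series (parameter 0.999 by default, leaving roughly half of a
3,000-taxon pool below the one-read detection limit at 25,000
reads/sample — the long tail typical of AS communities), then for each
sample draws a composition from $\mathrm{Dirichlet}(Nm\,p)$ — giving each
taxon the correct Beta marginal while closing the composition exactly —
and finally $N$ multinomial reads. The joint Dirichlet is a modelling
choice: the neutral theory specifies only marginals, and the Dirichlet is
the maximum-entropy way to satisfy them under closure. What the simulator
deliberately omits: taxon-taxon interactions, temporal autocorrelation
between monthly samples, PCR/copy-number bias, and overdispersion beyond
the neutral sampling itself. Passing neutral-recovery tests therefore says
the estimator is consistent under the model, not that real AS data are
neutral.

## Consensus co-occurrence networks

Per plant, two methods are run on the screened (>0.01%) table and
intersected:

1. `spearman_network()` — all pairwise Spearman coefficients (mid-ranks)
   on relative abundances, two-sided p-values from the t-approximation;
   a per-plant screen at $P<0.05$ and a stricter $P<0.01$ cut for the
   intersection step. No multiple-testing correction is applied by
   default, matching the raw thresholds used in the surveys this package
   follows; note the closure of relative abundances makes small-panel
   correlations structurally negative, another reason the conditional
   dependence method is run alongside.
2. `mb_network()` — neighborhood selection on CLR-transformed counts:
   each taxon's CLR profile is lasso-regressed on all others over a
   20-point log-spaced path from $\lambda_{\max}$ (the largest absolute
   covariance of the standardized CLR matrix) to $0.01\lambda_{\max}$,
   with the penalty chosen by StARS (50 subsamples of size
   $\lfloor 0.8\,n\rfloor$, instability threshold 0.05, OR-rule
   symmetrization, refit on the full data at the chosen penalty). These
   settings are pinned explicitly because "default settings" of graphical
   model software drift across versions. CLR profiles are standardized to
   unit variance before regression — the convention of
   neighborhood-selection implementations — which in our planted-graph
   checks lifts chain-recovery F1 from ~0.80 to ~0.88 and cuts null
   false-edges from ~2% to ~0.5%.

`cross_plant_consensus()` keeps pairs detected with the same sign in at
least two plants with at least one endpoint in the union of core taxa
(`core_taxa()`: above 0.1% abundance in more than 80% of samples) and
functional-guild members. Sign agreement and the one-endpoint rule are
choices the source surveys leave open; both are arguments
(`require_sign_agreement`, `endpoint_rule`) so the stricter readings are
one flag away. `network_stats()` reports Newman modularity via greedy
agglomeration on the unsigned graph.

## Functional guilds and dark matter

`extract_guilds()` matches lineage labels (case-insensitive, `Candidatus`
prefix normalized) against rank-level patterns for AOB, NOB, PAO, BFB and
anammox. The default pattern set encodes the genera and families named in
AS survey practice (Nitrosomonadaceae and its AOB genera; Nitrospira and
the other nitrite oxidizers; Ca. Accumulibacter and Tetrasphaera;
the common bulking/foaming genera; Ca. Brocadia) and is fully replaceable
via a YAML file, since published guild tables vary. Patterns above genus
rank only apply when the genus is unassigned or itself matches the same
guild, so a classified non-guild genus inside a guild-bearing family is
not swept in. `aob_nob_ratio()` flags groups with no NOB instead of
emitting infinities.

The dark-matter statistics treat a taxon as "genome-sequenced" when its
representative sequence matches a reference set. The exact criterion
(100% query coverage, 100% identity) is implemented as strand-aware exact
substring containment — equivalent to a BLAST hit at those thresholds but
dependency-free. The 97% criterion uses semi-global alignment (global in
the query, local in the reference, match +1 / mismatch −1 / gap −2), with
identity counted over alignment columns; coverage is query-relative since
genome-derived reference 16S regions are typically longer than the
amplicon. Ambiguity codes count as mismatches under both criteria —
conservative, and consistent with the exact criterion's definition.
`mdm_proportions()` then reports `P_number` (matched fraction of taxa) and
`P_abundance` (matched fraction of total relative abundance), per plant
and overall.

## Redundancy analysis

`rda()` is implemented from first principles (and cross-checked against
an independent implementation in the test suite): Hellinger-transformed,
column-centered community matrix projected onto the standardized
parameter matrix; canonical axes from the SVD of the fitted values;
constrained proportion $\|\hat Y\|_F^2 / \|Y\|_F^2$; marginal
per-parameter importance from single-variable fits (matching the "top
parameters" reading of survey figures; forward selection would answer a
different, conditional question); significance by permuting sample rows
of $X$ against pseudo-$F$ with 999 permutations. The Hellinger transform
is the default because raw abundance RDA lets total-abundance differences
dominate; it can be disabled. `param_taxon_correlation()` covers the
simple seasonal question — one parameter, one taxon, Spearman over time.

## Numerical and degenerate-input choices

* Rarefaction below depth drops the sample (never partial); all random
  stages take explicit integer seeds and restore the caller's RNG state.
* Zero-variance taxa are excluded from correlation and regression stages
  with a warning, not an error.
* PCoA reports negative eigenvalues untouched (no Lingoes/Cailliez
  correction) and returns coordinates only for positive axes.
* `log10` display transforms map zeros to missing values, never `-Inf`.
* Pielou evenness is undefined for one-taxon samples and reported as `NA`.
* Spearman p-values use the t-approximation throughout; with ties this is
  the conventional mid-rank treatment.

## Problem sizes used in the checks

The packaged checks run at the survey's stated design where that is cheap
(neutral-model recovery: 3,000 taxa × 13 samples × 25,000 reads, 20
replicates; network recovery: 50 taxa × 200 samples, 10 replicates;
permutation calibration: 200 replicate datasets of 200 samples) and at a
compact six-plant design (200 taxa, 2,000 reads/sample) for the
end-to-end determinism run, which exercises every stage twice and
compares outputs byte for byte.

## Known limitations

* The consensus-edge count of a real survey depends on upstream OTU
  processing that is out of scope here (read QC, clustering, taxonomy);
  the package reproduces the rules, not any particular published edge
  list.
* The neutral simulator's independence across samples understates the
  temporal correlation of monthly series; fitted $R^2$ on synthetic data
  is accordingly optimistic.
* Exact matching treats references as gold standard; chimeric or
  truncated references would inflate `P_number`.
* StARS instability is estimated from 50 subsamples; for tables with very
  few samples (the per-plant 13-sample case) the selected graph is
  conservative, which is the intended failure direction for a screen that
  feeds a cross-method intersection.
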