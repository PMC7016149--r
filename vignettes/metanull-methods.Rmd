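---
title: "Null-model inference of metacommunity assembly: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model inference of metacommunity assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metanull)
```

`metanull` infers community-assembly processes from site-by-OTU count
tables sampled repeatedly over time — the typical output of amplicon
surveys of connected habitat patches (rock pools, ponds, bromeliad
tanks). This vignette explains the statistical models behind each stage,
the parameters that matter, the synthetic data the package validates
itself against, and the design decisions taken where the methodological
literature leaves the choice open.

## The inferential problem

Community composition is shaped by four process families: *selection*
(deterministic filtering by the environment, either spatially variable
or homogeneous), *dispersal* (limiting or homogenizing), *drift*
(stochastic demographic change) and *historical contingency* (priority
effects, arrival order). None is observable directly; all must be
inferred from the imprint they leave on beta-diversity. Because each
class of null model is sensitive to a different imprint, the package
runs three complementary chains and then a disambiguation layer.

## Elements of metacommunity structure

The incidence matrix for one occasion is ordinated by reciprocal
averaging — rows and columns permuted by their first
correspondence-analysis axis scores, computed here directly from the
chi-square-standardized SVD. Three hierarchical tests follow.

**Coherence** counts *embedded absences*: zeros strictly inside the
first-to-last occurrence span of each species (column) and of each site
(row). Counting over both axes is the canonical choice; a column-only
mode exists (`countEmbeddedAbsences(mode = "columns")`) because some
descriptions only mention species ranges. The null is the
fixed-proportional `r1` model (site richness fixed exactly; species
drawn with probability proportional to occurrence frequency), and every
null matrix is re-ordinated before counting — an acknowledged
computational cost without which observed and null counts are not
comparable. With null mean $\mu$ and SD $\sigma$, the coherence z is
$(\mu - \mathrm{obs})/\sigma$, so a *deficit* of gaps (coherent
structure) is positive and a checkerboard-like excess is negative, with
$\pm 1.96$ as the two-tailed 5% threshold. p-values use the normal
approximation of the null (999 replicates by default; an exact
rank-based p is available via `exactP = TRUE`).

**Turnover** is computed on the range-filled matrix (embedded absences
set to present). For two species with filled ranges $R_1, R_2$ the
number of replacements is $|R_1 \setminus R_2|\cdot|R_2 \setminus
R_1|$, summed over species pairs. The null relocates each range block
uniformly along the ordered sites, preserving its length (the
Leibold–Mikkelson range-shift randomization — a deliberate convention
choice over `r1`, recorded in the result metadata). The turnover z is
$(\mathrm{obs} - \mu)/\sigma$: an observed count of zero (a perfectly
nested matrix) can only give $z \le 0$, so positive z means an excess
of replacements and negative z nested species loss. Note the sign
convention differs from coherence; both are documented in
`?EMSResult-class` because published software disagrees here.

**Boundary clumping** counts range boundaries per ordered site (each
filled range contributes its first and last site) and summarizes their
clustering with Morisita's index $I = S\sum b_i(b_i-1)/(B(B-1))$,
testing $b$ against uniformity with a chi-square test. $I > 1$ indicates
clumped boundaries, $I < 1$ over-dispersed ones.

`classifyMetacommunity()` maps the three tests onto the standard
hierarchy: negative coherence → checkerboard; non-significant →
random; positive coherence branches on turnover significance and sign
(nested species-loss variants vs Clementsian / Gleasonian / evenly
spaced, plus the quasi-variants when turnover is non-significant), with
Morisita's index deciding the boundary sub-type. The function is total:
every input receives exactly one label.

## Incidence Raup-Crick beta-diversity

For a site pair with richnesses $n_1, n_2$ and $SS_\mathrm{obs}$ shared
OTUs, each null replicate draws $n_1$ and $n_2$ OTUs without
replacement from the occasion's pool (all OTUs present at one or more
sites), with probability proportional to occurrence frequency, and

$$\beta_{RC} = 2\left(\frac{\#\{SS_\mathrm{null} > SS_\mathrm{obs}\} +
\tfrac12\#\{SS_\mathrm{null} = SS_\mathrm{obs}\}}{\mathrm{reps}}\right) - 1.$$

Ties at half weight match the published estimator; occurrence-frequency
weighting is the default and a uniform mode is kept for sensitivity
analysis (the classical unweighted formulation also has a closed
hypergeometric form, used in the test suite as an enumeration oracle).
Values near $-1$ flag deterministic convergence, near $+1$ deterministic
divergence; $\pm0.95$ is the conventional interpretation threshold
(`interpretBetaRC()`), used for reading individual values, not as a
hypothesis test. The per-occasion summary is the mean over all site
pairs.

## Quantitative process estimates

**Step 1 (phylogenetic null).** The abundance-weighted between-community
mean nearest-taxon distance is

$$\beta\mathrm{MNTD} = \tfrac12\Big[\sum_{i \in a} f_{ia}
\min_{j \in b} d_{ij} + \sum_{j \in b} f_{jb} \min_{i \in a}
d_{ij}\Big],$$

with $f$ within-site relative abundances and $d$ patristic distances
(with `weighted = FALSE` it reduces exactly to the unweighted mean
nearest-taxon distance). The null shuffles taxon identities across the
tips of the phylogeny — equivalently, permutes the labels of the
distance matrix — and $\beta\mathrm{NTI} = (\mathrm{obs} - \mu_\mathrm{null})
/\sigma_\mathrm{null}$. The tip-shuffle null was chosen over
within-pool abundance shuffles and is recorded in the output; both
observed and null statistics are computed by a small C++ kernel because
999 replicates over 120 site pairs is otherwise prohibitively slow in
interpreted code. Pairs whose null SD is numerically zero (e.g.
equidistant trees) are flagged `NA` and excluded from downstream
fractions, with their count reported.

**Step 2 (abundance null).** For pairs with $|\beta\mathrm{NTI}|\le2$,
each community is probabilistically reassembled: its observed richness
drawn without replacement with probability proportional to occurrence
frequency, one individual per drawn taxon, and the remaining observed
total distributed by sequential binomial (multinomial) draws
proportional to regional relative abundances — so richness and total
abundance are conserved exactly in every replicate, integer counts make
Bray-Curtis ties possible, and ties are half-weighted.
$\beta_{RC\mathrm{bray}}$ uses the same $[-1,1]$ scaling. The regional
pool is all sites of the same occasion.

**Classification.** $\beta\mathrm{NTI} > 2$ → variable selection;
$< -2$ → homogeneous selection; otherwise $\beta_{RC\mathrm{bray}} >
+0.95$ → dispersal limitation or historical contingency, $< -0.95$ →
homogenizing dispersal, else drift. The published rule uses strict
inequalities; values landing exactly on a threshold are assigned away
from selection and towards drift (the conservative side), which is
stated in `?classifyPairs`.

**Prerequisite.** QPE assumes phylogenetic distance carries niche
information. `phyloSignalTest()` computes abundance-weighted niche
values per OTU ($\mathrm{niche}_i = \sum_s (x_{is}/\sum_s x_{is})
E_s$), and a Mantel correlogram of niche distance against patristic
distance classes (progressive Bonferroni correction; number of classes
by Sturges' rule unless overridden). A significantly positive shortest
class declares signal.

## Attribution of the dispersal-limitation fraction

The $\beta_{RC\mathrm{bray}} > 0.95$ fraction conflates true dispersal
limitation, selection by phylogenetically non-conserved factors, and
historical contingency. Per occasion, Mantel tests of
$\beta_{RC\mathrm{bray}}$ against geographic distance (Euclidean on
coordinates) and environmental distance (Euclidean on standardized
variables) probe the first two; when both are significant, both partial
Mantel tests run with the other matrix as covariate — the gating
exactly mirrors that reporting convention. When neither supports
distance or environment, per-site temporal turnover decides:
`perSiteTemporalShift()` treats each occasion as one multivariate
observation of a site and runs a dry-vs-wet PERMANOVA (and PERMDISP) on
that site's Bray-Curtis series. Few shifted sites despite an
environmental shift is the signature of priority effects; mostly
shifted sites point to unmeasured factors. The verdict threshold is a
majority of sites (>50%), exposed as `shiftThreshold` because the
argument is inherently qualitative. The per-site design — one
multivariate observation per occasion, Bray-Curtis for consistency with
the QPE — is our reading of an under-specified analysis and is stated
here rather than hidden.

## Supporting statistics

Hellinger transformation, Bray-Curtis, rarefaction, PERMANOVA
(`adonis2`), PERMDISP (`betadisper`, spatial-median centres by
default), Mantel and partial Mantel, and Mantel correlograms are
delegated to vegan and ape behind stable package functions; the
contracts (inputs, seeds, outputs), not the internals, are the tested
surface. Forward selection for RDA is alpha-based: at each step the
candidate adding most constrained variance is tested by permutation
under the reduced model (residual permutation via `anova.cca` on a
partial RDA) and retained at p < 0.05 with 999 permutations — the
alpha-only flavour, matching the quoted procedure, rather than
adjusted-R² stopping. The collinearity screen greedily removes, from
the worst pair above |r| > 0.7, the variable with the larger mean
absolute correlation. Period comparisons use Kruskal-Wallis for
location and Brown-Forsythe Levene (median-centred) for spread.
Rarefaction is even-depth subsampling without replacement under an
explicit seed (sites under depth are dropped with a warning); because
"subsampling" is sometimes applied to the OTU registry instead,
`trimToTopOtus()` provides that alternative reading, with even-depth
as the default interpretation.

## The synthetic metacommunity generator

The generator is the package's ground truth, not a fixture. The
expected relative abundance of taxon $i$ at site $s$ is

$$\lambda_{is} \propto A_i \,
e^{-\frac{(E_s-\mu_i)^2}{2\sigma_w^2}} \,
e^{-\lambda_d\, d(s, h_i)} \,
e^{\varepsilon_{is}}, \qquad
\varepsilon_{is}\sim N(0, \sigma_\mathrm{drift}^2),$$

optionally masked by a per-site founder lottery (only a fraction
`poolFraction` of taxa can colonize each site, drawn once per site) and
mixed with the regional mean at migration rate $m$; counts are one
multinomial draw of `depth` individuals per site, so depth is exact and
rarefaction-free testing is possible. Sites sit on a unit-spaced grid
(16 sites = 4 × 4). The regime shift changes the among-site mean and SD
of the single driving environmental variable at the split index; extra
nuisance variables uncorrelated with composition can be added. One
driving variable is a deliberate simplification — multi-variable
selection is emulated by the nuisance channel, not by multi-dimensional
niches.

Key parameter choices, made once and kept:

* **Regional abundances** are log-normal with $\sigma = 1.5$, a typical
  skew for microbial taxon-abundance distributions; it sets realized
  per-site richness well below the pool size, which real OTU tables
  always show and which the Raup-Crick nulls require to have room to
  vary.
* **Niche optima** evolve by Brownian motion (rate `bmRate`, root 0) on
  the emitted Yule tree scaled to unit height; only contrasts matter.
  The `traitConservatism` exponent (node heights raised to a power
  $\le 1$ for the trait clock only) concentrates trait change on deep
  branches — an accelerating/decelerating-rates clock producing the
  clade-level niche conservatism seen in real 16S phylogenies. Plain
  Brownian motion on a unit Yule tree produces substantial trait
  convergence between distant clades, which dilutes phylogenetic
  clustering; the conserved clock is therefore used by the scenarios
  whose defining signature is clustering.
* **Clade anchoring** (`anchorClade = TRUE`) centres the environment on
  the mean optimum of an automatically chosen compact, trait-isolated
  clade (roughly a quarter to a half of the pool, minimal "leakage" of
  convergent outsiders); trees without such a clade are re-drawn
  deterministically from the seed (up to 20 attempts, then the best
  candidate with a warning). This guarantees that "homogeneous
  selection" scenarios filter a phylogenetically coherent set — the
  premise of the βNTI signature — for essentially every seed.

The canonical suite (`makeScenarioSuite()`) plants one process each:
two spatially coherent environmental clusters for variable selection; a
homogeneous clade-anchored environment plus founder lotteries for
homogeneous selection; selection off with strong distance decay
($\lambda_d = 3$) for dispersal limitation; full regional mixing
($m = 1$) for homogenizing dispersal; and moderate demographic noise
($\sigma_\mathrm{drift} = 0.25$) for drift. The neutral calibration
scenario (`neutralScenario()`) uses strong per-site demographic noise
($\sigma_\mathrm{drift} = 3$) and nothing else, which centres both the
incidence Raup-Crick and βNTI nulls. These magnitudes are calibration
choices for a synthetic system, documented as such — they are not
estimates of any real rock-pool metacommunity. The `"dry-wet shift"`
composite spreads the clade-anchored gradient widely in the dry period
(variable selection and drift) and collapses it at the split (strong
homogeneous selection), the planted effect the pipeline-level tests
must detect.

What the generator does *not* emulate: temporal autocorrelation beyond
the single regime shift, multi-variable niche axes, taxon interactions,
sequencing error and compositional artefacts, and the deep unevenness
of real libraries. Passing the validation suite therefore shows the
chain recovers processes from data satisfying its own assumptions; it
does not certify performance on real sequence data, where unmeasured
structure can move every one of these statistics.

## Numerical choices and degenerate inputs

* Permutation p-values are never 0: rank-based ones use
  $(b+1)/(\mathrm{reps}+1)$; EMS z-tests default to the normal
  approximation with the exact rank variant available.
* All seeded routines save and restore the caller's RNG state; pipeline
  stages derive sub-seeds as `stageSeed(master, stageName)` so adding
  or removing a stage leaves every other stage's results bit-identical.
* Ordination of a matrix with no off-diagonal CA structure (first
  singular value ≈ 0) keeps the input order; the axis sign is fixed by
  correlation with the input order, and every EMS statistic is
  invariant to reflection.
* βNTI pairs with null SD below a relative floor ($10^{-7}$ of the
  observed scale) are flagged rather than divided; fractions report the
  excluded count.
* All-zero site rows are dropped with a warning at validation (pools
  that dried out carry no information); OTUs absent from the phylogeny
  are a hard error in QPE, with explicit `prune = TRUE` opt-in, because
  silent pruning changes the question being asked.
* Problem sizes in the validation suite (16 sites × 150–200 taxa,
  depths 600–2000, 199–999 null replicates, 20-seed detection runs)
  were chosen so the full suite exercises every stage at realistic
  richness while remaining comfortably runnable on a laptop.

## Known limitations

The incidence Raup-Crick null is sensitive to the evenness of occupancy
probabilities: for pools where most taxa occur at most sites it
saturates towards $-1$ regardless of process. β_RCbray's drift window
($[-0.95, 0.95]$) is narrow; modest abundance noise moves pairs into
the dispersal-limitation fraction, which is precisely why the
attribution layer exists. EMS classification at one occasion has low
power for small matrices. The per-site temporal PERMANOVA treats
occasions as exchangeable replicates within periods, ignoring temporal
autocorrelation. These are properties of the underlying methods, which
the package implements faithfully rather than repairs.
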