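---
title: "Classifying habitat generalists and specialists and tracing their ecology and evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying habitat generalists and specialists and tracing their ecology and evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habgen)
```

# The question habgen answers

Multi-habitat amplicon surveys — for example five habitat types (moss,
sediment, soil, tree hole, water) sampled across several urban parks — ask a
recurring set of questions about the taxa they recover. Which taxa are
habitat **generalists** (broad, even habitat use), which are **specialists**
(confined to one habitat), and which are statistically unremarkable
**opportunists**? Do deterministic processes (environmental selection) or
stochastic ones (dispersal, drift) assemble these groups? How are
generalists and specialists wired into co-occurrence networks, and what
happens to those networks when one group is lost? And over evolutionary
time, do the two strategies differ in speciation, extinction and transition
rates?

habgen implements this pipeline end to end on a taxon-by-sample count table
with habitat/park metadata, a phylogeny, and (for the evolutionary stage)
binary tip states. Every stage is also backed by a synthetic-data generator
with planted ground truth, so each statistical claim the package makes can
be verified against data where the answer is known.

# Niche-breadth classification

Three indices are computed per taxon over its habitat-use proportions
$p_1,\dots,p_H$ (mean within-habitat relative abundances, renormalised):

* Levins' niche breadth $B = 1/\sum_h p_h^2$, between 1 (single habitat)
  and $H$ (uniform use);
* Shannon niche breadth $H' = -\sum_h p_h \log p_h$ in nats;
* occurrence frequency $F$, the fraction of samples occupied.

Averaging within habitats first keeps unequal sample numbers per habitat
from biasing the shares; occupancy is over samples. A taxon is called a
generalist when its observed value exceeds the upper bound of a null
envelope **for all three indices**, a specialist when below the lower bound
for all three, and an opportunist otherwise. The envelope is the empirical
2.5%/97.5% quantile band (95% central mass by default) of each taxon's
index under `n_perm` permutations of the count table.

## The permutation null

The null model is the load-bearing choice of the whole classification, and
the one place where equally plausible-sounding schemes behave completely
differently. `null_classify()` implements three:

* **`"shuffle"` (default)** — within each sample, the counts are permuted
  across taxa. Sample depths and each sample's abundance distribution are
  preserved exactly; what is destroyed is the association between taxon
  identity and abundance. Under this null a taxon's profile is an
  exchangeable draw from the per-sample abundance pools — typically skewed
  and therefore uneven across habitats. A biological generalist, whose
  abundance is *consistently moderate everywhere*, is genuinely more even
  than such draws and rises above the envelope; a specialist falls below
  it.
* **`"multinomial"`** — each taxon's total is re-spread over samples in
  proportion to sample depths. This preserves taxon totals, but on a
  rarefied table it is the *maximal-evenness* placement: any real
  preference structure only adds variance, so the expected observed
  breadth of every taxon is at most the null's. The scheme can detect
  specialists but essentially never generalists; it is retained because it
  is a useful specialist-only screen and an instructive contrast.
* **`"quasiswap"`** — count quasiswap (both margins and table fill
  preserved, via vegan). On very large, very sparse tables the fill
  constraint concentrates the null and behaves like the shuffle null; at
  the few-hundred-taxon scale of the bundled generator the fill constraint
  barely binds and generalist detection degrades, which is why it is not
  the default.

Two strictness rules follow the classification: strict generalists are the
classified generalists at or above the 90th percentile of all three index
values jointly (computed among generalists; ties inclusive), and strict
specialists are classified specialists with more than 50 total reads —
rare taxa may simply be below detection in most habitats, which mimics
specialism. Downstream stages use the strict sets.

# What the synthetic generator emulates

`generate_community()` draws a survey of `n_taxa` taxa over
`habitats x parks x replicates` samples (defaults: 5 habitats x 6 parks x 3
replicates = 90 samples, depth 10,000 reads). Its moving parts, and the
reasoning behind the defaults:

* **Habitat preferences** are symmetric Dirichlet draws; the concentration
  is the single knob mapping to niche breadth (50 for generalists — nearly
  even; 0.05 for specialists — essentially one-hot; 1 for background taxa —
  broad intermediate variety).
* **Abundances** are lognormal (sdlog 1.2), a moderately skewed species
  abundance distribution. Generalists additionally receive a mean-abundance
  multiplier of 8: real habitat generalists in this kind of survey are the
  ubiquitous, consistently present fraction of the community, and a
  handful of reads spread over 90 samples carries no recoverable niche
  signal for *any* classifier — planted labels must be recoverable in
  principle for recovery to be a meaningful test.
* **Space**: parks sit on a unit grid and each taxon is anchored to one
  park with abundance attenuated by `exp(-decay * distance)`. The decay is
  class-specific (generalist 0.2, specialist 2.5, background 0.8),
  mirroring the consistently lower spatial turnover of generalists in
  multi-habitat surveys; it also gives the distance-decay stage a planted
  slope ordering to recover.
* **Counts** are multinomial per sample (closure is exact, which the
  compositional stages rely on), with an optional Dirichlet overdispersion
  knob left off by default.

What the generator does **not** emulate: sequencing error, chimeras and PCR
bias (the pipeline starts at the denoised table); taxonomically structured
phylogenetic signal in niche labels (labels are assigned independently of
the simulated tree); tens-of-thousands-taxon sparsity of full surveys.
Passing recovery tests therefore demonstrates correctness of the machinery
under a realistic but idealised survey, not performance on any particular
real dataset.

# Community assembly

For every within-group sample pair the package computes the abundance-
weighted beta nearest-taxon distance, standardises it against `n_null`
shuffles of the taxon labels across the pool's tips
(betaNTI), and computes a modified Raup-Crick index on Bray-Curtis
dissimilarity: null communities preserve each sample's richness and total
abundance, recruit species proportionally to pool occupancy, and assign
individuals proportionally to mean relative abundance;
$RC = 2\,P(\text{null} < \text{obs}) - 1$ with ties counted half. The
decision rules are: betaNTI below -2, homogeneous selection; above 2,
heterogeneous selection; otherwise RC below -0.95, homogenizing dispersal;
above 0.95, dispersal limitation; the remainder drift. All four
inequalities are strict, so boundary values fall through to the next rule —
a value of exactly 2 is *not* selection. Group summaries report exact
count-based fractions (they sum to one by construction) and the
deterministic/stochastic totals. Phylogenetic-bin-based refinements of this
partition (per-bin nulls aggregated over bins) are deliberately out of
scope; the classification here operates on whole communities, so its
fractions approximate bin-refined analyses qualitatively rather than
numerically.

# Compositional networks and stability

Correlations come from the SparCC estimator written for this package:
per-sample fractions are drawn from a Dirichlet posterior (counts + 1,
which also handles zeros), the variation matrix
$t_{ij} = \mathrm{var}\log(x_i/x_j)$ is solved for basis variances under
the sparsity assumption, strongly correlated pairs (|rho| > 0.1) are
excluded from the basis system for up to 10 rounds, and estimates are
averaged over 20 Dirichlet resamples. Significance is a bootstrap sign
test: samples are resampled with replacement, SparCC re-run, and
$p = \min(1, 2(\min(b_-, b_+) + 1)/(B + 1))$, never exactly zero. Edges
require $|R| \ge 0.6$ and $p < 0.05$; no multiple-testing correction is
applied by default (the thresholds are a screening rule, not an inference),
and isolated nodes are dropped.

Module detection is greedy modularity maximisation on the unsigned,
unweighted graph (edge sign is kept as an attribute only); the merge
sequence is cut at its modularity maximum, preferring the most merged state
on ties so results are deterministic. Node roles use within-module
connectivity $Z_i$ and among-module connectivity $P_i$ with the standard
thresholds (network hubs $Z_i \ge 2.5, P_i \ge 0.62$; module hubs
$Z_i \ge 2.5$; connectors $P_i \ge 0.62$; peripherals otherwise; a module
whose within-degree variance is zero gives $Z_i = 0$). Keystone tallies
(module hubs + connectors, network hubs included) are reported relative to
each niche class's total richness so classes of different size are
comparable.

Stability analyses define: *remaining proportion* after removing 50% of a
class = nodes that still have at least one edge divided by the original
node count (secondary extinctions of newly isolated nodes count as losses;
the alternative "non-removed nodes" convention would make the statistic
insensitive to topology); *global efficiency* = mean inverse shortest-path
length over ordered pairs with unreachable pairs contributing zero;
*vulnerability* = the largest single-node relative drop in global
efficiency; *robustness* = the area under the random-order attack-tolerance
curve (0.5 is the ceiling for a maximally tolerant graph); *functional
complementarity* = total branch length of an average-linkage dendrogram on
Jaccard distances between same-side partner sets of the bipartite
interdomain view; *niche overlap* = mean Morisita-Horn similarity of those
partner profiles (for binary profiles this reduces to the Sorensen match
coefficient). Degree-preserving rewired replicates (double-edge swaps, at
least ten times the edge count per replicate) provide the null for
clustering and modularity z-scores.

# State-dependent diversification

The binary-state speciation-extinction likelihood integrates the coupled
extinction/data equations along each branch with an adaptive Cash-Karp
Runge-Kutta scheme (absolute/relative tolerance 1e-8 by default; each
branch's data variables are renormalised with an accumulated log
compensation, so underflow cannot occur on large trees). At internal nodes
the data variables combine as $\lambda_k D^{(L)}_k D^{(R)}_k$; at the root
the states are combined with weights proportional to their conditional
likelihoods by default ("equal" and user-supplied weights are available,
and conditioning on survival is optional and off by default, since the
model comparison happens between nested fits on the same tree).

`bisse_fit()` follows a two-step protocol: the constrained model (shared
speciation, shared extinction, symmetric transitions; 3 parameters) is
fitted first from a Yule-type starting point, then all six rates are freed
and optimised by Nelder-Mead in log-rate space starting from the
constrained optimum plus jittered restarts. Because the full optimisation
starts at the constrained optimum, the nesting inequality
$\ell_{full} \ge \ell_{constrained}$ holds by construction, and the two
fits are compared by a chi-squared likelihood-ratio test with three degrees
of freedom. The correctness anchor is analytic: when both states share all
rates, the BiSSE likelihood factorises exactly into a constant-rate
birth-death tree likelihood times a two-state Markov character likelihood,
and the test suite holds the implementation to that identity within 1e-6
across random trees.

Each state's diversification potential is $DP = \lambda + t - \mu$. The
transition term is taken as the rate *into* the focal state, since
transitions into a state add to that state's diversity (the variant using
the outgoing rate is also reported). The ratio $DP_s/DP_g$ summarises the
asymmetry between specialists and generalists; it is undefined when
$DP_g = 0$.

A caution on root-to-tip comparisons: on an ultrametric tree every tip is
equidistant from the root, so comparing root-to-tip path lengths between
states is only informative on non-clock trees (for example, trees with
branch lengths in expected substitutions). The simulators in this package
produce ultrametric trees; `root_to_tip_compare()` is therefore exercised
on crafted non-clock trees in the tests.

# Numerical conventions and problem sizes

Degenerate inputs are errors, not silent defaults: empty communities,
all-zero taxa, unrooted trees for rooted analyses, samples below the
rarefaction depth, fewer than 4 taxa for SparCC, fewer than 100
permutations for envelopes, zero-variance nulls for betaNTI. Zero
dissimilarities are dropped (with a count) from the log-log distance-decay
regression, whose slope on $\log(D+1)$ is base-invariant; natural logs are
used throughout. All randomness flows from one master seed through named
substreams, so any stage can be re-run alone and still reproduce its
pipeline result, and identical configurations yield byte-identical output
files.

The validation suite runs at deliberately modest scale: classifier
recovery on the default 600-taxon design with 1,000 permutations;
calibration checks on 250-500 replicates; SparCC fidelity at 50 taxa and
200-500 samples; likelihood-ratio calibration on 200 trees of 200 tips and
recovery on 20 trees of 500 tips; graph-metric oracles exhaustively on all
non-isomorphic graphs with up to six nodes; and a two-domain demonstration
pipeline of 160 + 120 taxa over 40 samples. These sizes were chosen so the
whole suite gives tight statistical checks in minutes on a single core.

# Known limitations

* The classifier's power depends on the data regime: taxa with very few
  reads cannot be confidently classified by any scheme, and the
  within-sample shuffle null calibrates the envelope to the community's
  abundance structure, so extreme abundance skew widens the envelopes.
* Assembly fractions are whole-community two-stage classifications;
  bin-refined variants can differ numerically.
* SparCC assumes a sparse true correlation network; dense strong
  correlation structure violates the basis approximation.
* The BiSSE machinery assumes complete extant sampling and binary states;
  there is no sampling-fraction correction or multi-state extension.
* Networks are screened by fixed correlation/significance thresholds;
  edge sets should be read as co-occurrence hypotheses, not interactions.
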