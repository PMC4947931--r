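---
title: "Models and methods behind fishpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fishpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishpopgen)
```

# Scope

`fishpopgen` implements the analysis chain used in riverine phylogeography
studies that combine mitochondrial sequence data with dominant
(band-phenotype) microsatellite data from polyploid genomes: haplotype and
site summaries, diversity indices, hierarchical AMOVA with permutation
tests, mismatch distributions with sudden-expansion dating, Fu's Fs,
median-joining networks, band-based diversity and distance statistics,
Mantel tests of isolation by distance, and a coalescent simulator that
generates data with the statistical structure these analyses assume.
Bayesian phylogenetics (relaxed-clock dating, skyline plots), ML tree
inference with model selection, and the STRUCTURE MCMC itself are out of
scope; only Evanno delta-K post-processing of clustering likelihoods is
provided.

# Sequence handling

Alignments are character matrices over {A, C, G, T, -, N}. Ambiguity codes
other than N are converted to N with a warning. Two conventions matter
downstream and are fixed package-wide:

* **Missing data (N) are excluded per site** for variability classification
  and **per pair** for distance counting (pairwise deletion). A consequence
  documented rather than "fixed": pairwise difference counts need not obey
  the triangle inequality when deletion patterns differ between pairs.
* **Gap-containing sites are flagged as indel sites** and excluded from
  transition/transversion classification; a site whose only variation is
  the gap is counted as indel-only variation, separately from
  substitution-variable sites. This keeps a control-region indel from
  inflating substitution counts.

Haplotype identity is exact string equality after upper-casing. Sequences
differing only at missing positions are *not* merged; with low-coverage
Sanger data this is the conservative choice, since merging would require an
imputation model.

# Diversity statistics

Haplotype diversity uses Nei's small-sample estimator
$Hd = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$. The mean number of
pairwise differences $K$ averages difference counts over all
$\binom{n}{2}$ pairs; nucleotide diversity $\pi$ divides each pair's count
by the number of sites actually compared for that pair and averages, which
matches the Arlequin/DnaSP treatment of missing data.

The Kimura two-parameter distance is
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with $P$ and $Q$ the
transition and transversion proportions. It is undefined (saturation) when
either log argument is non-positive; the package raises an error rather
than returning a clamped value. Group-level distances report both the raw
mean between-population distance and the net distance
$d_A = d_{XY} - (d_X + d_Y)/2$, since published tables rarely say which
convention they print.

Neighbour-joining delegates to `ape::nj` (the reference Saitou-Nei
implementation); negative branch lengths are clamped to zero and counted.
Bootstrap support resamples alignment columns with replacement, rebuilds
the tree, and scores bipartitions of the reference topology with
`ape::prop.part`.

# AMOVA

Variance components are estimated from squared pairwise distances
following Excoffier, Smouse & Quattro (1992): sums of squares are obtained
from within-group pair sums, mean squares are equated to expectations with
unequal-sample-size coefficients, and fixation indices follow as
$\Phi_{CT} = \sigma_a^2/\sigma^2$,
$\Phi_{SC} = \sigma_b^2/(\sigma_b^2+\sigma_c^2)$,
$\Phi_{ST} = (\sigma_a^2+\sigma_b^2)/\sigma^2$. For sequences, the
distance is the pairwise difference count; for binary band data, the
squared Euclidean distance between 0/1 rows. Negative variance components
are retained in the index formulas (mirroring Arlequin) but flagged, and
truncated at zero only for the percentage display.

Permutation schemes follow the standard design: $\Phi_{ST}$ permutes
individuals across the whole sample, $\Phi_{SC}$ permutes individuals
among populations within regions, and $\Phi_{CT}$ permutes whole
populations among regions. With two regions and few populations the
$\Phi_{CT}$ arrangement space is tiny; the package switches to exact
enumeration over all $\binom{P}{P_1}$ assignments and reports the
enumerated count, rather than quoting a misleading permutation P-value.
P-values from random permutation use $(b+1)/(B+1)$.

# Mismatch distributions and expansion dating

The sudden-expansion expectation treats a pair's coalescence time $T$ (in
mutational units, where a pair accumulates one difference per unit) as
exponential with rate $1/\theta_1$ back to the expansion at $\tau$, and
with rate $1/\theta_0$ earlier; differences are Poisson given $T$. This
yields

$$F_i = \hat F_i(\theta_1) + e^{-\tau/\theta_1} \sum_{j=0}^{i}
  \frac{e^{-\tau}\tau^j}{j!}\left[\hat F_{i-j}(\theta_0) -
  \hat F_{i-j}(\theta_1)\right],
  \qquad \hat F_j(\theta) = \frac{\theta^j}{(1+\theta)^{j+1}},$$

which collapses to the equilibrium geometric at $\tau = 0$ and to a
Poisson($\tau$) shape as $\theta_0 \to 0$, $\theta_1 \to \infty$. The
vector is truncated at the observed maximum difference count and
renormalised.

Fitting minimises the plain sum of squared deviations (SSD) between
observed and expected class frequencies, because SSD is the statistic
reported downstream. The optimiser is a deterministic moment-seeded coarse
grid (candidate $\tau$ values around the observed mean difference count)
followed by a Nelder-Mead polish with box constraints
$\tau \in [0, 2 d_{max}]$, $\theta_0 \ge 0$, $\theta_1 \in [0, 10^5]$.
A fit with $\tau$ at the zero boundary is flagged as degenerate.
Significance of SSD uses a parametric bootstrap: coalescent samples are
simulated under the fitted history, re-fitted, and
$P = \Pr(SSD_{sim} \ge SSD_{obs})$.

Harpending's raggedness is $r = \sum_{i=1}^{d+1}(x_i - x_{i-1})^2$ over
class frequencies $x_0..x_d$ with the closing convention $x_{d+1} = 0$,
so appending empty classes does not change $r$.

Expansion times convert $\tau$ through $u = 2\mu k T_{gen}$ (with $\mu$
accepted in percent per site per Myr, the unit in which rates are usually
quoted), $t = \tau/2u$ generations and $T = t\,T_{gen}$ years, i.e.
$T = \tau/(4\mu k)$ independent of generation time. The factor-2
convention in $u$ is taken literally as published for this analysis chain;
the package asserts the algebraic identity rather than re-deriving the
rate convention, and `soconnori_tau_table()` ships a worked table with
which the chain reproduces all published times at 3 decimals
(`tests/testthat/test-acceptance.R`).

# Fu's Fs

$\theta$ is estimated from mean pairwise differences; under the Ewens
sampling formula the probability of at least the observed number of
haplotypes is
$S' = \sum_{k \ge h} \left|s(n,k)\right| \theta^k / \theta^{(n)}$,
computed in log space with unsigned Stirling numbers of the first kind
(exact rational recursion is used as the test oracle for $n \le 12$);
$F_s = \ln(S'/(1-S'))$. The P-value is the fraction of neutral
constant-size coalescent simulations at the observed $\theta$ with
$F_s^{sim} \le F_s^{obs}$; following the usual convention, $F_s$ is judged
significant at the 5% level when $P < 0.02$.

# Median-joining networks

The substrate is the minimum spanning network: edge $(u,v)$ belongs to it
iff $u$ and $v$ are disconnected when only edges shorter than
$d(u,v) - \varepsilon$ are considered ($\varepsilon = 0$ default, the
Popart default; this is the union of all MSTs). Median vectors are
majority-consensus sequences of connected triples; candidates are
evaluated by the reduction in total spanning cost, added greedily
(best-first), and unsampled vectors of degree $\le 2$ are pruned at the
end. Because the algorithm is order-sensitive, nodes are processed in a
documented deterministic order (frequency descending, then label), and
three-way per-site ties resolve to the lexicographically smallest state.
Character weighting is uniform; an indel column participates as a fifth
character state.

# Dominant (band) microsatellite analysis

Tetraploid band phenotypes record presence, not dosage, so each
(locus, band) pair becomes a dominant binary column. The default
diversity convention works directly on the band-presence frequency $p$:
$H = 2p(1-p)$ and $I = -[p\ln p + (1-p)\ln(1-p)]$, averaged over all
bands; PPL counts bands with $0 < p < 1$ (a 95% criterion is available).
The Hardy-Weinberg dominant-marker estimator
($q = 1-\sqrt{1-p}$) is provided behind a flag but is *not* the default:
it assumes disomic HWE, which is unverifiable when auto- vs
allotetraploidy is unknown. Because published tables rarely state which
convention their software applied, printed $H$/$I$ values are treated as
qualitative, not regression targets.

Nei's unbiased distance treats each band as a biallelic locus
(frequencies $p$, $1-p$) with the $n$-individual sample-size correction
$(n j - 1)/(n-1)$ on within-population identities; disjoint band sets
give infinite distance, returned as `Inf` and flagged. PCoA uses Gower
double-centering with negative eigenvalues reported, never silently
dropped. Evanno's $\Delta K$ is the mean absolute replicate-wise second
difference of $\ln P(D)$ divided by its standard deviation at $K$;
$\Delta K$ is undefined at boundary $K$ and when the replicate standard
deviation is zero (flagged).

# Isolation by distance

The Mantel statistic correlates $d/(1-d)$ (linearised $\Phi_{ST}$ or
$F_{ST}$) with $\log_{10}$ distance in km over unordered pairs, permuting
rows/columns jointly. Distances are expected to be user-supplied
river-path kilometres; a great-circle helper exists but is deliberately
not the default, because straight-line distances misrepresent connectivity
along a drainage. The default test is two-sided; a one-sided (positive
IBD) option exists. `log10` is the base used wherever a published "log"
is ambiguous. With fewer than 4 populations the permutation space is
enumerated exactly and a warning notes how weak the test is.

# The synthetic-data generator

The simulator is first-class, tested code, because the acceptance of most
population-level claims rests on it.

* `simulate_coalescent` draws an n-coalescent with piecewise-constant
  scaled size ($\theta_1$ back to $\tau$, $\theta_0$ earlier), in
  mutational time units (pair mutation rate 1, pair coalescence rate
  $1/\theta$), so $E[\pi] = \theta$ and $E[S] = \theta\sum_{i<n} 1/i$ at
  equilibrium — both verified by simulation tests. Mutations are Poisson
  on branches; sequences use infinite sites by default or finite sites
  with a transition bias (default ts:tv = 10, a typical vertebrate
  mitochondrial value).
* `simulate_structured` adds a two-level hierarchy (populations merging at
  one depth, regions at a deeper one, optional within-region migration),
  emulating an expanding western group deeply split from an isolated
  eastern population; at large split depth the regions share no
  haplotypes.
* `simulate_tetraploid_bands` draws four alleles per locus per individual
  (tetrasomic) and reports the band set, so band counts are 1-4 and band
  presence frequency is $1-(1-p)^4$.
* `simulate_band_presence` generates hierarchically structured binary band
  data with Beta-distributed frequencies whose variances are chosen so
  the generating AMOVA components satisfy the requested $F_{CT}$ and
  $F_{SC}$ exactly at the presence-frequency level.

What the generator does **not** emulate: recombination, selection,
scoring error and null alleles in band calling, uneven locus mutation
rates, and spatially continuous (rather than discrete-deme) structure.
A green test therefore establishes that the estimators recover the
parameters of this idealised world at the stated sample sizes, not that
they are robust to those real-data complications.

# Numerical and design choices

* Stirling numbers, Ewens probabilities and $S'$ tails are computed in
  log space; $S'$ is clamped away from 0/1 before the logit.
* The expansion-fit grid is moment-seeded but fully deterministic; with
  identical input the fit is bit-reproducible.
* Permutation and bootstrap P-values use $(b+1)/(B+1)$ except where the
  arrangement space is exhaustively enumerated.
* In the SSD bootstrap, simulated mismatch histograms are capped at
  $\max(2 d_{max}^{obs}, 50)$ classes (excess pairs pooled into the top
  class): replicates drawn under a degenerate fitted model with huge
  $\theta$ would otherwise produce histograms with $10^5$ classes and
  quadratic-cost refits. For model-consistent replicates the cap is
  inactive.
* All simulators accept a seed and are byte-reproducible; the pipeline
  writes no timestamps into result files so reruns are byte-identical.
* Acceptance-scale choices: the SSD-calibration bootstrap runs at
  B = 50 (production default 1000) and the recovery experiment at the
  published n = 30, k = 1000 scale; both scales are stated in the test
  file and chosen for the 1-CPU test budget, not tuned to outcomes.

# Known limitations

* AMOVA supports at most two hierarchical levels.
* The median-joining implementation targets mitochondrial-scale haplotype
  sets (tens to low hundreds of haplotypes); it recomputes spanning
  networks per iteration and is not optimised for thousands of nodes.
* Fu's Fs P-values rely on the constant-size coalescent null; no
  Tajima's D is provided because this analysis chain does not use it.
* K2P group distances are undefined (error) under saturation rather than
  being truncated, which can surface with very divergent outgroups.
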