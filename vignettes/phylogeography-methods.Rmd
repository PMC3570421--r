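---
title: "Methods: mitochondrial phylogeography and glacial refugia testing"
author: "refugia package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial phylogeography and glacial refugia testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugia)
```

## Scope

`refugia` implements the standard single-locus (mitochondrial) analysis
chain used in range-wide phylogeographic surveys of structured species:
summary diversity statistics, neutrality tests with coalescent-simulated
significance, mismatch-distribution expansion dating, coalescent simulation
of gene genealogies inside competing refugial population-divergence models
scored with the minimum-sorting-events statistic *S*, parsimony-based
refugia localization, and AMOVA/SAMOVA. The worked system throughout is the
red knobby newt *Tylototriton shanjing* of Yunnan, a montane salamander
surveyed at 19 populations (146 individuals, four mitochondrial lineages
A–D, 2373 aligned mtDNA sites). The package ships the published
per-population haplotype-count table (`shanjing_haplotype_table()`); the
sequences themselves are not bundled — a synthetic generator emulates their
statistical structure so the whole chain runs self-contained.

Phylogenetic inference (tree building, clock dating, skyline plots) is out
of scope: the package *consumes* genealogies, it does not infer them.

## Diversity statistics

Gene diversity uses the unbiased estimator
$h = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ with Nei's sampling variance
$$V(h) = \frac{2}{n(n-1)}\Bigl\{2(n-2)\bigl[\textstyle\sum p_i^3 -
(\sum p_i^2)^2\bigr] + \sum p_i^2 - (\sum p_i^2)^2\Bigr\},$$
which reproduces, to all four printed decimals, every per-population
$h \pm \mathrm{se}$ of the survey table, and the pooled value for all 146
individuals (the tests assert this for every row). Nucleotide diversity is
the frequency-weighted mean per-site pairwise difference with the same
$n/(n-1)$ correction; its standard error uses Nei's total-variance
approximation, which folds in coalescent (stochastic) variance — the
package flags it as approximate since survey tables rarely state which
variance they print.

Watterson's $\theta_W = S/a_n$ converts to a female effective size through
$\theta = 2N_e\mu$ (mitochondrial inheritance). Two unit conventions
coexist in this literature and they differ by a factor of the generation
time; the package takes the *per-generation* sequence rate
$\mu_g = \text{rate} \times 10^{-8} \times L \times g$ (rate in %/site/My)
for $N_e$, because $N_e$ feeds the coalescent simulator whose clock is in
generations. Mismatch expansion dating, by contrast, uses the *per-year*
rate $u = \text{rate} \times 10^{-8} \times L$ in $t = \tau/(2u)$: only
this convention converts a fitted mismatch $\tau$ directly into calendar
years (it reproduces the published 0.129/0.119 My from $\tau$ = 6.648 and
6.156 at 1.086%/site/My over 2373 sites).

## Neutrality tests

Tajima's *D* follows the 1989 constants exactly. Fu's *Fs* computes
$S' = \Pr(K \ge k_{obs})$ under the Ewens sampling formula with
$\theta$ set to the mean pairwise difference; Stirling numbers of the first
kind are generated by the standard recurrence entirely in log space (cached
per *n*), so *Fs* is stable to $n$ well beyond the survey's 146. When the
tail probability saturates, a signed-infinity sentinel is returned with a
warning rather than a silent overflow. Fu's recommendation to judge *Fs* at
p < 0.02 for a nominal 0.05 level is carried in the output metadata but
never applied to the returned p-value.

Significance is simulated: constant-size coalescent samples *conditioned on
the observed number of segregating sites* (mutations dropped on branches
with probability proportional to length), the fixed-*S* convention of
Arlequin, which removes $\theta$ as a nuisance parameter. P-values are
one-tailed low — significantly negative *D* and *Fs* jointly signal
demographic expansion. The test suite checks type-I calibration directly:
over 500 null data sets the nominal 5% test rejects at a rate inside the
binomial 95% band.

## Mismatch distributions

The sudden-expansion model uses Rogers' simplification in which the
post-expansion size is infinite, so the expected mismatch probabilities are
the convolution of the geometric equilibrium distribution (parameter
$\theta_0$) with Poisson($\tau$) mutations accumulated since the expansion:
$$F_i(\tau, \theta_0) = e^{-\tau} \sum_{j=0}^{i}
\frac{\theta_0^j}{(\theta_0+1)^{j+1}}\,\frac{\tau^{i-j}}{(i-j)!}.$$
Only $\tau$ enters the dating, which is why the two-parameter form is the
default. Fitting minimizes the sum of squared deviations between observed
relative frequencies and $F_i$ by bounded quasi-Newton search from at least
8 starts on a log-spaced $\tau$ grid crossed with two $\theta_0$ levels
(SSD tolerance $10^{-10}$); the convolution is evaluated by FFT because the
parametric bootstrap re-fits thousands of replicates. Goodness of fit
(p~SSD~, p~raggedness~) is a parametric bootstrap: coalescent samples under
the *fitted* parameters — no coalescence more recent than $\tau$ (in
mutational units), Kingman dynamics with $\theta_0$ beyond — re-fitted with
identical optimizer settings so the observed and bootstrap statistics share
any fitting bias.

The raggedness index here pads the relative-frequency vector with zero
classes on *both* sides before summing squared successive differences, so a
single loaded class scores exactly 2 and two adjacent classes at 0.5 score
0.5. This differs from Harpending's original sum (which starts at the
second class) by the leading boundary term; the choice is immaterial for
p~rag~ because observed and bootstrap values use the same formula.

## Coalescent simulation within refugial models

Five competing hypotheses about Pleistocene refugia are encoded as
population trees with split times taken from the survey's dated phylogeny:
(a) one refugium with all populations diverging at the end of the Last
Glacial Maximum (18 ky BP); (b) two refugia separated 830 ky BP; (c) three
refugia (adds the 760 ky split); (d) four refugia persisting to the end of
the LGM (adds 710 ky); and (e) four refugia with pre-LGM within-lineage
diversification — population splits at the lineage TMRCAs (250/290/70/530
ky BP) and refugial joins at 710/760/830 ky BP. The lineage topology is
(A, (D, (B, C))). Design choices where the hypotheses' figures are silent:
within-lineage structure below a refugial split is a *star polytomy* (no
internal topology is hypothesised); ancestral branches keep the overall
$N_e$; and the overall $N_e$ is divided among refugial branches either
proportionally to the sampled individuals below each branch (default —
sample sizes are what generated the empirical $\theta$ the overall estimate
comes from) or equally. The default overall $N_e$ is the Watterson estimate
implied by the survey's 144 segregating sites in 146 sequences
(≈ 1.26 × 10⁵ females), converted with the 4-year generation time.

Within each branch the simulator runs a continuous-time n-coalescent:
while *k* lineages are present in a branch of size $N_e$, the next
coalescence is exponential with rate $\binom{k}{2}/N_e$ per generation —
the haploid scaling consistent with $\theta = 2N_e\mu$, so a sampled pair
in one population coalesces after $N_e$ generations on average (verified to
within 5% over 5000 replicates). Lineages surviving a split move to the
parent branch; genealogies are returned as rooted, ultrametric, binary
`ape::phylo` objects with branch lengths in generations and tips labelled
`individual|population`.

## The S statistic and hypothesis testing

Slatkin–Maddison *S* — the minimum number of sorting events needed to
explain the subdivision of a grouping character on a genealogy — is the
Fitch parsimony length of that unordered character on the rooted binary
tree, computed by the bottom-up pass that counts empty set intersections
(state sets as bit masks; at most 31 states). The suite proves the pass
equal to the exhaustive minimum over all internal assignments on 500 random
trees, and equal to an independent library implementation. A hypothesis is
rejected when the observed *S* falls outside the equal-tailed empirical
2.5–97.5 percentile interval of 1000 simulated values (midpoint
interpolation at ties; whether such published intervals are equal-tailed or
highest-density is rarely stated — equal-tailed is the package's choice).
Data generated under the four-refugia pre-LGM model land inside that
model's interval and outside the single-refugium interval in ≥ 90% of
seeded trials — the qualitative pattern that motivates multi-refugium
inference.

## Refugia localization

For each of a sample of genealogies (here: simulated; in an empirical
study, posterior draws), the set of most-parsimonious root states of the
locality character is the Fitch root state set — for binary trees exactly
the states attaining the minimum length, which the tests verify against
exhaustive enumeration. A unique root locality scores 1, *n* tied
localities score $1/n$ each; sums over genealogies divided by their number
give each locality's relative probability of having harboured the clade's
MRCA (scores sum to 1 by construction). For clade-level analyses the trees
are pruned to the clade's tips first (`prune_to_group()`).

## AMOVA and SAMOVA

The three-level analysis of molecular variance uses Excoffier's
sums-of-squares formulation on squared pairwise haplotype differences, with
the unbalanced moment equations for the variance components and
$\Phi_{CT} = \sigma_a^2/\sigma_T^2$, $\Phi_{SC} =
\sigma_b^2/(\sigma_b^2+\sigma_c^2)$, $\Phi_{ST} =
(\sigma_a^2+\sigma_b^2)/\sigma_T^2$. Distances are plain pairwise
differences, with sites carrying a gap or N in either sequence of a pair
excluded (pairwise deletion) — sequence surveys of this kind rarely state
their convention, and pairwise deletion matches the common default.
Negative variance components are reported as computed, never truncated:
published tables print them (a $\Phi_{CT}$ of −0.35 is a legitimate
outcome), and truncation would silently break the percentage column.
Permutation schemes follow the standard design: whole populations among
groups for $\Phi_{CT}$, individuals among populations within groups for
$\Phi_{SC}$, individuals among populations for $\Phi_{ST}$; p-values use
the (hits + 1)/(permutations + 1) convention. A conservation law holds
exactly and is tested: the three sums of squares add to the total sum of
squares. The variance *components* do not identically sum to the one-level
total variance on unbalanced designs — that identity holds only in
expectation, which is why the suite does not assert it.

SAMOVA searches partitions of populations into *K* groups for maximal
$\Phi_{CT}$ by simulated annealing: single-population moves, Metropolis
acceptance, geometric cooling (defaults: 10 starts × 5000 steps, T₀ = 0.1,
factor 0.995 — all exposed), with user-supplied partitions usable as extra
starts so the result provably never scores below them. An optional
contiguity constraint takes a user adjacency matrix and only moves a
population into groups containing one of its neighbours; it is off by
default because published groupings include geographically non-adjacent
partitions.

## The synthetic generator

`generate_study_fixture()` emulates the survey: one genealogy under the
four-refugia pre-LGM model at the empirically calibrated overall $N_e$,
HKY sequences along it (κ = 4, base frequencies 0.30/0.25/0.15/0.30 —
plausible amphibian mtDNA values, chosen once; site-rate heterogeneity is
deliberately omitted from the generator), and bounded rejection sampling
(≤ 1000 draws) until the four lineages are reciprocally monophyletic,
mirroring the empirical pattern. Matched features: sample sizes, population
and lineage structure, alignment length, reciprocal monophyly, the ranking
of between- versus within-lineage divergence. *Not* matched: the exact
haplotype count and segregating-site total (they vary around the survey's
58/144), site-rate heterogeneity, saturation at deep divergences, and any
geographic gradient within lineages — so green tests demonstrate
correctness of the machinery under the model's assumptions, not goodness of
those assumptions for real newts. Sequence simulation transition matrices
come from an eigendecomposition of the HKY generator scaled to one expected
substitution per site per unit branch length; the tests check a long-branch
divergence against an independent matrix exponential.

One generator property needs care: ranking the three between-lineage
divergences in split-time order is only a sharp property when both noise
sources — ancestral coalescent variance ($2N_e\mu$ per lineage pair) and
Poisson sequence noise ($\sqrt{\text{expected differences}}$) — are small
against the split-time gaps. At the study's own scale ($N_e \approx 10^5$,
L = 2373) neither is, so the property test runs at $N_e$ = 1500 and
L = 60000; the defaults are untouched.

## Problem sizes and numerical choices

The test suite scales Monte-Carlo experiments to what each property needs:
500 trials for type-I calibration (nominal 5%, binomial 95% band), 200
replicates per model and 20 trials for the refugial hypothesis contrast,
500 genealogies × 20 runs for root-origin recovery, 50 data sets for
$\tau$ recovery, ~100 trials × 99 bootstrap replicates for goodness-of-fit
uniformity. Every stochastic routine takes an integer seed and restores the
caller's RNG state; identical seeds reproduce results bit for bit, which
the suite asserts for every simulator and for the end-to-end pipeline.
Degenerate inputs are defined, not accidental: a mismatch histogram with a
single class fits $\tau = 0$ with SSD 0; monomorphic scopes raise
undefined-statistic errors in the statistics and yield NA rows in the
pipeline; samples of size 1 are reported with no diversity, as surveys
print them.

## Known limitations

Single locus, no recombination, no migration after splits, no serial
sampling. The S-statistic machinery requires binary trees (the simulator
only produces them; soft polytomies in user genealogies must be resolved
first). Fu's *Fs* uses the Ewens distribution with a plug-in $\theta$, as
in standard practice, not the exact conditional distribution. SAMOVA's
annealing is a heuristic: for many populations and large *K* the optimum is
not guaranteed, only never worse than any partition it was shown.
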