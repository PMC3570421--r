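# refugia

Single-locus (mitochondrial) phylogeography for structured species: who
diverged from whom, when populations expanded, and where they sat out the
Pleistocene glaciations.

The package implements the analysis chain used in range-wide mtDNA surveys,
with the red knobby newt *Tylototriton shanjing* of Yunnan (19 populations,
146 individuals, four mitochondrial lineages A–D, 2373 aligned sites) as
the worked system:

- **Haplotypes and diversity** — collapse alignments to haplotypes; gene
  diversity `h = n/(n−1)(1 − Σp²)` with Nei's sampling variance, nucleotide
  diversity π, Watterson's θ, and the θ = 2Nₑμ conversion to effective
  size.
- **Neutrality tests** — Tajima's *D* and Fu's *Fs* (log-space Ewens /
  Stirling computation), with p-values from constant-size coalescent
  simulations conditioned on the observed segregating sites.
- **Mismatch distributions** — sudden-expansion model
  `F_i(τ, θ₀) = e^{−τ} Σ_j θ₀^j/(θ₀+1)^{j+1} · τ^{i−j}/(i−j)!`, multi-start
  SSD fitting, parametric-bootstrap goodness of fit, raggedness, and
  expansion dating via `τ = 2ut`.
- **Refugial hypothesis testing** — structured coalescent simulation of
  gene genealogies inside five competing population-divergence models
  (one to four glacial refugia, LGM-aged or older), scored with the
  Slatkin–Maddison minimum-sorting-events statistic *S* (Fitch parsimony
  length of the population character) against its simulated 95% interval.
- **Refugia localization** — most-parsimonious root-locality sets averaged
  over genealogy samples, giving each sampling site a relative probability
  of having harboured a clade's MRCA.
- **AMOVA / SAMOVA** — Excoffier's variance decomposition with Φ_ST, Φ_SC,
  Φ_CT and the standard permutation schemes; simulated-annealing search for
  the population grouping maximizing Φ_CT.
- **Synthetic data** — an HKY simulator that generates alignments with the
  survey's sampling structure (and known truth) so every stage runs, and is
  testable, without any sequence download.

The published per-population haplotype-count table ships with the package
(`shanjing_haplotype_table()`); sequences are emulated, not bundled.

## Worked example

Gene diversity straight from the bundled survey counts:

```r
library(refugia)
ht <- shanjing_haplotype_table()
haplotype_diversity(scope_counts(ht, "JP"))   # h = 0.7333, se = 0.1199
haplotype_diversity(scope_counts(ht, "all"))  # h = 0.9608, se = 0.0078
```

Demographic machinery on data simulated with known truth (a sudden
expansion of mutational age τ = 6.6):

```r
a  <- generate_expansion_dataset(theta0 = 1, tau_true = 6.6, n = 60,
                                 L = 2373, seed = 7)
ht <- collapse_haplotypes(a)
d  <- pairwise_differences(ht)
neutrality_test(ht, d, nreps = 1000, seed = 7)
#> D = -2.937 (p = 0.000), Fs = -84.346 (p = 0.000)
mismatch_test(ht, d, nreps = 1000, seed = 7)
#> sudden-expansion fit: tau = 7.209, theta0 = 0.000,
#>   SSD = 0.0004 (p = 0.755), r = 0.0085 (p = 0.571)
#> expansion time: 139871 years (0.140 Mya)
```

Both expansion signals fire (strongly negative, significant *D* and *Fs*),
the fitted τ brackets the truth, and the goodness-of-fit bootstrap retains
the expansion model — with τ = 6.6 truth, the 0.140 My date is what
`τ/(2u)` gives at 1.086%/site/My over 2373 sites.

Refugial hypothesis testing on a full synthetic survey:

```r
fx  <- generate_study_fixture(seed = 42)      # 146 individuals, 19 pops
pops <- shanjing_populations()
lin <- setNames(pops$lineage, pops$population_id)
S_obs <- s_statistic(fx$tree, lin[tip_populations(fx$tree)])
#> S_obs = 3  (four reciprocally monophyletic lineages)

Ne <- effective_size(watterson_theta(144, 146), 1.086, 2373, 4)  # 125682
for (h in c("a", "e")) {
  m  <- refugia_model(h, Ne, pops)
  sd <- simulate_s_distribution(m, nreps = 1000, seed = 42)
  print(refugia_test(S_obs, sd))
}
#> hypothesis a: 95% interval [16, 25] -> reject
#> hypothesis e: 95% interval [3, 3]  -> retain
```

Data carrying four anciently isolated lineages are incompatible with a
single LGM refugium (the simulated *S* never drops near 3) but sit squarely
inside the four-refugia-before-the-LGM distribution. `run_all(run_config(...))`
chains every stage end-to-end and writes per-stage tables plus a manifest
of seeds.

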