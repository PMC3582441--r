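# haplomix

Single individual haplotyping (haplotype assembly) with per-region
confidence scores.

Given aligned SNP fragments — sparse binary vectors over heterozygous
sites, as produced by long-read or pooled fosmid sequencing pipelines —
`haplomix` reconstructs the two haplotypes of a diploid individual and,
unlike purely combinatorial assemblers, tells you *which parts of the
assembly to trust*. It is aimed at anyone who feeds phased haplotypes into
downstream analyses (recombination mapping, allele-specific expression,
tumour haplotype amplification) where an undetected switch error silently
corrupts every cross-switch conclusion.

## The model

Each fragment $f$ is an independent draw from a two-component mixture, one
component per haplotype ($p^m = 1/2$ each). With per-site phase
probabilities $\theta_{j\nu}$ over $\Delta = \{(0,1),(1,0)\}$ and a fixed
allele error rate $\alpha$ (default 0.1),

$$P(f \mid \Theta) = \sum_{h \in \{0,1\}} \tfrac12 \prod_{j \in X(f)}
\sum_{\nu \in \Delta} \theta_{j\nu}\, p^e(f_j \mid \nu_h),\qquad
p^e(\sigma\mid\sigma') = (1-\alpha)^{[\sigma=\sigma']}\alpha^{[\sigma\neq\sigma']}.$$

The model is fitted by variational Bayes EM with a per-site Dirichlet
posterior on $\theta$, plus a *twist-restart* heuristic: converged states
are re-run after swapping the haplotype labels from a weakly supported
boundary onward, and the twist is kept only when the marginal likelihood
improves. From the fit, the **connectivity** of boundary $j_0$,

$$\mathrm{connectivity}(j_0) = \log P(F\mid\Theta) -
\log P(F\mid\Theta^{\mathrm{twist}(j_0)}) \quad [\text{nats}],$$

measures the evidence against a switch at $j_0$; the **minimum
connectivity (MC)** of a site range is the minimum over its interior
boundaries. Blocks whose MC clears a threshold (default 6 nats) are
protected against switch errors. The package also ships a
pairwise-consistency evaluation suite (precision = CP/(CP+IP) over
within-block site pairs, recall over the connected-component pair space,
switch-error rate, a majority-vote no-assembly baseline), a chimeric
fragment detector for pooled data, and the fragment simulator used in all
evaluations.

## Worked example

```r
library(haplomix)

sim <- simulate_fragments(n_sites = 500, coverage = 5, len_range = c(3, 7),
                          error_rate = 0.1, seed = 1)
sim$fragments
#> <fragment_set> 994 fragments over 500 sites (4997 allele calls)

set.seed(2)
fit <- haplomix(sim$fragments)
summary(fit)
#> Haplotype mixture model fit (VBEM + twist restarts)
#>   sites: 500, fragments: 994, components: 1
#>   log-likelihood: -2451.3662  (25 twist attempts, 22 accepted)
#>   alpha = 0.1, MC threshold = 6
#>   blocks at MC >= 6: 29 covering 468/500 phaseable sites
#>  start end n_sites       MC
#>      1  12      12 7.061088
#>     13  50      38 6.479570
#>     54  64      11 6.316815
#>   ...

evaluate_blocks(predict(fit, "blocks"), sim$fragments, sim$truth)
#> <hap_eval> CP=6846 IP=0 precision=1 recall=0.05488 switch_error_rate=0

no_assembly_baseline(sim$fragments, sim$truth)
#> <hap_eval> CP=2156 IP=166 precision=0.9285 recall=0.01861
```

Reading this: the 500 sites form one connected component, so all
$\binom{500}{2}$ pairs are in the prediction space. At the default MC
threshold the fit keeps 29 blocks covering 468 sites; every one of their
6,846 within-block pairs agrees with the simulated truth (precision 1,
switch-error rate 0), at the cost of recall — only 5.5% of all pairs are
phased at this confidence. Majority voting over co-spanning fragments (no
assembly at all) is both less precise (0.93) and far shallower (1.9%
recall). Lowering `mc_threshold` in `predict()` trades precision for
recall; `plot(fit)` shows the connectivity profile the blocks are cut
from.

The same pipeline is available from a shell via the thin wrapper in
`inst/cli/` (subcommands `simulate`, `phase`, `chimerity`, `evaluate`,
`curve`).

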