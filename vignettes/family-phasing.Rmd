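---
title: "Family-based haplotype phasing in polyploid F1 populations"
author: "famphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based haplotype phasing in polyploid F1 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famphase)
```

## The problem

Short sequencing reads carry local phase information: alleles called in the
same read (or read pair) lie on the same chromosome copy. In a `k`-ploid this
is the only direct evidence for assigning SNP alleles to the `k` homologs,
and it is weak — reads are short, coverage per homolog is thin, and
sequencing errors produce spurious overlaps. In an outcrossing F1 population,
however, every haplotype segregating in the family must be present in one of
the two parents (recombination is negligible over the few kilobases a
short-read haplotype block spans). `famphase` exploits this: it pools the
reads of the *whole family* to estimate the two parental phasings, then
assigns each offspring a subset of the parental haplotypes, and uses
Mendelian segregation to correct and impute allele dosages along the way.

## The model

**Blocks.** Phase is only resolvable where reads connect SNPs. The
SNP-connectivity graph joins two sites co-covered by at least one fragment
(both mates of a read pair count as one fragment); its connected components
are the haplotype blocks (`find_blocks()`). Because connectivity is computed
from the pooled population reads, blocks are much longer than any single
individual's reads would give; the gaps-per-SNP statistic
`ngps = (blocks - 1) / l` measures the remaining fragmentation.

**Parental phasing by greedy Bayesian extension.** Within a block with sites
$s = 1, \dots, l$, the pair of parental phasings $(H_m, H_f)$ is built one
SNP at a time. Given the surviving candidates at $s-1$, every dosage-
consistent placement of the alternative alleles on the $k_m$ maternal and
$k_f$ paternal homologs is enumerated ($\binom{k}{g}$ columns per parent for
dosage $g$), and each extension's posterior is

$$ P(H_m^s, H_f^s \mid \cdot) \propto P(R \mid H_m^s, H_f^s, \epsilon)\,
   P(H_m^s, H_f^s \mid G_m^s, G_f^s, G_{c_1}^s, \dots, G_{c_n}^s,
     H_m^{s-1}, H_f^{s-1}), $$

normalized over all extensions of all surviving candidates. The read
likelihood treats a parent's fragment as a uniform mixture over that
parent's homologs and an *offspring* fragment as a uniform mixture over all
$k_m + k_f$ parental homologs — the no-recombination assumption says every
offspring read originates from some parental haplotype, which is exactly how
pooling the family reads boosts the effective coverage per parental
haplotype. Only fragments linking site $s$ to the phased prefix contribute
at step $s$ (anything else is constant across extensions); likelihoods are
accumulated in log space and per-fragment row mixtures are rescaled to avoid
underflow. The prior is uniform over dosage-consistent placements and zero
for extensions whose conditioning offspring dosages are not transmissible.

**Branching and pruning.** After each extension the candidate set is cut
back: candidates with posterior below the hard threshold $\rho$ are
discarded (*branching*), then those below $\kappa \cdot P_{\max}$
(*pruning*). Defaults are $\rho = 0.2$ and $\kappa = 0.94$. The argmax is
always retained, survivors are renormalized, ties are broken on the
canonical (row-sorted) phasing so runs are reproducible, and a safety cap
(`max_candidates = 256`, far above anything $\rho = 0.2$ admits) bounds the
worst case. $\rho \to 0$, $\kappa = 0$ disables pruning entirely and makes
the greedy sweep equivalent to exhaustive enumeration, which is how the
engine is validated on small diploid instances.

**Dosage correction and imputation.** The extension conditions on the called
dosages. When a call is missing, or an offspring call is impossible given
the parents under random polysomic segregation, the whole column of
population genotypes at that site is re-estimated by joint MAP
(`map_population_genotypes()`): a uniform prior over the parental dosage
pair, each individual's site likelihood under uniform-homolog base sampling
($P(\text{alt call}) = \tfrac{g}{k}(1-\epsilon) + (1-\tfrac{g}{k})\epsilon$),
and the transmission factor
$P(G_c \mid G_m, G_f)$ given by the convolution of two hypergeometric gamete
distributions (`offspring_dosage_pmf()`; no double reduction, no
preferential pairing). Otherwise input dosages are trusted. MAP ties break
toward the called dosage, then the smaller one. Every corrected offspring
dosage is transmissible by construction.

**Offspring phasing by MEC.** Each parent transmits $k/2$ homologs, so a
tetraploid cross admits $\binom{4}{2}^2 = 36$ candidate offspring phasings
per parental pair. Each offspring receives the candidate with the smallest
minimum-error-correction score against its own reads — the number of allele
calls that must be flipped for every fragment to match some haplotype — with
ties broken toward candidates matching more of its called dosages. An
offspring covered by no reads still gets a phasing (tie-break on dosage
match): this imputation is why family phasing misses far fewer offspring
SNPs than single-individual methods.

**Site exclusion.** Walking the phased sites in order, each offspring keeps
the set of transmissions compatible with its dosages at the sites accepted
so far. If that set would become empty — the genotype vector cannot arise
from any recombination-free transmission, e.g. parents
$(0,0,1,1)/(1,1,0,0)$ at two sites with an offspring phased $(0,0,0,1)$ at
the first and called dosage 4 at the second — the site is excluded from
phasing. By default exclusion is population-wide (one inconsistent offspring
removes the site for everyone); `exclude_scope = "offspring"` leaves only
the offending offspring unphased. With error-prone input dosages the
population-wide rule can over-exclude in large families, which is the main
reason a missing-SNP rate above zero is expected at all.

**Ranking.** Complete solution sets (a surviving parental pair plus its
offspring selections) are ordered by parental posterior, then by the summed
offspring MEC; the rank-1 set is the reported fit.

## The simulator

`sim_f1_population()` generates the study conditions end to end: a uniform
random reference region (1 kb by default), SNP positions from cumulative
lognormal gaps moment-matched to mean 50 bp / SD 90 bp
($\sigma^2 = \log(1 + (90/50)^2)$, $\mu = \log 50 - \sigma^2/2$), parental
dosages drawn per site from a categorical distribution favoring low
alternative dosages ($0.4, 0.3, 0.15, 0.1, 0.05$ for $g = 0..4$ — a stand-in
for the cultivar-panel distribution of the original study, which is not
published in reusable form) conditioned on segregation, alleles placed on
uniformly random homologs, offspring as uniform $k/2$-subsets of each
parent's homologs without recombination, and paired-end fragments
(2 x 125 bp, Gaussian insert 350 +/- 35 bp truncated at 250 bp, uniform
start) with a uniform per-base miscall rate (0.001 by default; the insert SD
is our choice, as is the error model — no indels or quality profiles).
Depths are per homolog (5-5-2x mother-father-offspring by default). The
emitted VCF carries the *true* genotypes; `call_genotypes()` produces
realistic noisy per-individual calls when the dosage-correction machinery is
to be exercised.

What the simulator does *not* emulate: real reference content (haplotyping
accuracy depends on SNPs, not sequence), alignment and variant-calling
artifacts, indels, mapping bias, depth heterogeneity beyond Poisson, or
recombination. Passing benchmarks on these simulations therefore shows the
estimator recovers the truth under its own generative assumptions at
realistic geometry and noise — not that it is robust to caller-specific
dosage error patterns.

## A worked run

```{r example}
sim <- sim_f1_population(n_offspring = 6, seed = 42)
fit <- phase_population(sim)
summary(fit)
evaluate_phasing(fit, sim)
```

## Benchmark scale and numerical choices

The packaged benchmark (`benchmark_grid()`, also driven by
`scripts/acceptance.R` and the `famphase benchmark` subcommand) uses 20
regions per scenario and 2, 6, 10 and 30 offspring — a reduced grid chosen
so the full replicate runs in minutes on one core while keeping the
per-scenario Monte-Carlo error well inside the wide empirical intervals it
is compared against. Error probabilities are clamped to
$(10^{-6}, 0.5)$; Q0 bases are dropped at extraction; overlapping mates
that disagree at a SNP drop the site (keeping either call would
double-count one uncertain base) and keep the smaller error when they
agree. Degenerate inputs are handled explicitly: single-SNP blocks are
reported dosage-only (no phase information exists), regions drawing fewer
than two SNPs are resampled, and a site whose extensions all fail even
after re-estimation is skipped rather than guessed.

One observed property of these conditions is worth calling out: with
lognormal gaps (mean 50, SD 90) about 1% of inter-SNP intervals exceed the
~455 bp maximum span a 350 +/- 35 bp template can bridge, so roughly one
region in five to ten contains an unbridgeable gap and the expected
gaps-per-SNP on the grid is of order $10^{-2.5}$, an order of magnitude
above zero. This is a property of the read geometry and SNP spacing, not of
the estimator: no phasing method can join SNPs no fragment connects.

## Known limitations

Even ploidies only (balanced meiosis), one ploidy per individual pair of
parents, bi-allelic SNPs only, no recombination within blocks (appropriate
for blocks up to ~20 kb in typical crops; populations large enough to make
recombinants likely should be split), no double reduction or preferential
pairing, and exact row-assignment in the reconstruction-rate metric is
enumerative (fine up to `k = 7`). Runtime grows linearly in the number of
SNPs and offspring and with the square of depth, but combinatorially in
ploidy through the $\binom{k}{g}$ placements per extension.
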