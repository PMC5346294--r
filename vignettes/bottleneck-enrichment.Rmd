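---
title: "Comparing allele frequency spectra across a population bottleneck"
author: "isoenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing allele frequency spectra across a population bottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoenrich)
```

## The scientific problem

Recently founded population isolates — populations established by a modest
number of founders that later grew by orders of magnitude — carry a
distinctive allele-frequency signature relative to large outbred
populations. The founder event loses much of the rare variation, while
alleles that survive it are pushed upward by drift, so a subset of variants
that are rare elsewhere segregate at low (2–5%) frequency in the isolate.
Variants under purifying selection are held rare in large outbred
populations, which makes their post-bottleneck frequency gain
proportionally larger. Both effects matter practically: an allele whose
minor allele frequency (MAF) is several-fold higher in an isolate needs a
several-fold smaller association study there.

`isoenrich` implements the statistics of this comparison for two population
sequencing panels of biallelic SNVs:

* folded-spectrum binning and cross-population sharing tables
  (`spectrum_table()`, `ratio_curve()`),
* a delta-method enrichment ratio with confidence intervals and a
  two-category comparison test (`enrichment_ratio()`,
  `compare_categories()`, `category_enrichment_scan()`),
* per-variant MAF fold-enrichment classification (`fold_ratio()`,
  `fold_summary()`),
* noncentral chi-square association power and sample-size calculators
  (`assoc_power()`, `required_n()`, `equivalent_n()`), and
* a per-site Wright–Fisher forward simulator that generates two-population
  data with these signatures (`simulate_sites()`,
  `bottleneck_expectation_check()`).

## The enrichment model

Suppose a variant category holds $F$ variants in population 1 and $B$ in
population 2, with $M = F + B$. Conditional on $M$, model $F$ as binomial
with success probability $s$, the share of the category's variants
contributed by population 1. The enrichment ratio is $u = s/(1-s)$,
estimated by $\hat u = F/B$, and the delta method gives

$$\operatorname{var}\log\hat u = \frac{1}{M\,\hat s\,(1-\hat s)},
\qquad \hat s = F/M,$$

from which a normal interval on the log scale is exponentiated back
(`enrichment_ratio()`). At $\hat s = 1/2$ this variance is exactly $4/M$.
Departure from equal counts is tested with a two-sided binomial test of
$F$ in $M$ trials against $1/2$.

Two categories are compared through
$\log\hat u_1 - \log\hat u_2$, which under the null of equal enrichment has
variance approximately $(1/M_1 + 1/M_2)/(\hat s(1-\hat s))$ with the pooled
$\hat s$ (`compare_categories()`). For moderate counts this reproduces the
standard two-sample proportion test; the suite checks agreement within 10%
relative error and that the discrepancy shrinks as counts grow.

`category_enrichment_scan()` applies the test per functional category
within one MAF bin. Bin membership is assessed with each population's own
folded MAF, matching how per-population spectrum columns are built. Two
baselines are provided: `"complement"` (variants outside the category;
disjoint counts, valid independence assumption — the default) and `"all"`
(the whole bin, category included — comparable to published category-vs-
genome constructions). Neither is asserted to be the exact construction
used in any particular study; both are reported as what they are. Raw
p-values are the primary output, with an optional Bonferroni column.

Zero counts make the ratio and interval undefined. Rather than silently
adding pseudo-counts, results are flagged, and an explicit
`haldane = TRUE` option adds 0.5 to every count involved.

## Frequency bins, sharing, and fold enrichment

The default `maf_bin_scheme()` uses edges 0.5%, 2%, 5% with a
5-copy minor-allele-count (MAC) floor on the lowest bin, reproducing the
standard four-bin presentation of isolate comparisons. Conventions the
sources leave open are fixed as follows:

* Interior bins are half-open $[\ell, h)$; a MAF of exactly 5% falls in the
  top bin. Applied uniformly.
* Study inclusion uses the *pooled* MAC across both panels
  (`filter_mac()`, floor 5), mirroring joint-call quality control. Within a
  population, any polymorphic variant (MAC $\ge 1$) below 0.5% counts in
  the lowest bin — the per-population columns must include variants rare in
  one panel but common in the other.
* `assign_bin()` distinguishes `"monomorphic"` (MAF 0) from `"filtered"`
  (polymorphic but under the scheme's MAC floor) instead of a single
  combined bucket; the two conditions have different causes and users may
  want to count them separately.
* "Shared" means minor allele count $\ge 1$ in the other panel — the
  literal reading of "polymorphic".

Fold enrichment (`fold_ratio()`) divides the frequencies of the *pooled*
minor allele in the two populations, not each population's own folded MAF:
a ratio of two different alleles' frequencies would be meaningless, and
per-population folding flips identity near 0.5. When the allele is absent
from the denominator panel the denominator becomes the single-copy
pseudo-frequency $1/(2n)$ — the smallest nonzero frequency a panel of $n$
diploids could have observed — and the variant is flagged rather than
silently imputed. Fold classes $[2,5)$, $[5,10)$, $[10,50)$, $[50,\infty)$
are half-open, so a fold of exactly 5 goes to the 5–10× class. Percentages
use the category's total variant count in the numerator population as the
denominator, which makes the genome-wide "at least 2×" fraction directly
interpretable as "share of this population's variants enriched at least
twofold".

## The power model

For a quantitative trait under an additive model explaining little
phenotypic variance, the 1-df association test statistic is noncentral
chi-square with noncentrality parameter

$$\lambda = 2Nf(1-f)b^2,$$

where $N$ is the sample size, $f$ the MAF and $b$ the per-allele effect in
phenotypic s.d. units; for a case–control design
$\lambda = 2Nf(1-f)r(1-r)b^2$ with case proportion $r$ and $b$ the
per-allele log-odds (an odds ratio may be supplied and is converted as
$b = \log \mathrm{OR}$). Power is the probability that the noncentral
chi-square exceeds the central critical value at $\alpha$
(default $5\times10^{-8}$, genome-wide significance; the quantile is
computed, never hard-coded). For one degree of freedom this equals
$\Phi(\sqrt\lambda - \sqrt{c}) + \Phi(-\sqrt\lambda - \sqrt{c})$, an
identity the tests verify to $10^{-10}$, and the closed form is checked
against $10^5$ simulated Wald statistics at three settings spanning power
0.01–0.9.

`required_n()` bisects over integer $N$ (power is strictly increasing in
$N$), returning the smallest $N$ at or above the target with
`power(N-1)` below it. Because the two NCPs are equal by construction,

$$N_2 = N_1\,\frac{f_1(1-f_1)}{f_2(1-f_2)}$$

is the sample size in a second population with the same power
(`equivalent_n()`); for a rare variant enriched twofold this is about half
the sample. Printed power is truncated to a whole percent (matching the
usual reporting style); full precision is retained in the returned
objects.

```{r power}
required_n(0.03862, 0.47, alpha = 5e-8, target_power = 0.8)
assoc_power(2415, 0.02016, 0.47)
round(equivalent_n(2415, 0.03862, 0.02016))
```

## What the simulator emulates

`simulate_sites()` is a per-site forward Wright–Fisher simulator. For each
site an ancestral minor-allele frequency is drawn from a density
$\propto 1/x$ on $[1/(2N_\mathrm{anc}),\,0.5]$ — the neutral shape of the
low-frequency end of the spectrum, truncated at 0.5 for folded-spectrum
symmetry instead of using a full mutation–drift stationary distribution.
The frequency is then propagated independently down two branches for
`t_split` generations by binomial resampling of $2N_t$ chromosomes:
population A at constant size, population B founded at `bottleneck_size`
diploids and growing exponentially back to the ancestral size over the
first `t_growth` generations after the split. Purifying selection is
applied deterministically before each drift step,
$f \leftarrow f(1-s)/(1-fs)$, the standard haploid-equivalent
approximation that keeps drift the only noise source. Finally each panel's
allele counts are drawn binomially from the branch frequencies, and sites
monomorphic in both samples are dropped.

Sites are simulated independently — no linkage — which is acceptable here
because every statistic in the package treats sites independently; a
coalescent machine would add realism the downstream analyses cannot see.
Sequencing error, low-coverage genotype likelihoods and phasing are
likewise not emulated.

Default demography (`demography_model()`): ancestral size 5000, split 100
generations ago, population A constant at 5000, population B founded at
1000 and growing exponentially to 5000 across the whole branch. These
values are a deliberately scaled-down rendition of a young isolate chosen
on two grounds: the founder drift
($\sum 1/(2N_t) \approx 0.04$ versus $0.01$ on the constant branch) is
strong enough to deplete rare variation and shift surviving rare alleles
into the 2–5% range, but mild enough not to scatter that bin past 5% —
a much deeper founding (say 100 diploids held for many generations)
erases the low-frequency excess entirely, pushing survivors to common
frequencies. Sizes in the thousands rather than the millions keep the
binomial updates cheap, so the three-seed property run below finishes in
well under a minute.

`bottleneck_expectation_check()` runs the generator over several seeds
(defaults: 200 000 sites, seeds 1–3, panels of 1463 diploids each) and
asserts three signatures on the MAC-filtered output:

1. **Rare-variant depletion** — population B holds fewer variants below
   0.5% MAF than population A.
2. **Low-frequency proportional excess** — the share of B's variants
   falling in the 2–5% bin, relative to A's share, exceeds 1. The
   *proportional* form is used deliberately: a founder effect enriches the
   low-frequency spectrum relative to the population's own baseline. An
   *absolute* count excess additionally requires mutational input
   replenishing the spectrum between the split and the present, which this
   mutation-free, fixed-site-set model intentionally lacks; the relative
   excess is the signature the model can and should show.
3. **Selection detectability** — a planted category under purifying
   selection (default `lof_like`: 8% of sites, $s = 0.035$, i.e. roughly
   $e^{-3.5}$ cumulative frequency suppression over the branch) is ranked
   above the neutral categories by the enrichment scan's $z$, with the
   bottlenecked population as numerator. The mechanism is the one the
   analyses are designed to detect: selection holds these variants rarer,
   placing them where the founder effect's drift can lift them
   disproportionately, while in the constant-size branch selection keeps
   acting efficiently.

With the bottleneck removed (`bottleneck_size = pop_a_size`, no growth)
the check reports that no bottleneck is modelled and the share ratio sits
at 1 within noise.

What passing these checks does *not* show: agreement with any real
population's demographic parameters (the model is not calibrated to a real
isolate's history), robustness to genotyping artefacts, or behaviour under
linkage — real data features the generator does not emulate.

## Numerical and degenerate-input choices

* `read_vcf_pair()` treats a site present in one panel's VCF but not the
  other's as genotyped reference there (count 0, full allele number), the
  correct reading for jointly called panels; `strict = TRUE` errors
  instead. Missing genotypes (`./.`) reduce the allele number rather than
  being imputed as reference. Multi-allelic records are split per alt
  allele; indels and non-autosomal chromosomes are dropped with a message.
* BED intervals are 0-based half-open, VCF positions 1-based; the
  conversion happens exactly once, inside `annotate_categories()`.
* `filter_mac()` never alters counts, only membership.
* Ratio-of-counts intervals with a zero denominator are flagged
  `undefined`, not dropped.
* All randomness in a simulation flows from the single `seed` in
  `demography_model()`; equal seeds give bit-identical tables.

## Problem sizes used by the checks

The test suite exercises the statistics on tables of $10^3$–$10^4$ random
variants against brute-force oracles, runs the two-category test's type-I
error at 1000 null replicates, compares the delta-method interval with a
$10^5$-replicate parametric bootstrap, validates power against
$10^5$-replicate Wald simulations, and runs the full bottleneck property
check at 200 000 sites for three seeds — sizes chosen so the complete
suite runs in a few minutes on one CPU while keeping Monte-Carlo error
well inside every asserted tolerance.

## Known limitations

* The delta-method interval is first-order; at very small counts
  (category–bin cells below ~10) its endpoints drift from the exact
  binomial geometry, which is why zero cells are flagged rather than
  corrected by default.
* The simulator's fixed site set cannot show absolute low-frequency count
  excess (see above), only proportional excess.
* Fold-enrichment percentages for *categories* use the category's own
  total in the numerator population as denominator; published tables do
  not always state their denominator convention, so cross-study
  comparisons of category percentages should be made with care.
* The power model assumes the variant explains little phenotypic variance
  and ignores LD, imputation quality, covariates and relatedness.
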