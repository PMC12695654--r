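---
title: "Tracing hematopoietic stem cell clones: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing hematopoietic stem cell clones: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneTrace)
```

# The problem

Aged human hematopoiesis is dominated by expanded stem-cell clones, many of
them marked by somatic mutations in clonal-hematopoiesis (CH) driver genes
such as *DNMT3A* or *TET2*, others by passenger mutations of undetermined
significance (CH-US). Such a mutation is a heritable barcode: every cell
descending from the founding hematopoietic stem cell (HSC) carries it. By
measuring the mutant cell fraction (MCF) of the barcode in purified cell
populations — HSCs, megakaryocyte progenitors (MkP, the platelet lineage
proxy), erythroid progenitors (EP), mature myeloid cells, B cells and
T cells — one can ask which of the five major blood lineages an individual
HSC clone actually replenishes, and by placing the same barcode on a
phylogeny of single-cell-derived colonies one can ask *when* the clone was
founded.

`cloneTrace` implements the full analysis chain:

1. **Bayesian MCF estimation** from duplex droplet-digital-PCR (ddPCR)
   quadrant counts (`posteriorMcf`), with positivity calling by posterior
   overlap against a negative control (`positivity`).
2. **Lineage pattern classification** of each clone's five-lineage output
   into balanced, restricted, biased or unique patterns (`classifyPattern`,
   `patternCensus`).
3. **Phylogenetic dating**: genotype matrices from colony read counts
   (`buildGenotypeMatrix`), a perfect-phylogeny builder for clean synthetic
   matrices (`perfectPhylogeny`), conversion of mutation-count trees to an
   age scale from conception (`makeUltrametric`) and per-branch acquisition
   ages with Poisson confidence intervals (`dateMutation`, `datingCI`).
4. **Clade statistics**: the lineage-concordance permutation test
   (`concordanceTest`) and Moran's I with phylogenetic weights (`moransI`).
5. A **synthetic cohort generator** (`simulateDonor`, `simulateDdpcr`,
   `simulatePhylogeny`, `simulateColonyReads`) that emits ground truth next
   to every dataset, so each inferential step has a recovery target. The
   real study cohort is controlled-access; nothing in this package requires
   it.

# The ddPCR measurement model

A duplex well partitions the template into droplets read out in four
quadrants: double-negative, mutant-only, wild-type-only, double-positive.
With $\theta$ the MCF, $e$ the extraction efficiency (the per-molecule
probability-like multiplier with which target DNA ends up amplifiable in a
droplet; after whole-genome amplification it may exceed 1), $N$ cells
loaded, $D$ droplets, ploidy $p$ (2 for autosomes and the female X, 1 for
the male X/Y) and one mutant copy per mutant cell (heterozygosity; the
targeted regions are copy-number neutral), the per-droplet occupancies are

$$\lambda_m = N\theta e / D, \qquad \lambda_w = N(p - \theta)e / D,$$

and under Poisson partitioning the quadrant probabilities are
$(e^{-\lambda_m-\lambda_w},\,(1-e^{-\lambda_m})e^{-\lambda_w},\,
e^{-\lambda_m}(1-e^{-\lambda_w}),\,(1-e^{-\lambda_m})(1-e^{-\lambda_w}))$.
The likelihood of the observed quadrant counts is multinomial in these
probabilities; the prior is $\theta \sim \mathrm{Beta}(1,1)$ and
$e \sim \mathrm{Exp}(\text{mean } 1)$, weakly informative members of the
stated families (the study's exact hyperparameters live in a
controlled-access repository). The efficiency support is not truncated at 1
on purpose.

**Numerics.** The joint posterior is integrated on a deterministic grid —
401 $\theta$ points, quadratically spaced so resolution concentrates near
zero where clonal fractions of interest live, times 201 efficiency points
placed at equal-mass quantiles of the exponential prior. Grid integration
makes every estimate bit-reproducible; the 2-D posterior is smooth, and an
MCMC backend could be swapped in behind the same contract. The credible
interval is equal-tailed (2.5/97.5 percentiles of the marginal CDF with
linear interpolation); the interval type is a package choice.

**Positivity.** A well is compared with a negative control through the
overlap coefficient $\sum_i \min(f_i, g_i)$ of the two $\theta$ marginals:
overlap < 5% is positive, [5%, 20%) likely positive, [20%, 40%)
inconclusive, ≥ 40% negative; figures and the census collapse this to
binary with likely-positive counted positive, and inconclusive wells are
excluded from pattern calling (with a logged reason). When no measured
control well is available, `nullControlAssay` builds a matched wild-type
well by moving the mutant-positive droplets into the corresponding
mutant-free quadrants, preserving total droplets and wild-type occupancy.
The overlap is computed on $\theta$ marginals (not the joint), a package
choice where the procedure is underdetermined.

Two analytic conventions are exposed because downstream rules quote them:
MCF = 2×VAF on two-copy loci (= VAF on the male X), and the bulk-DNA cell
count 60 ng / 6.6 pg per diploid cell = 9,090 cell equivalents. Tracing
eligibility is MCF ≥ 2% for driver-marked clones and ≥ 1% for CH-US-marked
clones.

# Lineage pattern rules

Positive lineages are sorted by MCF (ties broken by the fixed precedence
P > E > M > B > T) and nearest-neighbour ratios computed; negative lineages
rank below any positive one, so a ratio against them is infinite. A gap is
a ratio strictly above 5 ("more than fivefold"); a named group additionally
requires its max/min MCF ratio strictly below 10. Only the canonical splits
{P,E,M,B}|{T} and {P,E,M}|{B,T} receive named labels (`PEMB_biased` /
`PEM_biased` when the bottom group retains detectable output,
`PEMB_restricted` / `PEM_restricted` when it is negative); any other gap
structure — e.g. a gap isolating {P,M}, or a secondary >5-fold gap between
B and T — is `other_unique`, mirroring the empirical observation that no
other restriction patterns recur. Both fold thresholds are strict
inequalities; the source wording ("more than fivefold", "less than ten")
supports strictness, and the brute-force equivalence suite pins the
behaviour at the boundaries. The call is invariant to common rescaling of
all MCFs.

A clone positive in T but not B with {P,E,M} more than fivefold above T is
treated as `PEM_biased` by symmetry with the B-positive case: bias needs at
least one suppressed-but-detectable bottom lineage, and restriction
accounts for the missing one.

# Phylogenetic dating

Colony genotypes follow fixed read-count rules (positive: VAF ≥ 0.15 and
≥ 2 mutant reads; negative: 0 mutant reads at ≥ 5 total; otherwise
unknown), and colonies with skewed carried-mutation VAF (median outside
[0.35, 0.65]) or mean depth below 8 fail the single-cell purity check.
`perfectPhylogeny` builds the tree whose clades are exactly the mutation
carrier sets; it demands nested-or-disjoint carrier sets (the four-gamete
condition with a wild-type root) and names the offending mutation pair
otherwise. Unknown entries are treated as non-carriers when forming carrier
sets: at the depths the generator simulates, matrices are near-complete and
this coincides with clade-majority imputation. Real cohorts use external
parsimony trees, read via `readCladeTree`, and skip this builder entirely.

**Age scaling.** Assuming a constant lifelong mutation rate, a
mutation-count tree is converted to an age axis running from conception
(time 0) to sampling at $S = \text{age} + 40\ \text{weeks} \times 7/365.25$
years. Ages are assigned top-down:
$$t_{\text{child}} = t_{\text{parent}} +
 (S - t_{\text{parent}})\,\frac{b}{b + \bar m_{\text{below}}},$$
with $b$ the branch's mutation count and $\bar m_{\text{below}}$ the mean
count from the child node down to its tips. This pins every tip exactly at
$S$, reduces to exact proportionality when all root-to-tip counts are
equal, and — unlike a one-shot normalisation by the mean root-to-tip count
below each node — cannot produce a child dated older than its parent when
sister subtrees have very different total counts. A root edge, when
present, is the branch out of conception carrying mutations shared by all
colonies.

**Dating conventions.** Driver mutations are dated at the distal end of
their branch (descendants replace ancestors, so the expansion starts no
earlier than the branch's end); midpoint and proximal conventions are
provided as sensitivity variants for CH-US mutations, which can arise
anywhere along a branch.

**Confidence intervals.** Each branch count $k$ gets the exact (Garwood)
Poisson interval $[\tfrac12\chi^2_{0.025}(2k),\ \tfrac12\chi^2_{0.975}(2k+2)]$
(lower bound 0 at $k=0$; upper bound 3.689). The lower age bound is read
off a perturbed tree with the root-to-node path at lower bounds and *all*
remaining branches at upper bounds, re-scaled to ultrametric form over the
same span; the upper bound reverses the roles. Perturbing every off-path
branch (not only those below the dated node) is required for the bounds to
actually bracket the recursive age, because off-path counts enter the
normalisation through the mean tip counts. An alternative interval built
around the expected count (tree-average rate × branch duration) sits behind
`method = "rate"`, default off, since the wording that inspired it is
ambiguous. Intervals widen monotonically as counts shrink at fixed
topology, and on simulated cohorts the true acquisition ages fall inside
the 95% interval in well over 90% of clones.

Clades enter tracing only at HSC MCF ≥ 2% (`cladeFilterForTracing`), the
same filter the ddPCR arm applies.

# Clade concordance statistics

For clades with ≥ 2 terminal clones whose positivity pattern is one of
all-positive, T-negative or B/T-negative, the concordance score is the
proportion showing the clade's modal pattern. The observed statistic pools
clades as an unweighted mean of per-clade scores (the aggregation is not
pinned down by the procedure's description; a clade-size-weighted mean is
available behind a flag). Each of the B = 10,000 null draws refills every
clade by sampling its size without replacement from the pooled clone labels
of all donors and scores the maximum pattern frequency; the empirical p
uses the add-one convention, so p ≥ 1/(B+1) and the test cannot report
zero.

Moran's I uses weights $w_{ij} = 1/(1 + d_{ij})$ on phylogenetic age
distances, zeroed across donors and on the diagonal, with clone values
taken as per-lineage MCF normalised to the HSC MCF. The statistic, its
expectation $-1/(n-1)$, the normality-assumption variance and a one-sided
(greater) p-value are computed from the standard definitions; a permutation
p is available via `nsim`. Values are analysed per lineage.

# What the synthetic cohort emulates — and what it does not

`simulateDonor` draws clones with HSC MCFs from a log-normal with
`meanlog = log(0.022)`, `sdlog = 0.8` (mean ≈ 3.0%, matching the reported
cohort mean of 3.03%), driver probability 47/57, and a default pattern mix
of (15 balanced, 13+12 PEMB restricted/biased, 7+6 PEM restricted/biased,
4 unique)/57 — the published census with the restricted/biased split, which
is not printed, divided near-evenly. Pattern effect sizes are rule-forced:
positive lineages draw factors U(0.5, 2) of the HSC MCF (max ratio 4,
inside both fold rules); biased top groups draw U(1, 2) while suppressed
lineages divide the HSC MCF by a shared U(6, 30) fold times U(1, 1.6)
per-lineage factors, guaranteeing the >5-fold gap without creating a
secondary gap inside the suppressed pair. Acquisition ages are uniform on
(10, age−5) years from conception.

`simulateDdpcr` implements two sampling paths — explicit Poisson molecule
counts scattered over droplets, and a single multinomial draw from the
closed-form quadrant probabilities — which are identical in distribution
and are tested against each other. Defaults: 14,000 droplets, 2,000 cells
per sorted population, efficiency drawn U(0.1, 0.9).

`simulatePhylogeny` is deliberately stylised: background lineages split in
one early developmental burst (0.3 years from conception) and each clone's
expansion is a single polytomy at its acquisition age, with branch counts
Poisson at 17 mutations/year (an order-of-magnitude adult HSC rate; the
value is configurable and no claim is attached to it). Clone stems carry at
least the clone-defining mutation; clones allocated fewer than two colonies
are flagged undetectable. `simulateColonyReads` draws per-entry depths
Poisson(meanDepth) and mutant reads Binomial(total, 0.5) for carriers —
reproducing the VAF-near-50% signature of single-cell colonies — or
Binomial(total, errorRate) otherwise.

What passing tests on this cohort do **not** show about real data: the
generator has no gradual coalescent structure inside clades, no
amplification artefacts or abnormal-fluorescence wells (the visual QC of
real plates is out of scope; only the ≥ 8,000-droplet filter is
implemented), no copy-number alterations, no storage-induced artefact
mutations, and mutation rates that are exactly constant rather than merely
approximately so. Recovery results are statements about the correctness of
the estimators under their own model assumptions, not about robustness to
these real-world violations.

# Problem sizes used in the test-suite and validation runs

Chosen so the whole suite runs comfortably on a single CPU: quadrant
closed-form vs Monte-Carlo at 10^6 droplets; MCF recovery over 200 assays
spanning θ from 0.001 to 0.5 (bias < 0.02, 95%-interval coverage within
[0.90, 0.99]); classification equivalence over all 2^5 positivity patterns
× quantised MCF grids straddling both fold thresholds; perfect-phylogeny
recovery at sequencing depth 40 where the per-entry dropout probability
(~e^{-depth/2}) is negligible, so "error-free" matrices are actually
complete; dating-interval coverage over 100 donors × 30 colonies; and
type-I error of both clade tests over 2,000 null cohorts each (rejection at
α = 0.05 required to stay within [0.03, 0.07]; the permutation test is
slightly conservative by discreteness and the add-one convention).

# Known limitations

- The positivity rule compares θ marginals; if the study compared joint
  posteriors the overlap would differ slightly in wells where efficiency is
  poorly identified.
- The perfect-phylogeny builder is for clean matrices only; it has no error
  tolerance and is not a substitute for parsimony search on real colonies.
- The "likely negative" category mentioned alongside the binary collapse is
  resolved as: ≥ 40% overlap is negative, inconclusive wells are excluded.
- Serial-sample stability models, mixed models for lineage ratios versus
  age, xenograft concordance models, signature fitting and structural-variant
  analysis are out of scope.
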