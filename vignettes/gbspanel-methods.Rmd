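---
title: "Models and methods behind gbspanel"
author: "gbspanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gbspanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gbspanel` characterizes large inbred genotyping-by-sequencing (GBS)
panels. This vignette records the statistical models the package
implements, the conventions it fixes where the underlying procedures are
ambiguous, and what its synthetic-data tests do and do not demonstrate
about real data.

# The data model

A `GenotypePanel` stores one diploid call per (site, sample): homozygous
first allele (0), heterozygous (1), homozygous second allele (2), or
missing. Sites are biallelic SNPs sorted by chromosome (natural order) and
1-based position; duplicate positions are rejected. Allele frequencies,
MAF and dosage are always recomputed from the calls at hand and never
stored, so subsetting can never leave stale summaries behind.

Because the panels of interest are inbred lines, most analyses begin by
*haploidization* (`haploidize()`): each line is treated as a random sample
of a single haplotype from its population, and residual heterozygous calls
— which in inbreds mostly reflect incomplete fixation or collapsed
paralogs rather than usable phase information — are set to missing.
Functions that must *not* haploidize (IBS with allele-sharing weights, the
panmixia coefficient, allele presence, concordance) operate on the diploid
codes directly.

# Site filters

`siteSummary()` computes, among non-missing calls at a site: call rate,
the first-allele frequency $p$ (a heterozygote contributes one copy of
each allele), MAF $= \min(p, 1-p)$, observed heterozygosity $H_O$,
expected heterozygosity $H_E = 2p(1-p)$, and the coefficient of panmixia
$1 - H_O/H_E$. The discovery filter keeps a site iff call rate $\ge$ 10%,
panmixia $\ge$ 0.8 and MAF $\ge$ 0.2%.

Numerical conventions, fixed once:

- All thresholds are **inclusive**. The sources state values, not
  strictness; inclusive comparisons make the boundary cases testable.
- A monomorphic site has $H_E = H_O = 0$; its panmixia is **defined as
  1** (fixation is maximally consistent with inbreeding) rather than 0/0.
- Panmixia is stored clamped to $[0, 1]$; the unclamped value (negative
  under excess heterozygosity) is kept in `panmixia_raw` for auditing.
  Clamping cannot change any filtering decision at the 0.8 threshold.
- All-missing sites are flagged `defined = FALSE` and never kept.

## The biparental error-correction filter

A SNP that appears polymorphic inside a biparental family where it cannot
truly segregate is evidence of genotyping error or paralog collapse. For
each family the within-family MAF is computed on haploidized calls; the
family is *segregating* iff that MAF $\ge$ 0.15 (inclusive). The
site-level apparent error is aggregated across non-segregating families by
**max** — the conservative choice; the sources do not state max versus
mean — and the site fails when it exceeds 0.01.

The complementary LD test asks whether a SNP that does segregate shows
local linkage: within each segregating family, r² between the focal SNP
and a window of one-twentieth of the chromosome's SNPs (centered on the
focal SNP by index; the nearest SNPs by index distance, ties toward the
lower index, truncated windows extending into the available side), with
SNPs within 100 kb of the focal position excluded as protection against
local assembly-order errors. The median within family, then the median
across families, must reach 0.5. Chromosomes with fewer than 20 SNPs use
all SNPs minus the exclusion zone.

Open points decided here: families with fewer than 10 genotyped members at
a site are not assessed (the sources are silent; small families cannot
distinguish segregation from error); and a SNP segregating in **no**
family passes the LD component by vacuity (`vacuous_ld_pass = FALSE`
inverts this, for users who prefer to demand positive evidence).

# Window imputation

The panel is partitioned into consecutive windows of 1,024 SNPs that never
span a chromosome boundary (a biologically motivated restriction; the
sources do not state one). For each (sample, window) with missing calls,
the donor minimizing the mismatch fraction over jointly non-missing
haploidized calls is selected; ties are broken by larger overlap, then
lexicographic donor id, so runs are exactly reproducible. A donor is
**vetoed** above 5% mismatch, and donors sharing fewer than
`min_overlap = 32` jointly called sites are never considered — a guard
against spurious zero-mismatch matches on tiny overlaps (the sources state
no floor; 32 of 1,024 sites keeps the binomial error of the mismatch
estimate below ~4 percentage points at the veto boundary). Mismatch is
computed on intersections of non-missing calls; accepted donors donate
their calls only into the target's missing cells, so observed calls are
never altered and donor-missing cells stay missing.

`evaluateImputation()` scores deliberately masked cells: the error rate is
wrong-imputed / imputed, with a heterozygote-excluded variant dropping
cells heterozygous in truth or imputation.

# Relatedness

**IBS** uses allele-sharing weights per jointly called site: 1 for equal
genotypes, 0.5 for a heterozygote against either homozygote, 0 for
opposite homozygotes. For inbred panels this is nearly haploid matching;
the diploid weights matter only at residual heterozygotes.

**IBD** is estimated, on LD-pruned sites, by the three-state method of
moments: $\hat\pi = P(Z{=}1)/2 + P(Z{=}2)$, where $P(Z{=}0)$ is read off
the opposite-homozygote count against its expectation for unrelated
pairs, $P(Z{=}1)$ off the one-shared-allele count after removing the
$Z{=}0$ contribution, and $P(Z{=}2)$ is the remainder. The classical form
computes the unrelated-pair expectations from Hardy–Weinberg allele-
frequency products; for fully inbred lines those products are badly wrong
(the chance that two unrelated inbreds are opposite homozygotes is $2pq$,
not $2p^2q^2$), which would make $\hat\pi$ under-estimate pedigree
sharing. `gbspanel` therefore computes the $Z{=}0$ expectations from
**observed per-site genotype frequencies** (default
`freq_model = "genotype"`), which reduces to the classical products under
Hardy–Weinberg equilibrium and stays consistent under inbreeding; the
classical mode is retained as `freq_model = "hwe"`. Estimates are clamped
to $[0, 1]$ with raw values kept for audit. Under this estimator a line
derived by four backcrosses shows $\hat\pi \approx 1 - (1/2)^5 = 0.969$
against its recurrent parent, the "97% identical" pedigree benchmark.

**LD pruning** slides a 100-SNP window by steps of 25 and greedily removes
the later member of any surviving pair with r² above 0.2 — guaranteeing no
window instance retains such a pair (pairs that never co-occur in a window
are, by design, not constrained).

**Duplicate merging** single-links pairs at IBS $\ge$ 0.99 and collapses
each cluster to a consensus: the unanimous non-missing call, missing on
conflict. Merging is by genotype only; accession names are metadata here.

**Ordination** is classical metric principal coordinates (Gower
double-centering and eigendecomposition) of $1 -$ IBS, with an optional
non-metric refinement (Kruskal stress minimization initialized at the
metric solution). The two are not claimed equivalent; the metric solution
is the default because it is deterministic and satisfies the
reconstruction identity used in the tests.

# Diversity statistics

**Weir–Cockerham θ.** On haploidized calls each line is one allele draw,
so the variance-components estimator takes its haploid form: with $r = 2$
groups of $n_1, n_2$ called lines and allele frequencies $p_1, p_2$,

$$\mathrm{MSP} = \sum_i n_i (p_i - \bar p)^2, \qquad
  \mathrm{MSG} = \frac{\sum_i n_i p_i (1 - p_i)}{\sum_i (n_i - 1)},$$

$$\hat\theta = \frac{\mathrm{MSP} - \mathrm{MSG}}
                    {\mathrm{MSP} + (n_c - 1)\,\mathrm{MSG}},
  \qquad n_c = N - \tfrac{\sum_i n_i^2}{N}.$$

Per-window values are the **unweighted mean** of per-site θ (matching the
"average per window" presentation); the multi-locus ratio-of-sums
$\sum a / \sum d$ is also reported and is the genome-wide estimate used in
recovery tests, because it is the standard weighting when sites vary in
information. Sites need $\ge 2$ called lines per group.

**Nucleotide divergence** per 1-Mb window is $1 -$ mean cross-group pair
IBS on haploidized calls; pair-windows with fewer than 10 jointly called
sites are excluded (the sources state no floor; 10 keeps a single
discordant call from implying 10% divergence).

**Haplotype lengths.** A draw picks a random focal SNP and two random
group members, compares haploidized genotypes at the focal site and
extends outward until they differ, with **one mismatch forgiven per
side**; missing-in-either sites are skipped, counting neither as match nor
mismatch (treating them as mismatches would confound missingness with
diversity). Conventions pinned by an exact-enumeration oracle:
`length_sites` counts compared-and-matching sites including the focal
site; forgiven mismatches are not counted; a mismatch at the focal site
itself consumes the forgiveness of both sides and the draw floors at
length 1; `length_bp` spans the terminal matching sites; draws are
assigned to genome intervals by the **median position of their matching
sites**. Lengths are reported both in SNPs and bp. No allele-frequency
filtering precedes the calculation.

**LD decay** filters sites with more than 25% missing data or MAF below
0.05, then draws 180 lines (groups of different sizes would otherwise not
be comparable; smaller groups are used whole, with a warning), computes
pairwise r² on haploidized dosages within a maximum distance, and
summarizes per distance bin as mean, median, and central 50%/90% ranges.
Bins are log-spaced by default — decay is fastest at short range — with
linear bins and explicit edges available.

**Window rank correlations** use Spearman's ρ with ties mid-ranked,
reported alongside ρ² so scans can be compared on the determination scale.

# The synthetic generator

`simulateStructuredPanel()` is a Balding–Nichols drift model: ancestral
frequencies uniform on $[0.05, 0.95]$ (wide enough to be informative at
every site; the real site-frequency spectrum is far more rare-shifted, see
limitations), subpopulation frequencies
$p_g \sim \mathrm{Beta}\!\big(p \tfrac{1-F}{F},\, (1-p)\tfrac{1-F}{F}\big)$
with $F$ the target fixation index — the closed-form link that makes the
Weir–Cockerham recovery test exact in expectation. Lines draw one
haplotype and double it; residual heterozygosity (default 0.5% of calls)
and base-call errors (default 0.18%, the repeated-sample error rate
typical of GBS) are injected afterwards. An injected error flips a
homozygote to the opposite homozygote, the signature of a miscalled base
on an effectively haploid low-coverage call; this makes the apparent
family MAF of error sites equal the error rate after haploidization.

Pedigree simulators place a Poisson number of crossovers (default 2 per
chromosome per meiosis) uniformly in bp — a uniform genetic map; real
recombination-rate variation is emulated only by
`simulateFounderMosaicPanel()`, whose per-gap founder-switch probability
can be suppressed regionally to create pericentromere-like long-haplotype
regions. Backcross derivation doubles a final gamete ("selfing to
fixation"), so the expected recurrent-parent fraction after $b$
backcrosses is exactly $1 - (1/2)^{b+1}$, and the realized fraction is
tracked per site through every meiosis.

Missingness (`maskGenotypes()`) draws per-sample target call rates
uniformly from $[0.02, 0.75]$, the coverage range of single-run GBS
samples, and hides exactly the complementary number of calls, recording
every hidden cell so masking is invertible bit-exactly. The
`genotype_bias` multiplier reduces a sample's call rate in proportion to
its haploid distance from a designated reference line, mimicking the
reference-alignment and presence/absence effect that costs
reference-distant lines coverage; how strongly missingness covaries with
reference distance in real data is not quantified in the sources, so the
multiplier is a free modeling knob, default off.

For haplotype-length ground truth the package plants **exact** shared
blocks: `simulateHaplotypeBlockPair()` builds two lines agreeing in blocks
of exactly $L$ SNPs separated by fully discordant gaps, so every
focal-match draw must return $L$. A literal founder-block panel would
instead yield $L$ times a run-length factor (consecutive blocks can share
a founder), which is why the planted-pair design is used for recovery
tests and the founder mosaic for decay-shape tests.

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each recovery is statistically sharp: drift
recovery on 3 × 60 lines and 5,000 SNPs; imputation on a fully duplicated
120-line, 4,096-SNP panel masked to 35% call rate; pedigree expectation
over 1,000 replicates on a 10-chromosome genome; haplotype recovery from
500 draws on planted blocks of 50 and 500 SNPs. Every stochastic function
takes an explicit seed; identical seeds and configurations reproduce
outputs exactly, including donor choices and LD-decay curves (sample
order is normalized before subsampling).

# What passing tests do and do not show

The generator reproduces the statistical structure the analyses assume —
drift-distributed frequencies, IBD mosaics, family segregation, coverage
heterogeneity, homozygote-flip errors. It does **not** reproduce: the
rare-shifted site-frequency spectrum of a real collection (ancestral
frequencies are uniform), linked selection or domestication sweeps,
presence/absence variation as a *biological* source of missingness
(masking hides calls at random given the per-sample rate; imputation can
therefore never "over-impute" truly absent loci here, a failure mode real
panels do have), sequencing-batch effects, or reference-genome
ascertainment of SNP discovery. Recovery of a parameter under the
generator demonstrates the estimator and its implementation, not the
field performance of GBS on any particular germplasm.

Known limitations: the IBD moment estimator assumes the panel's genotype
frequencies describe the "unrelated" background, so in a panel composed
mostly of close relatives pi-hat is biased toward its relatives; windowed
LD pruning constrains only pairs that co-occur in a window instance;
consensus merging can lower the call rate below a member's at sites where
members conflict; and the haplotype-length conventions at focal
mismatches, while pinned and documented, are one of several defensible
readings of the verbal procedure.
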