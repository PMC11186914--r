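---
title: "Envirotyping a multi-environment trial and classifying QTL stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envirotyping a multi-environment trial and classifying QTL stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metenviro)
```

## The problem

Seed yield of winter oilseed rape is shaped by a genetic effect (G), a
large environmental effect (E) that mixes pedoclimatic conditions with
nitrogen management, and their interaction (G×E). A multi-environment
trial (MET) — a grid of `year × location × nitrogen regime` combinations —
lets a breeder ask which yield QTL are *stable* (expressed across the
network) and which are *interactive* (expressed only under a particular
combination of stresses). Interpreting interactive QTL requires knowing
*what* stressed each environment, which is what envirotyping provides:
environments are first described by agro-pedoclimatic indicators, the
indicators that actually limited yield are identified, and environments
sharing a limiting-factor pattern are grouped into *envirotypes*.
Association scans run at three nested scales — each single environment,
each envirotype, and the whole MET — and a QTL region's detection pattern
across scales determines its stability class.

`metenviro` implements this entire chain as composable functions plus a
seeded synthetic-MET generator, so that every stage can be validated
against a known ground truth without any external data.

## Environmental indicators

Daily weather (temperatures, rainfall, reference evapotranspiration
`ET0`, solar radiation) is summarized over the crop-cycle periods: fall
(F), climatic winter (CW), bolting (B), flowering (FLO), seed-number
fixation (P300), pod reserve allocation (P600) and seed growth (P1000).
Period boundaries are inputs: in a real MET they are fixed from phenology
observations of probe cultivars, and the package does not predict them.

The thirteen limiting indicators computed by default are the temperature
summaries (`TMN_CW`, `TMAX_B`, `TMAX_FLO`, `TMAX_P300`, `TMIN_P600`),
heat-day counts at flowering (`HT_FLO`, days with `tmax > 25` °C),
radiation at flowering (`SSR_FLO`), water status (`WSC_MAX`, the soil's
maximal water capacity in mm, and `WD_P600`, days with an empty water
bucket during pod fill), vernalization fulfilment (`VERN`), and the
nitrogen indicators (`NNI`, `N_total`, `DAI`).

Water-dependent indicators rest on a deliberately simple single-bucket
balance: `WSC_t = clamp(WSC_{t-1} + rain_t - ET0_t, 0, wsc_max)`,
initialized at field capacity, with a *leaching day* flagged whenever the
pre-clamp content exceeds the capacity. A multilayer soil model would be
more realistic but is not needed for the day-counting indicators built on
top of it. Two further conventions matter and are exposed as constants or
arguments:

* a day is "rain-free" when rain < 0.1 mm (a trace threshold, so the
  dryness indicators do not flip on floating-point noise in rain
  records);
* `VERN` is the fraction of a vernalization requirement met — days with
  mean temperature in [0, 7] °C during F+CW divided by a requirement
  (default 40 days), capped at 1. The cap means fully-vernalizing
  networks show a constant indicator; constant indicators are dropped
  before regression and map to the neutral value 5 in profiles.

Nitrogen is supplied one to three times per trial, so the per-supply
water indicators (`DBI`, `DAI`, `RF`, `RO`, `WSC_I`) are aggregated into
one trial-level value as a supply-weighted mean,
`sum_i value_i × N_i / N_total`, fixed to 0 for unfertilized trials. The
windows are day-resolved closed intervals and the supply day itself
belongs to the "after" window.

Missing indicator cells (e.g. `NNI` not measured in some trials) are
completed by a regularized iterative principal-component reconstruction:
columns are standardized, missing cells initialized at the column mean,
and the rank-*k* truncated-SVD reconstruction (default *k* = 2) is
re-imputed into the missing cells — with the column means re-estimated
from the completed matrix at each pass, so the centring is
self-consistent at convergence (tolerance 1e-6, at most 500 iterations).
Observed cells are never altered.

## Limiting factors and envirotypes

The limiting factors are found by univariate partial least squares
(PLS1): per-environment mean yield of probe genotypes is regressed on the
standardized indicator matrix using the NIPALS algorithm with deflation.
The number of latent components is chosen by 5-fold cross-validation (up
to 5), then backward elimination repeatedly drops the variable with the
lowest VIP (variable importance in projection), refits, and tracks the
cross-validated RMSE of every visited subset; the returned set minimizes
CV-RMSE, with exact ties broken toward the smaller set and elimination
never passing below one variable. The fold assignment is seeded, making
the whole selection deterministic. With all components retained, PLS1
reproduces ordinary least squares on full-rank designs — one of the
package's oracle tests.

Environments are clustered on their standardized limiting-factor values
with Ward linkage on Euclidean distance. When the number of envirotypes
is not given, it is chosen from the inertia-gain curve: writing g(k) for
the within-cluster inertia explained by moving from k−1 to k clusters,
the package picks the k in [2, min(10, n−1)] with the largest relative
drop (g(k) − g(k+1))/g(k) — an explicit form of the usual elbow read off
a dendrogram. Degenerate inputs with zero total inertia fall back to
k = 2. Profiles for interpretation min–max scale, per indicator, the set
of envirotype means plus the overall mean onto [0, 10]; an indicator
constant across envirotypes maps to 5 everywhere.

## Mixed models, BLUEs and heritability

Three model families are fitted by REML (via `lme4`):

* per environment: `Y = μ + G + R + ε` with replicate and residual
  random — genotype BLUEs and plot-level heritability
  `h² = σ²G / (σ²G + σ²ε / r)`;
* per envirotype and MET-wide: `Y = μ + G + E + G×E + R(E) + ε` —
  BLUEs from the fixed-genotype fit, and
  `h² = σ²G / (σ²G + σ²GxE / e + σ²ε / (r·e))` with `e` environments and
  `r` replicates (the interaction divisor is taken equal to `e`; the
  median replicate count is used when unbalanced);
* the envirotype-aware partition of the whole MET:
  `Y = μ + G + En + En(E) + G×En + G×En×E + R(En×E) + ε`.

Variance-percentage tables always come from all-random refits; the
fixed-genotype fits are reserved for BLUEs. This all-random convention is
applied uniformly because a percentage-of-variance table is only
well-defined when every term has a variance. In the fixed-genotype group
fit the genotype-by-environment term is not separable from the plot error
and is left in the residual; on balanced complete designs this does not
move the BLUEs, which reduce to genotype means (a closed form the package
uses directly on such designs, and which the REML route must match to
1e-8 in the tests). BLUEs are reported as `μ + ĝ` so they live on the
trait scale.

A derived quantity of interest is the share of environmental variance the
envirotyping explains, `100·En/(En + En×E)`, and its interaction
analogue `100·G×En/(G×En + G×En×E)`. Finally, a QTL×E partition
(`Y = μ + G + E + marker×E + R(E) + ε`, all random) quantifies how much
of the total variance the interaction between one marker's dosage and the
environment explains.

## Association scans and stability classes

SNPs are filtered at MAF ≥ 2.5% and missingness ≤ 10%, then mean-imputed
per SNP (a deliberate simplification of haplotype-based imputation; with
array-scale data a dedicated imputation tool should be preferred
upstream). Kinship uses the allele-frequency-standardized cross-product
`K = (1/M) Σ (x − 2p)(x − 2p)ᵀ / (2p(1−p))`, and scans on chromosome *c*
use the leave-one-chromosome-out (LOCO) kinship built from all other
chromosomes, so the tested chromosome's own signal is not absorbed by the
polygenic term.

The scan itself is the spectral mixed-model algorithm: per chromosome the
LOCO kinship is eigendecomposed once, the variance ratio
`δ = σ²ε/σ²g` is REML-estimated under the intercept-only null, and every
SNP is tested by weighted least squares in the rotated basis at that
fixed δ. The squared Wald statistic is referred to F(1, n−2), which makes
the scan collapse *exactly* onto ordinary simple regression when the
kinship is the identity — the package's strongest scan oracle. Estimating
δ once per (scale, chromosome) and reusing it per SNP is the standard
fast mode; re-estimating δ for every SNP moves individual −log10 p values
a little on small panels (the test suite pins the median displacement
below 0.05 on a 50-genotype fixture) while the dense-matrix GLS oracle at
the null components is matched within 0.2 everywhere.

Multiple testing uses the effective number of independent tests: within
consecutive blocks of at most 1,000 SNPs per chromosome, the eigenvalues
of the dosage correlation matrix (composite LD, appropriate for unphased
data) are accumulated until they reach 99.5% of the trace, and the block
counts are summed into `M_eff`. The genome-wide threshold is
`t = −log10(α_G / M_eff)` with α_G = 0.1 per scan.

Significant SNPs are chained into intervals while consecutive gaps stay
within 500 kb (a default chosen so that multi-megabase regions reported
for dense panels would chain; it is an explicit argument), and intervals
from different traits/scales that overlap on a chromosome merge into one
region carrying all its detections. Classification then reads the
detection pattern: *stable* if detected at the MET scale or in at least
two envirotypes; *interactive* if detected in exactly one envirotype and
not at the MET scale; *environment-specific* if detected only in single
environments. The favorable allele is the trait-increasing one at the
peak SNP, reported as major/minor by frequency.

## Diversity statistics

The panel is split at 18 µmol/g seed glucosinolate (strictly greater =
GSL+), a proxy for pre- versus post-quality-breeding germplasm. Per-site
nucleotide diversity uses the unbiased pairwise form
`π = 2p(1−p)·n/(n−1)` with `n` the called alleles (missing genotypes
reduce `n`; diversity statistics use raw calls, never the GWAS-imputed
matrix). Windowed π divides the summed site π by the full 10 kb window
length, counting invariant sites as zero diversity; chromosome and genome
values divide by the total covered length, so the genome value is exactly
the length-weighted mean of chromosome values.

Differentiation uses the Weir–Cockerham (1984) two-population estimator:
per polymorphic site the components a (among populations), b (among
individuals within) and c (within individuals) are formed from sample
sizes, allele frequencies and observed heterozygosities, and
`θ̂ = a/(a+b+c)`. "Mean F_ST" is the unweighted mean of per-site θ̂ —
matching the common toolkit output — while the ratio-of-sums
`Σa / Σ(a+b+c)` is also reported. The two differ in finite samples: the
per-site mean sits a little below the simulated differentiation parameter
(low-frequency sites pull it toward zero) while the ratio-of-sums is
nearly unbiased; both are exposed so the reader can choose.

## The synthetic MET generator

The generator is first-class, tested code; its defaults define the study
conditions every validation runs under.

**Design.** Environments (default 22; the classification suites use 16)
are spread evenly over envirotypes (default 4) and assigned N⁺/N⁻
regimes, with N⁻ receiving 80–100 kg/ha less nitrogen. Because nitrogen
stress is itself part of a limiting-factor pattern, each envirotype leans
3:1 toward one regime rather than being regime-pure — the composition
observed in real envirotyped networks.

**Weather built backwards from templates.** Each envirotype is a template
vector over the 13 limiting indicators. Template offsets are drawn as
random *orthogonal* directions in indicator space, scaled (default 1.75
template-spread units per indicator) so templates are equidistant and
several within-type standard deviations apart — the regime in which
envirotypes are meaningful at all. Daily weather is then generated so the
indicator stage recovers the template: period temperatures are shifted to
the target means, maxima/minima pinned by a designated extreme day,
heat-day counts at flowering planted directly, flowering radiation set to
the target sum, P600 rain thinned according to the water-deficit target,
and the rain pattern around N supplies arranged to the dryness target.
Within-envirotype variability (`envirotype_sd`, default 0.25 of the
template spread) is a free parameter — real networks do not pin it down —
and the realized weather adds further noise on top, most visibly for
`WD_P600` and `TMAX_FLO` (which is floored by the planted heat days,
mimicking the correlated indicators of real data). `VERN` is typically
constant at 1 under the default mild winters, exercising the
constant-indicator paths downstream.

**Genotypes.** Inbred-line dosages in {0, 1, 2} with residual
heterozygosity ≤ 2%: SNPs sit at fixed 12.5 kb spacing in haplotype
blocks (default 20 SNPs) carrying two complementary founder haplotypes at
a frequency drawn from `maf_range`; accessions copy one founder per block
(two independent copies at the `het_rate`), and rare flips to the
opposite homozygote (1%) decay within-block LD slightly below 1. This
block-copy model is not a coalescent — it is exactly enough LD structure
to exercise the effective-test correction, region chaining and
block-resolution QTL localization at desk scale.

**Phenotypes with exact variance bookkeeping.** Seed yield is a sum of
independent components — genotype (polygenic plus stable QTL), envirotype,
environment-within-envirotype, genotype×envirotype (interactive QTL plus
noise), genotype×environment, replicate and residual — each projected
onto its model subspace (interactions double-centred, nested terms
centred within their parent) and rescaled so its mean square per model
degree of freedom equals the configured fraction of the total variance
(default total 60 (q/ha)², mean 30.35 q/ha). That mean-square-per-df
scale is precisely what a variance-component estimator recovers, so the
realized fractions sit on the targets up to estimation noise and the
recovery suites can use tight tolerances without luck. The polygenic
background is orthogonalized against planted stable QTL so each QTL
explains exactly its configured share of Var(G); interactive QTL add
their effect only inside the target envirotype, sized to the configured
share of Var(G) there. Thousand-seed weight is lognormal around 4.5 g so
the derived seed number `SN = SY × 100000 / TSW` is exercised.

One parameterization subtlety deserves emphasis. Because envirotype
values are shared across a type's environments, the variance the *plain*
MET model recovers for E is a design-dependent linear combination of the
two nested components — smaller than their sum. Published MET tables show
the same asymmetry between the two model families fitted to identical
data. `model5_variance_targets()` inverts the relation, returning
generator targets whose fitted plain-model percentages land on a
requested plain-scale profile; `met_variance_profile()` is the
envirotype-aware default.

**Divergent populations.** For the diversity stack, two populations are
simulated under the Balding–Nichols model: ancestral frequencies uniform
on (0.05, 0.95) and population frequencies
`Beta(p(1−F)/F, (1−p)(1−F)/F)`, with Hardy–Weinberg genotypes within
populations.

## What the validations do and do not show

Every generator is a pure function of (configuration, seed); all
validation is at desk scale, chosen so the full suite runs in minutes on
one CPU: variance recovery uses 20 seeded METs of 16 environments × 100
accessions × 2 replicates; QTL classification uses 20 METs of 16
environments, 4 envirotypes, 150 accessions and 2,000 SNPs with a stable
QTL at 12% and an interactive QTL at 20% of Var(G); F_ST recovery uses
2,000 SNPs × 60+60 individuals over 10 seeds. Under those conditions the
planted stable and interactive QTL are classified correctly in ≥ 90% and
≥ 80% of runs and the variance fractions are recovered within ±5 points
(mean absolute error ≤ 3).

The generator emulates the *structure* of a real MET — nested variance,
envirotype-patterned weather, blocky LD, regime-linked nitrogen — but not
its texture: no spatial field trends, no phenology feedback of weather on
period boundaries, no allele-frequency spectrum from demography, no
correlated measurement error. Passing these suites therefore shows the
statistical machinery is implemented correctly and is well calibrated
under the stated conditions; it does not show that any particular real
network contains four envirotypes, nor that real QTL of a given effect
size will be detected at these rates.

## Numerical and degenerate-input conventions

* REML fits constrain components to ≥ 0 (boundary estimates are reported
  as 0); confounded random terms are rejected up front with the pair
  named.
* The scan's δ is optimized on the log scale over [1e-5, 1e5]; SNPs
  monomorphic in the scanned subset return NA rather than a spurious
  p-value.
* Ties in backward elimination go to the smaller variable set; the elbow
  falls back to k = 2 when total inertia is zero.
* Sites monomorphic over the pooled sample are excluded from F_ST;
  `a + b + c = 0` sites are skipped; small negative θ̂ values are kept
  (they belong to the estimator).
* Region merging is idempotent and independent of scan input order;
  empty region tables are legal output.

## Reproducing the analysis

The `analysis/` directory holds the numbered drivers
(`01_simulate.R` … `06_diversity.R`) that run the whole chain on the
demonstration MET and write their tables under `results/`;
`scripts/acceptance.R --seed <s> --out <path>` recomputes the package's
headline quantities from scratch and writes them as JSON.
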