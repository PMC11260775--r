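---
title: "Two-sample Mendelian randomization with mrkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. For SNP $j$, write $\gamma_j$ for its
effect on the exposure (in SD units of the exposure trait, with standard
error $\sigma_{Xj}$) and $\Gamma_j$ for its effect on a binary outcome (in
log-odds units, standard error $\sigma_{Yj}$), each taken from an
independent GWAS. If the instrument is valid — associated with the
exposure, independent of confounders, and affecting the outcome only
through the exposure — then $\Gamma_j = \theta\,\gamma_j$, where $\theta$
is the causal log-odds of the outcome per 1 SD increase in the exposure.
A variant that additionally affects the outcome through another pathway
carries a direct (horizontally pleiotropic) effect $\delta_j$, so that
$\Gamma_j = \theta\,\gamma_j + \delta_j$; everything in the sensitivity
battery exists to detect or tolerate non-zero $\delta_j$.

`mrkit` implements the full two-sample workflow on summary statistics:
instrument selection and LD clumping against a local reference panel,
proxy substitution, allele harmonization, four estimators of $\theta$,
heterogeneity/pleiotropy/outlier diagnostics, trait-category exclusion
re-analyses, instrument strength and power.

## Instrument selection

SNPs passing genome-wide significance (`p_select = 5e-8`) are clumped
greedily: the remaining SNP with the smallest p-value becomes an index
SNP, and every SNP on the same chromosome within $\pm$`window_kb`
(default 10,000 kb) whose $r^2$ with the index exceeds `clump_r2`
(default 0.001) is discarded. $r^2$ is the squared Pearson correlation of
unphased allele dosages in the reference panel (composite LD); the panel
can equally be supplied as precomputed $r^2$ records. Equal p-values are
broken by position, then rsid, so clumping is deterministic; SNPs absent
from the panel are conservatively dropped by default, since silently
retaining them could violate the mutual-independence assumption of the
downstream estimators.

Instruments missing from the outcome study can be recovered through a
proxy: the outcome SNP with the highest $r^2 \ge$ `proxy_min_r2`
(default 0.8) with the target, ties broken by genomic distance and then
rsid. The sign of the dosage correlation maps the proxy's counted allele
onto the target's counted allele, so the substituted record is expressed
directly on the target's alleles.

## Harmonization

Exposure records are never altered; outcome records are swapped,
sign-flipped and/or strand-complemented until both studies refer to the
same effect allele. Palindromic variants (A/T, C/G) are the delicate
case: their allele labels are identical on both strands, so orientation
must be inferred from allele frequencies. The rule used here infers
orientation only when the minor allele frequency is below
`palindromic_maf = 0.3` in *both* studies, adopting the orientation that
makes the effect-allele frequencies concordant (same side of 0.5);
otherwise the variant is dropped as ambiguous. Blanket removal of
palindromic SNPs would discard recoverable instruments; inference near
MAF 0.5 would be guesswork — 0.3 is the conventional compromise and the
threshold is exposed. Every input SNP is accounted for in an audit table
(kept, or dropped with a reason), and the kept+dropped counts always sum
to the input count.

Instrument strength is summarized by the variance in the exposure
explained per SNP, $r^2_j = 2\beta_j^2 x_j(1-x_j)$ with $x_j$ the MAF and
$\beta_j$ the SD-unit effect, and by
$F = (R^2/k)\,/\,((1-R^2)/(n-k-1))$. Some reports omit the factor 2 in
the per-SNP formula; both conventions are implemented
(`formula = "standard"` vs `"as_printed"`), with the factor-2 version the
default because it is the textbook variance of a Hardy–Weinberg genotype
effect on a unit-variance trait.

## Estimators

All estimators consume the harmonized table; per-SNP Wald ratios are
$\hat\theta_j = \Gamma_j/\gamma_j$ with first-order delta-method SE
$\sigma_{Yj}/|\gamma_j|$ (adequate here because the pipeline targets
strong instruments; second-order terms matter only near weak-instrument
regimes).

**IVW.** $\hat\theta = \sum_j w_j\gamma_j\Gamma_j / \sum_j w_j\gamma_j^2$
with $w_j = \sigma_{Yj}^{-2}$ — weighted regression through the origin.
The default is a multiplicative random-effects model: the fixed-effect SE
is inflated by $\max(1, \sqrt{Q/(J-1)})$, so heterogeneity widens the
interval but under-dispersion is never rewarded. p-values are normal;
CIs are $\hat\theta \pm z_{0.975}\,\mathrm{SE}$, exponentiated for odds
ratios.

**MR-Egger.** Weighted least squares of $\Gamma_j$ on $\gamma_j$ *with*
an intercept; the slope estimates $\theta$ under the InSIDE assumption
and the intercept estimates average directional pleiotropy. Each pair is
first oriented so $\gamma_j > 0$, which makes the fit invariant to
arbitrary allele orientation. SEs use the residual-based $Q$ on $J-2$
degrees of freedom with the same clip-at-1 scaling, and p-values use the
t distribution with $J-2$ df. An exact fit (zero residual) is handled
explicitly rather than dividing by a zero residual scale; identical
oriented instrument strengths leave the slope unidentified and are
reported with a collinearity flag. Note that the intercept is an
extrapolation to $\gamma = 0$: when instrument strengths span a narrow
range far from zero it is weakly identified, and its SE says so.

**Weighted median.** Ratios are sorted, weights
$w_j = \gamma_j^2\sigma_{Yj}^{-2}$ normalized, and the estimate is the
linear interpolation of $\hat\theta_{(j)}$ at cumulative weight $1/2$
using the cumulative-midpoint convention $p_j = S_j - w_j/2$. It is
consistent while valid instruments hold a majority of the weight. The SE
is the standard deviation of the estimate over `n_boot` parametric
bootstrap replicates, redrawing each association from its reported
sampling distribution; the seed is a required argument, so no hidden RNG
state exists anywhere in the package.

**Weighted mode.** The weighted Gaussian-kernel density of the ratios is
maximized, with bandwidth $h = \varphi \cdot 0.9\min(\mathrm{sd},
\mathrm{mad})\,J^{-1/5}$ (a robust Silverman-type rule; $\varphi$ =
`bandwidth_factor`, default 1). It is consistent when the largest group
of instruments sharing one ratio is valid, even if that group holds a
minority of the weight. Degenerate inputs (all ratios equal) return the
common value. The density is evaluated on a 1024-point grid, which
bounds the argmax discretization error at roughly the grid spacing. One
practical caveat worth knowing: because the bandwidth rule uses the MAD
of the ratios, it breaks down when more than half the *SNPs* (not the
weight) are pleiotropic — the robust scale then tracks the contamination
and the density is over-smoothed. The estimator's guarantee is therefore
sharpest when the invalid instruments are a strong minority carrying a
large weight share.

## Sensitivity analyses

**Cochran's Q** over the ratio estimates, $\chi^2_{J-1}$ under
homogeneity; zero exactly when all ratios coincide. **Egger intercept**
with a two-sided test at $\alpha = 0.05$. **Leave-one-out** IVW for every
instrument. **MR-PRESSO**: the observed residual sum of squares around
leave-one-out IVW predictions is compared with `n_sim` parametric
simulations under no pleiotropy (global test); each SNP's squared
residual is compared with its own simulated distribution and
Bonferroni-adjusted (outlier test); and the percent change in the IVW
estimate after removing outliers is compared with the change from
removing equally many random non-outlier SNPs (distortion test).
Empirical p-values use the $(1 + \#\{\cdot\})/(n_\mathrm{sim}+1)$
convention, so the smallest attainable adjusted outlier p-value is
$J/(n_\mathrm{sim}+1)$: outlier detection at $J \approx 40$–50 requires
$n_\mathrm{sim} \ge 1000$, which is the default.

**Trait-category exclusion.** Instruments are annotated with trait
categories from a local lookup table (`lipid`, `blood`, `inflammation`,
`body_composition`, `type_2_diabetes`, `other`; duplicated SNP–category
pairs collapse to one). For each category the annotated instruments are
removed — or, in the converse keep-only mode, retained exclusively — and
the full estimator battery plus Q and the Egger intercept are re-run on
the reduced panel through exactly the main-analysis code path. A
category that empties the panel is recorded as not estimable rather than
failing the run.

## Power

For a binary outcome, the IVW estimator's asymptotic variance is
$1/(n R^2\,\mathrm{cf}(1-\mathrm{cf}))$, with $n$ the outcome sample
size, $\mathrm{cf}$ the case fraction and $R^2$ the variance in the
exposure explained by the instruments. Two-sided power at level $\alpha$
for a true odds ratio $\mathrm{OR}$ is
$\Phi(\lambda - z_{1-\alpha/2}) + \Phi(-\lambda - z_{1-\alpha/2})$ with
$\lambda = |\log \mathrm{OR}|\sqrt{n R^2\,\mathrm{cf}(1-\mathrm{cf})}$,
so a null OR of 1 returns exactly $\alpha$. Because a power statement is
meaningless without the effect size it presumes, the module takes the
detectable OR as an explicit input and also answers the inverse query
(the smallest OR detectable at a target power). The test suite validates
the formula against a Monte-Carlo oracle that simulates full two-sample
summary statistics and applies a fixed-effect Wald test — the fixed
model being the one the non-centrality approximation describes.

## The synthetic-data generator

`simulate_mr_study()` instantiates the causal diagram directly at the
summary level: MAFs $x_j \sim U(0.05, 0.5)$; instrument effects
$\gamma_j \sim N(0, \tau^2)$ truncated away from zero (default
$\tau = 0.08$, floor 0.02 — sized so that roughly 40–50 instruments
explain about 10% of a SD-scaled exposure, the regime the package
targets); exposure SEs $1/\sqrt{2 n_X x_j(1-x_j)}$ for a unit-variance
trait; outcome SEs $1/\sqrt{2 v\, x_j(1-x_j)}$ with effective size
$v = n_\mathrm{case} n_\mathrm{control}/(n_\mathrm{case} +
n_\mathrm{control})$, the standard binary-trait approximation. Observed
effects are drawn from normals centred on the truth, with
$\Gamma_j^\mathrm{true} = \theta\gamma_j +
\mathrm{sign}(\gamma_j)\,\delta_j$ — pleiotropy is expressed in the
orientation of the exposure-increasing allele, so a non-zero mean
$\mu_p$ is genuinely directional instead of cancelling across arbitrary
allele codings. Default sample sizes (114,999 exposure; 9,358 cases and
15,482 controls) match the study design the package's validation suite
emulates. Palindromic allele pairs, swapped and strand-recoded outcome
records are injected at configurable rates; reference-panel genotypes
realize LD blocks by resampling a fraction of a block-index SNP's
dosages. Seeds are mandatory wherever randomness exists.

What the generator does *not* emulate: individual-level genotypes for
the traits (only for the LD panel), linkage between instrument strength
and pleiotropy (InSIDE always holds unless you construct data
otherwise), winner's-curse selection effects, sample overlap between the
two studies, population stratification, and exact logistic-model
sampling for the binary outcome (the effective-sample-size normal
approximation is used). Passing tests therefore demonstrate correctness
of the estimators and plumbing under the stated model, not robustness to
those real-data complications.

`simulate_benchmark_study()` is a deterministic end-to-end fixture whose
instrument accounting is fixed *by construction* for any seed: 72 of 82
exposure SNPs are genome-wide significant and clump to 52 independent
signals; 48 are measured in the outcome study, 2 more are recovered via
planted proxies at $r^2 \ge 0.8$ (one with negative LD phase), one
further region has only a weak $r^2 \approx 0.15$ proxy and one none at
all; 7 signals are palindromic with MAF $\ge 0.3$ in both studies and 1
has irreconcilable alleles — leaving exactly 42 instruments. The truth
uses $\theta = \log 0.92$ with balanced pleiotropy
($\delta_j \sim N(0, 0.03)$) plus four large-offset outliers, giving the
heterogeneity, pleiotropy and outlier diagnostics real signal; the
annotation table covers all five analysis categories so every exclusion
and keep-only run is exercised.

## Numerical and design choices

* CIs use $z_{0.975} = 1.9600$ (normal approximation) throughout;
  MR-Egger p-values use the t distribution with $J-2$ df.
* Random-effects scaling is clipped below at 1 for both IVW and Egger.
* Bootstrap SE defaults: `n_boot = 1000`; fewer than 2 replicates is a
  configuration error.
* The MR-PRESSO distortion null removes random subsets of non-outlier
  SNPs of the same cardinality as the outlier set; distortion is
  undefined (and flagged) when fewer than three instruments remain.
* Clumping tie-breaks: p-value, then position, then rsid.
* Validation never silently drops rows: rejected rows are returned with
  per-row reasons and counted against the input.
* Problem sizes in the validation suite — 200 replicates of 100-SNP
  studies for parameter recovery and coverage, 1000 null replicates for
  Q calibration, 100 replicates at `n_sim = 1000` for MR-PRESSO
  specificity, 2000 Monte-Carlo replicates per point of the power grid —
  were chosen so each Monte-Carlo standard error sits several-fold below
  the tolerance it guards.

## Known limitations

Single-nucleotide variants only (no indels or multi-allelic sites); no
Steiger directionality filtering, multivariable MR, radial MR or
contamination-mixture estimators; no network clients for GWAS or
phenome-scan databases (annotations come from a local table); LD is
composite $r^2$ on unphased dosages, which is adequate for pruning and
proxy search but is not a haplotype-phase estimate. The Egger intercept
and the weighted mode have the identification caveats described above;
both are reported with diagnostics rather than silently.

## A worked example

```{r, eval = FALSE}
sim <- simulate_benchmark_study(seed = 104)
cfg <- mr_config(
  exposure = sim$exposure, outcome = sim$outcome,
  panel = sim$panel, annotations = sim$annotations,
  output_dir = "mr_run", n_case = 9358, n_control = 15482,
  seed = 42
)
report <- run_mr_pipeline(cfg)
report                      # four-method summary over 42 instruments
glance(report$strength)     # R2 and F
report$sensitivity$q        # heterogeneity
tidy(report$sensitivity$presso)  # per-SNP outlier table
autoplot(report, "scatter")
```
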