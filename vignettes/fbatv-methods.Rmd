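---
title: "Family-based rare-variant testing with weighting schemes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant testing with weighting schemes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbatv)
```

## The testing problem

Rare variants are individually too scarce for single-marker tests, so
region-based tests aggregate them: the quantity under test is a weighted
combination of minor-allele counts, $\sum_m w_m x_{im}$.  In pedigree data a
family-based design has a further advantage: conditioning on parental
genotypes makes the test robust to population stratification, because under
the null hypothesis the only randomness left is Mendelian transmission.

`fbatv` implements this family-based rare-variant test for a quantitative
trait.  For offspring $i$ with trait residual $\tilde y_i$ and genotype
$x_{im} \in \{0,1,2\}$ at variant $m$, the per-variant score is

$$U_m = \sum_i (\tilde y_i - \mu)\,\bigl(\tilde x_{im} - E(\tilde x_{im}
\mid P_{im})\bigr),$$

where $P_{im}$ is the parental genotype pair and $\mu$ the mean trait
residual over tested offspring.  Scores combine as
$W = \sum_m w_m U_m$ and the statistic is $Z = W / \sqrt{\widehat{\mathrm{Var}}(W)}$,
approximately $N(0,1)$ in large samples under the null, with a two-sided
p-value.

Two identities shape the implementation:

* **Covariate cancellation.**  Both trait and genotypes are residualized on
  covariates by ordinary least squares, but the genotype-side fitted value
  appears in both $\tilde x_{im}$ and $E(\tilde x_{im} \mid P_{im})$ and
  cancels exactly, so each term reduces to
  $(\tilde y_i - \mu)(x_{im} - (g_f + g_m)/2)$.  The statistic is therefore
  invariant to the genotype-side regression; we still perform it because the
  *optimal weights* are defined on genotype residuals.
* **Empirical variance over pedigrees.**  Extended pedigrees are decomposed
  into nuclear families, but when linkage is present the transmissions of
  different nuclear families within one pedigree are correlated.  Pedigrees
  are therefore the independent units: with $D_k$ the summed weighted
  contribution of pedigree $k$, $\widehat{\mathrm{Var}}(W) = \sum_k D_k^2$.
  The sum is uncentered because each $D_k$ has expectation zero under the
  null given the conditioning set (traits, covariates, parental genotypes);
  a centered version is available via `fbatv_config(centered_variance = TRUE)`.

Families with a missing parent are excluded from testing (the
sufficient-statistic machinery for partially observed parents is out of
scope), and an individual contributes as offspring only in the nuclear
family in which they are a child, even if they are a parent elsewhere in a
three-generation pedigree.

## Weighting schemes

All founder-level quantities (allele frequencies, odds ratios, optimal
weights) are computed from founders only — pedigree members with no
recorded parents — because founders are mutually unrelated and their
genotypes are not constrained by the conditioning.  Variants monomorphic in
founders receive weight zero under every scheme.

* **`af` (allele-frequency baseline).**  The inverse-frequency weight
  $1/\sqrt{l\,p_m(1-p_m)}$ on $l$ founders, max-normalized.  This is the
  canonical comparator weight; it uses no trait information.
* **`grv` (genotype risk value).**  The founder trait, averaged over exams,
  is dichotomized at a prespecified threshold (140 is the natural choice
  when the trait is systolic blood pressure; simulations default to the
  founder 75th percentile).  A log-additive logistic fit gives a per-allele
  odds ratio; with risk-allele frequency $p$, the average relative risk is
  $\mathrm{ARR} = (1-p)^2 + 2p(1-p)\mathrm{OR} + p^2\mathrm{OR}^2$ and the
  genotype weights are $1/\mathrm{ARR}$, $\mathrm{OR}/\mathrm{ARR}$,
  $\mathrm{OR}^2/\mathrm{ARR}$.  Because these are *genotype-level* weights,
  they cannot enter $W=\sum_m w_m U_m$ directly; the package multiplies each
  offspring-variant term by the weight of the offspring's own genotype.
  This is the minimal extension of the per-variant formula and is a design
  choice of this package, not a prescription of the method's source; the
  HWE identity $(1-p)^2 w_{AA} + 2p(1-p) w_{AB} + p^2 w_{BB} = 1$ is
  enforced to $10^{-12}$ in tests.  The odds ratio is fitted without
  covariates by default (`grv_covariates = TRUE` adds them).
* **`lor` (log odds ratio).**  The signed log odds ratio from a
  covariate-adjusted logistic fit.  The sign matters: protective variants
  flip their contribution, which is the direction-adjustment property.  A
  `lor_absolute` flag gives $|\log \mathrm{OR}|$ for users who prefer a
  magnitude-only weight; signed is the default because direction adjustment
  is the scheme's point.
* **`ow` (optimal weight).**  $w_m = \rho(\tilde y, \tilde x_m) /
  \sqrt{\sum_i (\tilde x_{im} - \bar{\tilde x}_m)^2}$ over founders, with
  $\rho$ the Pearson correlation (the natural reading of "correlation
  coefficient", and the choice consistent with the population-based test
  this weight originates from).  It up-weights rare variants (small spread)
  and trait-associated variants simultaneously, signed by direction.
* **`fp` (functional prediction).**  Nonsynonymous variants are weighted by
  a precomputed functional score in $[0,1]$ (e.g. PolyPhen-2 output
  consumed as a TSV — the annotation tools themselves are never run);
  nonsynonymous variants without a score get their gene's median available
  score, genes with no scores fall back to zero, and all other annotation
  classes get zero.

### Numerical choices

Single-variant logistic fits are unstable for very rare variants.  When the
maximum-likelihood fit separates or diverges (|log OR| > 10 or
non-convergence), the package falls back to a Firth-penalized fit
(Jeffreys-prior score adjustment, Newton iterations with step-halving on
the penalized likelihood); if even that fails the variant's effect is set
to zero with a warning.  Dichotomization places the boundary value in the
case group.  Ties in the minor-allele definition (founder frequency exactly
0.5) keep the VCF alt allele.  Mendelian-inconsistent trio genotypes are a
hard error by default, configurable to set the offending offspring genotype
missing.  Regions where no family is informative, all weights are zero, or
the empirical variance vanishes return an `untestable` result with a reason
code rather than an error; a single contributing pedigree yields a
degenerate $Z = \pm 1$ and is flagged.

## Residualization

The trait is residualized per exam (adjusting for age, sex and medication
use by default), standardized to unit residual SD per exam, and averaged
over the exams available for each individual; the final analysis trait is
this average, matching the repeated-exam design the package targets.
Standardization applies to the trait only by default
(`standardize = "both"` extends it to genotype residuals) because the
optimal-weight formula depends explicitly on the genotype-residual scale.
Genotypes are exam-invariant, so their regression uses each individual's
first-exam covariates.  With no covariates the machinery reduces to
mean-centering, and residualizing twice is a no-op (tested).

## The synthetic cohort generator

No public individual-level data accompany the method, so the package ships
a generator whose defaults encode the study conditions used for
calibration: 300 trio families (600 founders), 50 variants, 70% of
variants below 1% founder MAF (rare MAFs log-uniform on
$[5\times10^{-4}, 0.01]$, 13% low-frequency on $(0.01, 0.05]$, the rest
common), three exams, and covariate effects for age, sex and medication.

The trait follows a variance budget of 1 *net of covariates*:

$$y^{(e)} = \textstyle\sum_m \beta_m x_m + a + \gamma^\top z^{(e)} +
\varepsilon + \varepsilon^{(e)},$$

* $a$ is an additive polygenic value produced by gene-dropping 100
  unobserved background loci (frequency 1/2) down each pedigree and scaling
  to variance $h^2 = 0.68$ — the heritability of the null trait being
  emulated.  Gene dropping, rather than a multivariate-normal kinship draw,
  gives parent-offspring and sibling correlations of $h^2/2$ automatically
  in arbitrary pedigree structures.
* $\varepsilon$ is a permanent environmental deviate with variance
  $1 - h^2 - \mathrm{TVE} - \sigma^2_{exam}$; $\varepsilon^{(e)}$ is
  exam-level noise with SD 0.1 (10% of the trait SD), echoing the
  three-exam averaging design.  A requested TVE at or above $1 - h^2$ is
  rejected.
* In power mode, causal variants are drawn from the polymorphic variants
  (preferring MAF $\le$ 5%), given raw effects proportional to
  $1/\sqrt{2p(1-p)}$ (equal expected per-variant contributions), a
  configurable fraction sign-flipped, and rescaled so the sample variance
  of $\sum_m \beta_m x_m$ equals the target TVE exactly.  The
  `sim_config_map4()` preset mirrors the strongest reference profile:
  TVE 6.48% with ~70% of variants below 1% MAF.  Realized TVE is reported
  against the covariate-free trait, consistent with the unit budget.

Each variant is recoded after gene dropping so that counts refer to the
allele that is minor among the *realized* founders; this makes the stored
matrix exactly reproducible through the VCF/PED readers (which define the
minor allele the same way) and keeps $p_m \le 0.5$ by construction.

What the generator deliberately does **not** emulate: linkage
disequilibrium between variants (drawn independently), sequencing error,
ascertainment of families through affected members, and the exact trait
model of the access-restricted cohort the method was originally applied
to.  Calibration and qualitative power orderings transfer; absolute power
values for specific genes do not, and the package makes no attempt to
reproduce them.

## The evaluation harness

`type_one_error()` runs 200-replicate null experiments by default and
compares each scheme's empirical rejection rate at levels 0.1, 0.05 and
0.01 with the normal-approximation binomial interval
$\alpha \pm 1.96\sqrt{\alpha(1-\alpha)/R}$ rounded to three decimals (this
formula reproduces the three printed reference intervals exactly, which is
how it was identified; that inference is this package's, not a statement
of its source).  `power_experiment()` applies the same machinery to causal
configurations, with paired Monte-Carlo standard errors for scheme
comparisons via `compare_power()`.  Untestable replicates are excluded
from the denominator and reported; more than 5% of them is an error.

Problem sizes used by the packaged experiments (chosen as the smallest
sizes at which the Monte-Carlo tolerances are meaningful): 200 replicates
of 300 trios for calibration; 50,000 trio families for the
midparent-regression heritability check; 50 replicates for realized-TVE
recovery; 2,000 Mendelian resamples of a 500-trio cohort for the
normal-approximation oracle; 100 replicates for the ow-versus-baseline
power ordering.

## Known limitations

* Families with an ungenotyped parent are dropped rather than handled by
  sufficient statistics, so cohorts with sparse parental genotyping lose
  information.
* The `grv` mapping of genotype-level weights into the combined score is a
  documented extension (see above); alternative mappings (e.g. averaging
  the genotype weights into a per-variant weight) would be equally
  consistent with the scheme's definition.
* The empirical variance requires a reasonable number of independent
  pedigrees; with very few pedigrees the normal approximation degrades and
  the package flags the degenerate single-pedigree case.
* X-chromosome inheritance, non-additive genotype codings, multi-allelic
  variants and phasing are out of scope; multi-allelic VCF records are
  skipped with a warning.
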