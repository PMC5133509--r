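# fbatv

Family-based association tests for rare variants in pedigree cohorts, with
five per-variant weighting schemes and an empirical variance that keeps
type I error controlled in the presence of linkage.

## The problem and who this is for

Rare variants carry too little information individually, so region-based
tests aggregate them into a weighted burden. In family data one can do
better than population-based burden tests: conditioning on parental
genotypes leaves Mendelian transmission as the only source of randomness
under the null, which makes the test immune to population stratification.
This package is for statistical geneticists analysing quantitative traits
(the motivating application is blood pressure) in pedigree cohorts with
sequenced rare variants, and for methodologists studying how the choice of
variant weights affects power.

## The statistic

For offspring *i* in a complete nuclear family, with covariate-adjusted
trait residual *ỹᵢ* and minor-allele count *xᵢₘ* at variant *m*:

    Uₘ = Σᵢ (ỹᵢ − μ) (x̃ᵢₘ − E(x̃ᵢₘ | Pᵢₘ))
    W  = Σₘ wₘ Uₘ
    Z  = W / √Var(W),   Z ~ N(0,1) under the null

where *Pᵢₘ* is the parental genotype pair, so that
*x̃ᵢₘ − E(x̃ᵢₘ|Pᵢₘ) = xᵢₘ − (g_f + g_m)/2* exactly (the covariate fit
cancels). Extended pedigrees are decomposed into nuclear families; the
variance is computed *empirically* as ΣₖDₖ², the sum of squared
per-pedigree contributions, because nuclear families within a pedigree are
correlated when linkage is present.

Five weighting schemes are provided, all computed from founders only:

| scheme | weight |
|--------|--------|
| `af`  | 1/√(l·p(1−p)), the inverse-frequency baseline |
| `grv` | genotype-level 1/ARR, OR/ARR, OR²/ARR with ARR = (1−p)² + 2p(1−p)OR + p²OR² |
| `lor` | signed log odds ratio from a covariate-adjusted logistic fit |
| `ow`  | ρ(ỹ, x̃ₘ)/√Σ(x̃ᵢₘ − mean)², correlation over founders |
| `fp`  | functional-prediction score for nonsynonymous variants, 0 otherwise |

`grv`, `lor` and `ow` adjust the direction of association (protective
variants flip sign); `fp` consumes a precomputed score table (e.g.
PolyPhen-2 output) and imputes missing nonsynonymous scores with the gene
median. See the methods vignette (`vignettes/fbatv-methods.Rmd`) for
derivations, defaults and design choices.

## Worked example

Simulate a cohort of 300 trios under the bundled power profile (a gene
explaining 6.48 % of trait variance through mostly-rare causal variants)
and test it under all five schemes:

```r
library(fbatv)
cohort  <- simulate_cohort(sim_config_map4(n_families = 300), seed = 42)
results <- fbatv_all(cohort, schemes = c("af", "grv", "lor", "ow", "fp"))
for (r in results) print(r)
#> FBAT-v [af] MAP4: W=0.7735 Var=9.669 Z=0.249 p=0.8036 (300/300 informative families, 50 variants)
#> FBAT-v [grv] MAP4: W=6.236 Var=782.8 Z=0.223 p=0.8236 (300/300 informative families, 50 variants)
#> FBAT-v [lor] MAP4: W=8.969 Var=61.23 Z=1.146 p=0.2517 (300/300 informative families, 50 variants)
#> FBAT-v [ow] MAP4: W=0.08173 Var=0.03448 Z=0.440 p=0.6598 (300/300 informative families, 50 variants)
#> FBAT-v [fp] MAP4: W=5.356 Var=30.45 Z=0.971 p=0.3317 (179/300 informative families, 50 variants)
```

Each line reports the combined score `W`, its empirical variance, the
normal statistic `Z` with its two-sided p-value, and how many nuclear
families were informative (had a heterozygous parent at some weighted
variant — note `fp` uses fewer families because synonymous variants get
weight 0). A single replicate is noisy; power is a property of the
ensemble:

```r
s <- power_experiment(sim_config_map4(), schemes = c("af", "ow", "fp"),
                      R = 60, levels = c(0.05, 0.1), seed = 11)
as.data.frame(s)[, 1:6]
#>   scheme level rejections  R untestable      rate
#> 1     af  0.05         11 60          0 0.1833333
#> 2     af  0.10         24 60          0 0.4000000
#> 3     ow  0.05         24 60          0 0.4000000
#> 4     ow  0.10         38 60          0 0.6333333
#> 5     fp  0.05         20 60          0 0.3333333
#> 6     fp  0.10         30 60          0 0.5000000
```

Here the optimal weight roughly doubles the rejection rate of the
allele-frequency baseline at the 0.05 level, and informative functional
scores sit in between — the orderings the weighting schemes were designed
to produce.

Real data enter through standard files:

```r
cohort <- read_cohort("study.vcf", "study.ped", "phenotypes.tsv",
                      scores_path = "polyphen_scores.tsv")
run_fbatv(cohort, scheme = "ow",
          config = fbatv_config(threshold = 140))  # SBP-style threshold
```

A thin command-line wrapper with `test`, `simulate` and `evaluate`
subcommands lives at `inst/cli/fbatv.R`.

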