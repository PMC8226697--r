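# rrtdm — random regression test-day models for somatic cell score

`rrtdm` estimates genetic parameters for dairy test-day records — somatic
cell score (SCS, the log2 transform of somatic cell count, an udder-health
proxy) and production traits — with a multiple-trait **random regression
test-day animal model** fitted by **Gibbs sampling**. It is aimed at animal
breeders and quantitative geneticists who want a self-contained, testable
implementation of the full pipeline: data editing, pedigree processing,
Bayesian variance-component estimation, and post-processing into daily
heritabilities and between-trait correlation surfaces, plus a synthetic
herd generator with known truth for parameter-recovery studies.

## The model

A test-day record of cow *l* at days in milk (DIM) *t* is

```
y = HTD_i + Σ_{b=0..4} AS_jb φ_b(t) + Σ_{b=0..2} a_lb φ_b(t)
          + Σ_{b=0..2} pe_lb φ_b(t) + e
```

with `HTD_i` a fixed herd-test-day class (nested in parity, absorbing the
mean), `AS_jb` fixed age-season-of-calving regressions, `a_l` and `pe_l`
random additive-genetic and permanent-environmental regression coefficient
vectors on normalized Legendre polynomials `φ_b` of order 2, and `e` a
homogeneous residual. Additive vectors follow `a ~ N(0, A ⊗ K_a)` over the
pedigree (sparse `A⁻¹` by Henderson's rules with Meuwissen–Luo
inbreeding); `pe_l ~ N(0, K_pe)`; same-day trait residuals share a
covariance `R`. Covariance components get inverted-Wishart full
conditionals; location effects are drawn in blocks, with each cow's
additive and permanent environmental vectors drawn jointly and dedicated
scale moves that keep the additive/PE split mixing. Daily heritability is
`h²(t) = σ²_a(t) / (σ²_a(t) + σ²_pe(t) + σ²_e)` with
`σ²(t) = φ(t)' K φ(t)`, and daily genetic correlations follow the same
covariance-function algebra.

## Worked example

Simulate the package's reference single-trait SCS condition (true
`K_a = diag(1.48, 0.02, 0.01)`, `K_pe = diag(1.86, 0.04, 0.02)`,
`σ²_e = 2.44`, so the true DIM-average heritability is 0.182), fit it, and
summarize. The chain takes about two minutes:

```r
library(rrtdm)
truth <- truth_scs()
ped <- simulate_pedigree(n_founders = 340, n_generations = 3,
                         offspring_per_mating = 2, seed = 1)
herd <- sim_design(n_herds = 2, cows_per_herd = 250, n_tests = 12)
ds <- simulate_records(ped, truth, herd, seed = 2)
chain <- fit_dataset(ds, n_iter = 20000, burn_in = 5000, seed = 3)
chain
#> Posterior chain: 1500 retained samples ( 20000 iterates, 5000 burn-in, thin 10 )
#>   traits: SCS | RR order: 2
#>   posterior mean trace(K_a): 1.697

surface <- daily_surfaces(chain)
subset(summarize_mean_range(surface), quantity == "h2")
#>  quantity name      mean       min       max
#>        h2  SCS 0.1969873 0.1930983 0.2112692

mean(truth_surface(truth)$est$h2)
#> [1] 0.182

head(chain_diagnostics(chain), 4)
#>  component element       mean      ess   geweke_z
#>         Ka   [1,1] 1.57919896 125.9816 -0.1190737
#>         Ka   [2,2] 0.06747516 142.3263 -0.1698060
#>         Ka   [3,3] 0.05022931 152.1133 -0.2526092
#>        Kpe   [1,1] 1.84052822 163.1038 -0.1102193
```

The `h2` row is the lactation-average daily heritability with its (min,
max) range over DIM 5–365 — here 0.197 against a generating value of
0.182, within the posterior and sampling scatter expected at 500 cows. The
diagnostics table reports effective sample sizes and Geweke z scores for
the covariance elements.

For real data, the same pipeline runs from CSV files through a YAML
configuration: `tdm_simulate()` / `tdm_fit()` / `tdm_summarize()` (see
`?load_config`), with `apply_edits()` implementing the standard test-day
edits (parities 1–3, complete trait records per test-day, DIM 5–365, age
at first calving 640–1200 d, lactation nesting) and
`transform_scs()` the SCS transform.

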