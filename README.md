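# estkernel

Estimation and comparison of plant **establishment kernels** (effective
dispersal kernels) from transect censuses around a seeded source
population, built for herbivore-exclusion experiments: replicate plots
with and without mammalian herbivores, stems censused along transects
radiating from the edge of a seeded core, and the question of whether
herbivores change how far a species establishes and how many individuals
it recruits.

The package is organised as an analysis workflow (`analysis/01_*.R` …
`analysis/06_*.R`) over a tested R package (`R/`), and ships a
synthetic-data generator that reproduces the statistical structure of the
field design, so every stage is runnable and testable without field data.

## The model

Binned establishment distance $y_{ijk}$ (stem $i$, plot $j$, treatment
$k$; bins of 0.1 m by default) follows a Poisson-gamma mixture — a
negative binomial with directly parameterized mean:

$$y_{ijk} \sim \text{Poisson}(\mu_{jk}\rho), \quad
  \rho \sim \text{Gamma}(\alpha, \alpha), \quad
  \ln(\mu_{jk}) = \beta_{0j} + \beta_{1j}\,\mathrm{trt}_k,$$

with plot effects $\beta_{0j} \sim N(\delta_0, 1/\tau_0)$,
$\beta_{1j} \sim N(\delta_1, 1/\tau_1)$, non-informative priors
($\delta \sim N(0, \text{prec } 10^{-4})$,
$\tau \sim \text{Gamma}(10^{-4}, 10^{-4})$, $\ln\alpha$ Laplace with rate
$10^{-4}$), fitted by an adaptive Metropolis-within-Gibbs sampler with
conjugate hyper-parameter updates and split-chain $\hat R$ diagnostics.
Upstream, the kernel family itself is chosen by maximum likelihood + AIC
among normal, negative exponential, negative binomial and Poisson
candidates; downstream, plot-level population growth is compared by
one-way ANOVA and the cover context around each stem by linear models
with treatment interactions (sequential sums of squares). Details and the
reasoning behind every numerical choice are in
`vignettes/establishment-kernels.Rmd`.

## Worked example

Running the numbered scripts in order regenerates the whole analysis
under `results/` (each takes seconds; `03_fit_model.R` runs 5 chains and
takes about a minute):

```sh
Rscript analysis/01_simulate.R        # synthetic field campaign
Rscript analysis/02_select_kernel.R   # AIC over candidate families
Rscript analysis/03_fit_model.R       # hierarchical Poisson-gamma MCMC
Rscript analysis/04_kernel_summaries.R
Rscript analysis/05_population_growth.R
Rscript analysis/06_cover_context.R
```

With the default seeds this prints, among other output:

```
wrote 556 stems across 6 plots (3 with herbivores excluded)

   family                     params    logLik k      AIC       dAIC
   nbinom mu=9.39928, alpha=0.568075 -1790.36  2 3584.71    0.0
     nexp              rate=0.106391 -1801.79  1 3605.58   20.9
   normal    mean=9.39928, sd=12.048 -2172.78  2 4349.55  764.8
  poisson               mean=9.39928 -4430.97  1 8863.95 5279.2

Population growth: 152.3 vs 33 stems/plot (78.3% reduction)
  F(1,4) = 1114, p = 4.802e-06

Establishment-kernel summaries (farthest 1% tail)
          statistic   value
        mu_absent_m 0.99980
       mu_present_m 0.71140
        mean_diff_m 0.28840
            overlap 0.05013
     range_absent_m 6.30000
    range_present_m 4.70000
       range_diff_m 1.60000

Cover-context model (weedy cover)
            term df sum_sq      F         p
           cover  1  912.4  32.78 3.130e-05
 cover:treatment  1  513.2  18.44 5.579e-04
slopes: absent 0.4115, present 0.05879 stems per cover %
```

Reading these: the negative binomial describes the kernel best (the
establishment data are strongly overdispersed); herbivores cut plot-level
recruitment by ~78%, pull the posterior kernel mean in by ~0.29 m (with
the two treatments' credible sets for $\mu_k$ overlapping only at their
95%/5% quantiles), and shorten the farthest-1% establishment distance
from 6.3 m to 4.7 m. Weedy cover raises establishment only where
herbivores are excluded — the significant cover × treatment interaction —
while native-prairie and bare-ground cover show main effects but no
interaction.

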