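# gliogrow

A clinical-scale, two-dimensional simulator of glioblastoma multiforme
(GBM) growth, hypoxia-driven brain invasion, and the response to
anti-angiogenic therapy — together with the clinical statistics used to
confront the model with imaging and survival data.

## The science

GBM shows a classical multilayer structure on MRI: a necrotic core, a
contrast-enhancing rim of proliferating cells, and a diffuse nonenhancing
(FLAIR) margin of invading cells.  `gliogrow` models this with four
densities on a grid — proliferative cells `P`, invasive cells `I`,
healthy brain `B`, necrotic material `N` — under the **go-or-grow**
hypothesis: `P` divides but does not move, `I` moves but does not divide,
and the local hypoxic state `H = min(C / C_ref, 1)` (with
`C = P + I + B + N`) switches cells between the phenotypes across two
threshold fields:

- `H < τ_h` — normoxia: maximal mitosis, invasive cells revert to `P`;
- `τ_h < H < τ_l` — hypoxia: mitosis slows, `P` switches to `I`;
- `H > τ_l` — lethal crowding: all living cell types die rapidly into `N`.

Invasive cells migrate by **passive diffusion** (Fickian, faster along
white-matter tracks: `D = D0·(1 + w·(κ_wm − 1))`) and by **active
transport** (bulk advection with velocity `γ·∇B`, up the healthy-brain
gradient, stopping where the brain is uniform).  **Angiogenesis** raises
both thresholds with the local proliferative density
(`dτ/dt = α·P·(τ_cap − τ)`), letting a vascularised tumour sustain higher
density; **anti-angiogenic therapy** suppresses that term and resets the
thresholds, which shrinks the proliferative mass, accelerates necrosis —
and fuels invasion.  The simulator reproduces growth *without*
angiogenesis through the cycle of proliferation → hypoxia → phenotype
switch → invasion → reversion in fresh brain, which expands necrosis; the
rebound of rapid growth when therapy is lifted; and a positive
association between necrotic area and invaded area.

The clinical module implements the matching statistics: bidimensional
lesion areas (product of perpendicular diameters), robust
least-absolute-residuals polynomial fits, Kaplan–Meier curves and the
log-rank test, plus a synthetic cohort generator for two patient groups
with distinct progression-free survival.

## A worked example

```r
library(gliogrow)

dom <- synthetic_brain(c(64, 64), seed = 1)   # deterministic phantom
p   <- gbm_params()                           # defaults (see vignette)

full <- run_simulation(dom, p, make_schedule("full"), n_steps = 3000,
                       record_every = 1000)
aa   <- run_simulation(dom, p, make_schedule("aa"),   n_steps = 3000,
                       record_every = 1000)

glance(full)
#> # A tibble: 1 × 7
#>   mode  n_steps P_mass I_mass pct_necrosis pct_invasion pct_proliferation
#>   <chr>   <dbl>  <dbl>  <dbl>        <dbl>        <dbl>             <dbl>
#> 1 full     3000   156.   132.         1.72         65.0              63.9
glance(aa)
#> # A tibble: 1 × 7
#>   mode  n_steps P_mass I_mass pct_necrosis pct_invasion pct_proliferation
#>   <chr>   <dbl>  <dbl>  <dbl>        <dbl>        <dbl>             <dbl>
#> 1 aa       3000   17.5   1.72         14.9          9.58              13.3
```

The untreated (angiogenic) tumour reaches a proliferative mass of about
156 with 65% of the brain invaded above the 10⁻⁴ threshold; under
anti-angiogenic therapy from time zero the tumour still grows, but to
roughly a ninth of that mass — while necrosis expands *faster* (14.9%
against 1.7%), because with the thresholds pinned at baseline, crowded
tissue dies sooner.
`autoplot(full)` draws the four observable time series;
`plot_state(full$final, "I")` maps the invasive field;
`layer_radii(full$final, dom, p)` quantifies the core–rim–margin
ordering; and `virtual_mri(full$final, dom, p)` labels each cell as
necrotic core, enhancing rim, FLAIR margin or normal brain.

On the clinical side:

```r
coh <- synth_cohort(seed = 1, n = 200)
grp <- split(coh, coh$group)
logrank_test(grp$necrosis_minus$pfs_time, grp$necrosis_minus$event,
             grp$necrosis_plus$pfs_time,  grp$necrosis_plus$event)
#> Log-rank test: chi-square = 25.69 , p = 4.02e-07
```

The two synthetic groups are built with mean progression-free survival
times of 333 and 178 days; at 100 patients per arm the log-rank test
separates them decisively.

A command-line launcher is installed at `inst/cli/gliogrow`
(subcommands `simulate`, `calibrate`, `sweep`, `clinical`, `make-brain`).

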