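# ashbalance

Mineralogical mass balance for biomass combustion ash.

## The problem

Burning crop residues concentrates their mineral nutrients into an ash
that can be returned to fields as fertiliser. Quantitative X-ray
diffraction (Rietveld refinement with an internal standard) tells you
which crystalline phases the ash contains and in what amounts — sylvite
(KCl), arcanite (K₂SO₄), apatites, carbonates — but a quarter to a third
of a typical straw ash is amorphous, and diffraction is blind to its
chemistry. Whether the ash is a potassium fertiliser or a phosphorus
trap depends on where each element sits.

`ashbalance` answers this with a stoichiometric mass balance. The
crystalline contribution of element *e* is

    c_e = Σ_i w_i · f_ie        f_ie = n_ie · m_e / M_i

(w_i = phase weight fraction in wt%, f_ie = element mass fraction from
the phase formula). Subtracting from an independent bulk chemical
analysis b_e gives the amorphous composition by difference,

    a_e = max(0, b_e − c_e)     σ_a = sqrt(σ_b² + Σ_i (f_ie σ_i)²)

with Gaussian error propagation over the refinement esds σ_i and the
bulk sds σ_b, clamping of negative differences (flagged, never hidden),
closure diagnostics, water-solubility classification of the phases
(plant-availability proxy), straw-to-ash element recovery across
combustion, and a synthetic-sample generator for validating the
estimator on known ground truth.

The package ships a reference dataset: phase quantification, bulk ash
chemistry and straw composition of four sorghum straw ashes (grain
variety Razinieh and sweet variety Della, each grown on
phosphate-supplemented and phosphate-depleted soil, ashed at 550 °C).

## Worked example

```r
library(ashbalance)

asm <- sorghum_ash_phases("razinieh_normal")   # 18 phases + amorphous 27.40 wt%
blk <- sorghum_ash_bulk("razinieh_normal")     # bulk analysis, wt%
rep <- ash_mass_balance(asm, blk)
rep$report
#> # A tibble: 9 × 9
#>   element  bulk bulk_sd crystalline crystalline_sd amorphous amorphous_sd clamped soluble_fraction
#>   <chr>   <dbl>   <dbl>       <dbl>          <dbl>     <dbl>        <dbl> <lgl>              <dbl>
#> 1 C        3.36    0.07        2.68         0.0378     0.685       0.0796 FALSE             0.195
#> 2 Ca      14.7     0.01       11.6          0.135      3.14        0.136  FALSE             0.0753
#> 3 Cl      10.7     0           9.07         0.0829     1.63        0.0829 FALSE             0.987
#> # … 6 more rows
rep$diagnostics
#> <closure_report> razinieh_normal
#>   total 100.00 wt% (deviation +0.00, ok)
#>   over-allocated: Fe
#>   in phases, not analysed in bulk: H, Al, F, Mn, Na, O, Ti
#>   below detection: Zn
```

Reading the output: of the 25.6 wt% potassium in this ash, 16.0 wt% is
crystalline — and `soluble_fraction = 1` for K (row not shown): all of
it sits in water-soluble or water-reactive carriers — while 9.55 wt% is
amorphous. Phosphorus splits 1.72 wt% crystalline (apatites,
`soluble_fraction = 0`) against 0.91 wt% amorphous. The `clamped` Fe row
records that crystalline Fe slightly exceeds the bulk measurement, so
its amorphous estimate is censored at zero; closure of the assemblage
at exactly 100 wt% and the over-allocation warning are in the
diagnostics.

The scripted analyses in `analysis/` run the same pipeline over all
four bundled ashes (`01`), compute solubility and recovery indices
(`02` — e.g. straw-to-ash P recovery of 0.97–0.99 versus 0.27–0.48 for
volatile-prone S), and validate the estimator on synthetic assemblages
(`03`), writing tables under `results/`.

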