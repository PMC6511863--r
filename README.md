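# polfid

Nucleotide-selection energetics and transcription fidelity for a
single-subunit RNA polymerase.

Single-subunit RNA polymerases such as the T7 enzyme elongate with an
error rate near 10⁻⁴ despite having no proofreading activity. The
fidelity must therefore be built in *before* chemistry, in the
free-energy landscape that a nucleotide crosses between its
**pre-insertion** and **insertion** configurations at the active site.
`polfid` implements the full quantitative chain for analysing this
mechanism:

- **`wham_reconstruct` / `bootstrap_pmf` / `extract_barriers`** —
  potential-of-mean-force (PMF) reconstruction along the
  difference-of-RMSDs insertion coordinate
  (`delta_rmsd(X) = rmsd(X, X_pre) − rmsd(X, X_ins)`) from umbrella
  windows, by the weighted histogram analysis method with a
  Newton-accelerated self-consistent solver and multinomial bootstrap
  uncertainties.
- **`bar_pair` / `leg_total` / `compute_cycle`** — relative binding free
  energies ΔΔG_b from bidirectional alchemical samples via the Bennett
  acceptance ratio and the thermodynamic cycle
  ΔΔG_b = ΔG_protein − ΔG_solution.
- **`align_landscape` / `derive_selection_energies` /
  `path_populations`** — composite cognate/non-cognate landscapes on one
  energy axis, on/off-path Boltzmann populations, and the four
  checkpoint selection energies Δ_b−, Δ_in+, Δ_in−, Δ_c+.
- **`steady_state` / `gillespie_validate` / `fit_catalytic_selection` /
  `checkpoint_placement_scan`** — a branched five-state master equation
  of the nucleotide addition cycle whose steady-state error rate
  Err = J_nc / (J_c + J_nc) connects the selection energies to observed
  fidelity; stationary populations come from the numerically robust
  Grassmann–Taksar–Heyman elimination and are validated against exact
  stochastic simulation.

Because all-atom enhanced-sampling MD cannot be reproduced at desk
scale, the package includes a synthetic-data generator
(`sample_window`, `sample_alchemical`) that draws exact Boltzmann
samples from packaged reference free-energy profiles and
Crooks-consistent Gaussian work distributions. The generator's defaults
are the study conditions (0.1 Å window spacing,
k = 210,000 kJ mol⁻¹ nm⁻², 2,000 retained samples per window, 21 λ
states × 5,000 samples per direction), so the complete estimator chain
can be exercised and judged on parameter recovery. All energies are in
kBT at 310 K, all coordinates in Å.

## Worked example

PMF recovery for the cognate case at study conditions, with a
200-replicate bootstrap:

```r
library(polfid)

rec <- recover_case("rATP", "cognate", n_boot = 200)
rec$pmf
#> <pmf_profile> 130 bins of 0.02 A over [-1.29, 1.29] A, 27 windows
#>   G range [-3.23, 2.99] kBT (zero: pre-min); converged in 10 iterations (residual 4.86e-09)
#>   bootstrap sigma: median 0.233 kBT
rec$barriers
#> <barrier_summary>
#>   pre-insertion min: G = 0.00 kBT at -1.27 A
#>   transition max:    G = 2.99 kBT at -0.03 A
#>   insertion min:     G = -3.23 kBT at 1.29 A
#>   dE_in = 2.99, dE_rev = 6.22, dG_end = -3.23 kBT
```

The recovered activation barrier (2.99 kBT) and end-state stabilization
(3.23 kBT) match the 3 kBT planted in the cognate reference profile to
well within the bootstrap spread.

Relative binding free energy of the mismatched rGTP versus rATP through
the alchemical thermodynamic cycle (planted value +3 kBT):

```r
legs <- sample_cycle("rGTP")
compute_cycle(legs$protein, legs$solution)
#> <cycle_result> ddG_b = 2.964 +/- 0.032 kBT
#>   protein leg  2.990 +/- 0.022 kBT
#>   solution leg 0.026 +/- 0.022 kBT
```

Fidelity of the branched kinetic scheme for rGTP (4 kBT pre-insertion
rejection and 4 kBT insertion inhibition on the off-path branch,
0.5% / 99.5% on/off entry), and the catalytic selection needed to reach
an error rate of 10⁻⁴:

```r
steady_state(rgtp_scheme())
#> <fidelity_result>
#>   elongation rate J = 210 s^-1 (J_c 209, J_nc 1.14)
#>   error rate Err = 5.445e-03
#>   populations:
#>        I       II     IIIc      IVc       Vc    IIIon   IIIoff     IVnc
#> 0.071319 0.150766 0.243547 0.417708 0.104378 0.001183 0.008242 0.002287
#>      Vnc
#> 0.000571

fit <- fit_catalytic_selection(rgtp_scheme(), target_err = 1e-4)
as.numeric(fit)
#> [1] 7.031555
```

The pre-chemical checkpoints alone leave the error rate near 5 × 10⁻³;
an additional ~7 kBT of discrimination at the catalytic step is required
for 10⁻⁴ — the central fidelity inference reproduced by the package.

## Command-line interface

An executable wrapping the same operations is installed at
`system.file("exec", "polfid", package = "polfid")`:

```sh
polfid simulate-windows --species rATP --path cognate --out win
polfid wham --metadata win/rATP_cognate_metadata.txt --boot 200 \
      --summary barriers.json --out pmf.tsv
polfid simulate-alchemy --species rGTP --out alc
polfid bar --protein alc/rGTP_protein.tsv --solution alc/rGTP_solution.tsv
polfid fidelity --config $(Rscript -e 'cat(system.file("extdata",
      "example_scheme.cfg", package = "polfid"))')
polfid fit-catalytic --target 1e-4
polfid scan --total 8 --out scan.tsv
polfid reproduce --seed 20190327 --out-dir report
```

Every command logs package version, seeds and tolerances to stderr and
exits nonzero with a one-line `error: <cause>` on failure.

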