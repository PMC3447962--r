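# sbmsaxs

Characterizing the solution-state conformational ensemble of a
multi-domain protein by combining structure-based (Gō-type) molecular
dynamics with small-angle X-ray scattering (SAXS).

A crystal structure shows one conformation; in solution, a multi-domain
enzyme with flexible linkers — the motivating case is a multi-domain
tyrosine kinase with SH3 and SH2 domains tethered to a catalytic domain —
populates a mixture of compact and extended forms, and a SAXS curve is the
population-weighted average over that mixture. `sbmsaxs` implements the
pool-based workflow for resolving such mixtures:

1. **Forcefield construction** — an all-atom structure-based model whose
   minimum is the native structure: harmonic bonds, angles and planarity
   terms with native reference values, Lennard-Jones 12-6 native contacts
   from the Shadow contact map (pair distance < 6 Å, ≥ 4 residues apart,
   unoccluded line of sight), a purely repulsive excluded volume
   `ε_nc (σ_nc/r)^12`, with all stabilizing inter-domain contacts removed
   and linker dihedrals freed so the domains move as rigid-ish bodies on
   flexible tethers.
2. **Conformational sampling** — Langevin dynamics (BAOAB) in reduced
   units at timestep 0.0005, producing a pool of candidate conformations
   (the production protocol saves one snapshot every 0.5 time units over
   20,000 time units, i.e. 40,000 candidates).
3. **Theoretical scattering** — the exact Debye sum
   `I(q) = Σᵢⱼ gᵢ(q) gⱼ(q) sin(q rᵢⱼ)/(q rᵢⱼ)` with tabulated atomic form
   factors (optionally solvent-corrected), plus Guinier and Kratky
   analyses.
4. **Ensemble analysis** — each candidate is scored against an
   experimental curve with the reduced chi-square

   ```
   χ² = (1/N_q) Σ_q [ (c·I_theo(q) − I_exp(q)) / σ(q) ]²
   ```

   (`c` a fitted scale); the 5% of conformations with the lowest χ² define
   the P(Rg) population histogram; four representatives per major peak
   (pairwise RMSD > 2 Å) seed a search over candidate ensembles, where the
   combined curve `I_combined(q) = Σᵢ wᵢ Iᵢ(q)` is evaluated for **every**
   weight vector on the grid `wᵢ = 0.1·n` (n = 0…10, Σwᵢ = 1) and the
   global χ² minimum is returned. A cross-condition table fits each best
   ensemble against every other condition's curve.
5. **Synthetic data** — toy multi-domain structures, hinge-opened conformer
   families and mock experimental curves with known generating weights and
   a q-dependent noise model, so the whole chain can be validated without
   any external data.

The weighted-ensemble fit is a first-class model object
(`saxs_ensemble_fit`) with `print`, `summary`, `coef`, `fitted`,
`residuals`, `predict`, `simulate` and `plot` methods.

## Worked example

```r
library(sbmsaxs)

# a miniature three-domain protein analog and its structure-based topology
toy  <- toy_multidomain(3, atoms_per_domain = 80, linker_length = 12, seed = 7)
topo <- build_topology(toy)
topo
#> sbm_topology: 264 atoms | 263 bonds, 264 angles, 0 impropers, 259 dihedrals, 774 contacts

# short Langevin demonstration run on the toy topology
pool <- run_sampling(topo, toy,
                     sampler_params(total_time = 25, snapshot_interval = 0.5, seed = 1))
pool
#> conformation_set: 50 frames, 264 atoms
#> Rg range: 25.00 - 25.92 A

# three structurally distinct conformers: compact, extended, and L-shaped
fam <- bind_conformations(list(
  conformer_family(toy, 20, mode = "hinge", seed = 8, max_angle = pi * 0.8),
  conformer_family(toy, 20, mode = "hinge", seed = 8, max_angle = pi * 0.8,
                   hinge_scale = c(1, 0))))
members <- subset_conformations(fam, c(1, 20, 21))
round(members$rg, 1)
#> [1] 11.5 25.2 15.1

# a mock "experimental" curve mixed with weights 0.5 / 0.3 / 0.2 (1% noise),
# then a grid-weight ensemble fit against it
curves <- profile_set(members)
mock <- mock_experiment(curves, c(0.5, 0.3, 0.2), noise = noise_model(seed = 7))
fit <- fit_ensemble(mock$curve, curves)
fit
#> Weighted SAXS ensemble fit
#>   members: 1, 2, 3
#>   weights: 0.5, 0.3, 0.2
#>   chi2 = 0.8971, scale = 1.004 (66 weight vectors searched)

# size information carried by the fitted ensemble curve
round(guinier_rg(predict(fit))$rg, 1)
#> [1] 14.8
```

The fit recovers the generating weights exactly on the 0.1 grid, with a
reduced χ² at the noise floor (≈ 1), and the Guinier radius of the fitted
ensemble curve is the scattering-weighted size of the mixture. The full
multi-condition pipeline (`run_full()` with a YAML config; see
`inst/scripts/pipeline.R` for a command-line wrapper) chains topology →
sampling → profiles → scoring → filtering → P(Rg) → representative
selection → ensemble search → cross-condition table, with a provenance
manifest and `resume_run()` support.

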