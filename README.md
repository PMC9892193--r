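# nbalance

Operando quantification of biofilm and planktonic biomass — and of the
biomass-specific rates that actually measure microbial performance — in
continuously operated biofilm electrochemical reactors, from nothing more
than routine total-nitrogen (TN) and optical-density (OD600) measurements.

Written for bioprocess engineers running biofilm-based microbial
electrosynthesis (MES), gas fermentation or similar continuous systems with
3D electrodes, where the biofilm cannot be weighed without killing the
reactor and performance is otherwise only reported per electrode area or
electrolyte volume.

## The method

Elemental nitrogen is only assimilated, never created or destroyed, so the
cathode compartment's nitrogen balance has no reaction term:

    dn_N/dt = F·c_N-aq,in − F·c_N-aq,out − F·c_N-pX,out

Integrating over each sampling interval gives the nitrogen retained in the
compartment; dividing by the biomass nitrogen content ν_N,X (0.2 mol_N per
C-mol for CH1.8O0.5N0.2 biomass) converts it to total biomass:

    n_X,T(t) = n_X,0 + Σ Δn_N / ν_N,X

An OLS calibration line c_N-pX = a·OD600 + b converts optical density into
the nitrogen held in suspended cells, hence planktonic biomass
n_pX = c_N-pX·V_TC/ν_N,X, and the biofilm is the difference
n_bX = n_X,T − n_pX. Differencing the product balances gives volumetric
rates r_i, and normalizing to biomass gives the q-values and specific
growth rate:

    q_i = r_i·V_TC·C_i / n_X,T   (C-mol basis; C_i = 2, 4, 6 for C2, C4, C6)
    μ   = (Δn_X,T/Δt + F·c_pX) / n_X,T

plus Faradaic efficiency from trapezoidally integrated charge, the standard
KPI normalizations (catholyte volume, electrode volume, projected surface
area, cathode-volume current density) and the biofilm space occupancy
against the ~13 mmol cm⁻³ theoretical packing limit.

A seeded ODE simulator of a continuously fed biofilm reactor
(Monod-on-nitrogen growth, logistic electrode colonization, detachment,
washout, stoichiometric current) generates observations with known ground
truth, so the whole pipeline is testable without laboratory data.

## Worked example

```r
library(nbalance)

cfg <- reactor_config()          # 0.12 L catholyte, HRT 8 d, 7.35 cm3 cathode
cal <- calibration_model(0.0052, -2e-5, r_squared = 0.9989)

# simulated 80-day run with 5% observation noise (stands in for your CSVs;
# use read_measurements()/read_reactor_config() for real data)
sim <- simulate_reactor(cfg, scenario_params("growth_plateau", seed = 42))

biomass <- accumulate_biomass(cfg, sim$samples, cal)
tail(biomass[, c("t", "n_x_total", "n_px", "n_bx", "biofilm_fraction")], 3)
#>       t n_x_total     n_px   n_bx biofilm_fraction
#> 1  79      0.0276 0.000284 0.0273            0.990
#> 2  79.5    0.0278 0.000264 0.0276            0.991
#> 3  80      0.0281 0.000275 0.0278            0.990

rates <- rate_series(cfg, sim$samples, biomass)
tail(rates[, c("t_mid", "q_p_total", "mu")], 3)
#>   t_mid q_p_total     mu
#> 1  78.8    0.0943 0.0198
#> 2  79.2   -0.0239 0.0196
#> 3  79.8    0.374  0.0195

kpi <- kpi_report(cfg, sim$samples, biomass, t0 = 60, t1 = 80)
kpi$per_product
#>   product   titer_g_per_l rate_catholyte rate_electrode_volume rate_psa
#> 1 acetate           5.53          0.774                  12.6     126.
#> 2 butyrate          2.05          0.302                   4.93     49.3
#> 3 hexanoate         0.592         0.0839                  1.37     13.7
```

Reading the output: after 80 days the reactor holds 28.1 mmol of biomass of
which 99.0% is biofilm on the cathode — planktonic cells are a rounding
error, which is why OD alone cannot characterize such reactors. Growth has
slowed to μ ≈ 0.02 d⁻¹ (mature biofilm); the per-interval q_p scatter
(even transiently negative values) is what twice-weekly sampling noise does
to differenced rates, and is why q_p is judged from its trend. The KPI
table is the conventional engineering view: ~5.5 g L⁻¹ acetate at
0.77 g L⁻¹ d⁻¹, i.e. 12.6 g L_cathode⁻¹ d⁻¹ or 126 g m⁻² d⁻¹ for this
electrode. Over the same window the FE computed from integrated charge is
97.1% and the biofilm occupies 29.2% of the electrode's physical space.

The end-to-end file pipeline (`run_pipeline()`, or
`Rscript inst/cli/nbalance.R run config.yaml measurements.csv out/`)
reads a YAML reactor configuration and a measurement CSV
(`t_days,c_n_aq_out_mol_per_l,od600,acetate,butyrate,hexanoate,current_a`),
and writes the biomass trajectory, rate series, KPI table and an audit log
of every assumption in force.

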