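# catchbond

Structure-based modelling of catch-slip and slip-only bonds between the
T-cell receptor (TCR) and peptide-MHC (pMHC) ligands, from single-bond
force-clamp lifetime data.

Strong agonist pMHCs form *catch-slip bonds* with the TCR — mean bond
lifetime rises with tensile force to a peak near 10–20 pN before falling —
while weak ligands form *slip-only bonds* whose lifetime decays
monotonically. `catchbond` implements a Kramers-theory model in which force
deforms a 1D linear-cubic energy landscape through a polymer-mechanics
extension functional built from the conformational changes of the
TCR–pMHC complex (interface tilting, partial unfolding of interdomain
joints, domain stretching):

- off-rate `k(F) = k0 sqrt(1-eps) exp(DeltaG0 (1-(1-eps)^1.5))` with
  `eps = 2 delta0 gamma(F) / (3 DeltaG0 kBT)` and
  `delta0 gamma(F) = integral of delta_z(f) df` — the accumulated
  extension gap between transition-state and bound-state conformations;
- class I and class II pMHC extension-gap geometries (freely-jointed-chain
  rigid bodies, extensible worm-like-chain unfolded joints), plus the Bell
  model and the generic two-pathway comparator;
- Levenberg–Marquardt fitting of binned lifetime-vs-force data with the
  prefactor constraint `DeltaG0 = ln(k_w/k0)`, the contour-length
  criterion, and mean±SEM refit / curvature standard errors;
- bond-profile metrics (`t0`, `t_peak`, `F_opt`, `Delta_t`, `F_range`,
  `L`, `B`, and the catch-bond intensity `I = L/(1+B)`);
- bond-type classification and `n*`–`theta` phase diagrams;
- cohort analyses: Lloyd's k-means (SO/WC/SC bond classes), PCA with
  Mahalanobis distances, potency correlations, and cross-examination of
  the class I and class II models including the 0.4 nm/aa contour-length
  limit on `delta0*` vs `n*` slopes;
- a seeded simulator of biomembrane-force-probe style datasets
  (exponential dwell times, binned mean ± SEM).

See the methods vignette (`vignettes/catchbond-methods.Rmd`) for the model,
its assumptions and every numerical choice.

## Worked example

Simulate a catch-slip system at experimental scale (8 force bins spanning
2–30 pN, 50 lifetimes per bin), refit it, and extract its bond profile:

```r
library(catchbond)

cc  <- default_constants()
th  <- tilt_from_unfolding(10, cc$pc, cc$segments, "I")   # 33.69 deg
sp  <- structural_params_c1(theta_deg = th, n_star = 10, d_alpha3 = 5.2,
                            delta0 = 3.2, segments = cc$segments)
lp  <- landscape_params(k0 = 1, delta0 = 3.2, kBT = cc$pc$kBT)
g   <- gamma_class1(sp, cc$pc)
rate <- function(F) as.numeric(off_rate(F, lp, g))

classify_bond_type(lp, g)
#> [1] "catch-slip"

ds  <- make_dataset(simulation_spec(rate, seed = 42))
fit <- fit_bond_model(ds, "classI", cc$pc, cc$segments)
fit$se <- fit_uncertainty(ds, fit)
fit
#> bond_fit [ classI ]  R^2 = 0.9354
#>       k0   delta0    theta   n_star d_alpha3
#>   0.9506   3.8504  37.0519  11.3246   5.3205
#> SE:
#>       k0   delta0    theta   n_star d_alpha3
#>   0.3099   0.9446   4.6021   2.0073   0.1500

extract_metrics(fit)
#> bond_metrics [catch-slip]
#>   t0 = 1.05 s, t_peak = 2.18 s, F_opt = 14.5 pN
#>   Delta_t = 1.13 s, F_range = 28.2 pN, L = 0.518, B = 0.947, I = 0.266
```

The generating parameters (`k0 = 1`, `delta0 = 3.2` nm, `theta = 33.69`
degrees, `n* = 10` aa, `d_alpha3 = 5.2` nm) are all recovered within about
one standard error at this noise level; the fitted profile peaks at
~14.5 pN with catch-bond intensity `I` of 0.27. (These numbers are the
output the code prints for this seed.)

A thin command-line wrapper covers the same pipeline:

```sh
Rscript inst/cli/catchbond.R simulate --model classI --params p.yaml --seed 7 -o data.csv
Rscript inst/cli/catchbond.R fit --model classI data.csv -o report.json
Rscript inst/cli/catchbond.R phase-diagram --model classI --k0 1 --delta0 2 -o grid.csv
```

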