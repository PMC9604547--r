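# hbridge

Substituent-increment analysis of intramolecular hydrogen-bridge proton
transfer in salen-type tri-ring aromatic Schiff bases.

These compounds carry two symmetric O–H...N hydrogen bridges. Scanning
the O–H distance of a bridge gives a double-well energy profile with
three parameters (kcal/mol, referenced to the optimised molecular
form): the activation energy **EA** (barrier top), the second minimum
**SM** (proton-transferred well), and their difference. Substituting
the outer rings with –Br, –NH2 or –NO2 at positions 1–4 shifts these
parameters, and the shifts decompose additively — the *composite
substituent effect*:

```
EA = EBC + IE-SUB + IE-STER + IE-DIST
SM = SBC + IS-SUB + IS-STER (+ IS-DIST)
```

* `EBC`/`SBC` — parameters of the unsubstituted parent (per group:
  ortho, meta, para);
* `IE-SUB` — classical (resonance/induction) increment, shared within
  the position pairs 1/3 and 2/4;
* `IE-STER` — proximity increment of the bridge-adjacent positions 1
  and 4 only;
* `IE-DIST` — small contribution of the remote (distal) ring,
  |value| ≲ 0.5 kcal/mol.

The package is for computational chemists who have such scan profiles
(or want to prototype the analysis without any quantum chemistry): it
reads profiles and extracts (EA, SM, difference), fits the increments
from mono-substitution grids, predicts parameters for new substitution
patterns, scores approximation error, builds proximal × distal heatmap
matrices with spread statistics and charge-difference diagnostics, and
generates synthetic double-well datasets with known ground truth so the
whole pipeline is testable end to end. The published empirical
increment table ships as packaged data (`empirical_increments()`).

## Worked example

Predict a nitro substituent adjacent to the bridge (position 1) on a
parent with EBC = 12, SBC = 10 kcal/mol:

```r
library(hbridge)
tab  <- empirical_increments()
base <- base_parameters("meta", e_base = 12, s_base = 10)
predict_bridge(tab, base, proximal = "NO2,1")
#> <prediction> proximal NO2,1, distal None,None: EA = 9.551, SM = 9.117 kcal/mol
#>   term     ea     sm
#> 1 base 12.000 10.000
#> 2  sub -0.322 -1.496
#> 3 ster -2.127  0.613
#> 4 dist  0.000  0.000
```

The barrier drops by almost 2.5 kcal/mol — mostly the steric term of
the bridge-adjacent nitro group — while the PT well deepens less, so
the profile flattens (EA − SM = 0.43 kcal/mol).

Close the loop entirely in silico: materialise a synthetic para+meta
scan campaign, re-extract every profile, and re-fit the increments:

```r
fx  <- make_fixture_suite(file.path(tempdir(), "fx"), seed = 42)
ds  <- load_dataset(fx[["noiseless"]])     # 338 profiles -> parameters
fit <- fit_increments(ds)
max(abs(fit$e_sub[names(tab$e_sub)] - tab$e_sub))
#> [1] 8.881784e-16

effect_spread(build_matrix(ds, "meta", "ea"))
#> <effect spread> proximal 0.89 +/- 0.00, distal 0.00 +/- 0.00 kcal/mol
```

The fit recovers the packaged increments to machine precision, and the
spread statistics show the proximal substitution dominating the distal
one (exactly zero here because the packaged table carries no distal
increments; `estimate_distal_increments()` fills them from matched
record pairs when distally substituted data exist).

`plot_bridge_matrix()` renders the usual EA / SM / difference heatmap
panels, and `inst/scripts/hbridge-cli.R` wraps extract / fit / predict
/ simulate / report for shell use.

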