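# xpdtdose

Desk-scale Monte Carlo simulation of kilovoltage X-ray energy selection
for nanoparticle-mediated dose enhancement in X-ray-induced photodynamic
therapy (X-PDT).

X-PDT drives scintillating high-Z nanoprobes with an external kV beam;
the locally absorbed dose is the physical proxy for the initial
reactive-oxygen yield, so the tube potential that maximizes the
**dose-enhancement ratio**

```
DER(z) = D_with_probe(z) / D_without_probe(z)
```

is the quantity of clinical interest. `xpdtdose` is written for medical
physicists and nanomedicine researchers who want to screen tube
potentials, probe concentrations or probe compositions without a
full-scale Geant4 run: it generates filtered tungsten-anode kVp spectra,
transports photons through voxelized tumor phantoms under the kerma
approximation (with explicit K-fluorescence escape for the lanthanide
constituents), and computes depth dose, percentage depth dose (PDD),
layer-wise DER, the tumor average absorbed dose (AAD) and its
enhancement ratio, per-voxel statistical uncertainties, a closed-form
slab-absorption oracle, and a synthetic tumor-growth-inhibition cohort
for dose-to-outcome correlation.

The modeled system: a 5 mm cubic tumor on a 6 x 3 x 3 cm water slab,
irradiated top-down by a parallel beam exactly covering the tumor face,
with the tumor either water (Model A) or a 10 mg/mL aqueous suspension of
`Na(Lu0.65Gd0.20Tb0.15)F4` nanocrystals (Model B); Models C/D are the
isolated cubes. Dose is scored on 0.2 mm voxels (25^3 in the tumor),
with uncertainties from 10 independent batches.

## Worked example

Compare Models A and B at 60 kVp with a million histories per arm:

```r
library(xpdtdose)
tabs <- load_xsec_tables()

spec <- generate_spectrum(tube_config(60), tabs)
spec
#> <xray_spectrum> 118 bins, 1.25-59.75 keV (60 kVp), mean 26.94 keV

runA <- run_transport(build_model("A"), spec, transport_config(1e6, seed = 42), tabs)
runB <- run_transport(build_model("B"), spec, transport_config(1e6, seed = 42), tabs)
runB
#> <dose_grid> Model B @ 60 kVp, 1e+06 histories: tumor edep 5.198e+06 keV (19.3% of emitted)

der <- der_curve(depth_dose(runB), depth_dose(runA))
der
#> <depth_curve> DER: 25 layers, 0.10-4.90 mm, max 1.303 at 0.30 mm

aad_der(runB, runA)
#> [1] 1.229
max_rel_uncertainty(runB)
#> [1] 0.327
```

Reading the numbers: the generated 60 kV spectrum has a fluence-weighted
mean energy of 26.9 keV; adding the nanoprobe raises the layer dose by up
to 30% (peak DER 1.30 in the shallow layers) and the whole-tumor average
dose by 23% (AAD enhancement 1.229). The per-voxel relative standard
error in the high-dose region is 33% at 10^6 histories, i.e. about 1%
when extrapolated by `1/sqrt(N)` to a 10^9-history production run.

The full pipeline (spectra -> both arms -> endpoints -> synthetic cohort
-> AAD--TGI correlation, plus a reproducibility manifest) runs from a
single YAML config:

```r
run_pipeline(list(n_photons = 1e6, kvp_list = c(40, 80, 120, 160)),
             out_dir = "out")
```

or from the shell via the thin CLI in `exec/xpdt`
(`xpdt spectrum --kvp 60 --out spec60.tsv`, `xpdt simulate ...`,
`xpdt pipeline ...`).

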