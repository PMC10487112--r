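# hgmrs

Quantification of the oncometabolite **2-hydroxyglutarate (2-HG)** from in
vivo proton MR spectroscopy, for non-invasive prediction of IDH mutation
status in diffuse glioma.

IDH-mutant gliomas accumulate 2-HG, whose resonance near 2.25 ppm overlaps
the glutamate + glutamine C3 signal (**Glx3**, window 2.25–2.35 ppm) but
not the C4 signal (**Glx4**, 2.31–2.40 ppm). In healthy tissue the
Glx3/Glx4 area ratio is a stable 0.81 ± 0.06, so 2-HG is read out as the
percentage elevation of the tumor ratio over the contralateral reference:

    E = 100 * (R_tumor / R_contra - 1) [%],   R = area(Glx3) / area(Glx4)

with `E > 0%` called positive. Assuming similar relaxation for 2-HG and
Glx, `[2-HG] ≈ (E/100) * ([Glu] + [Gln])` mmoles/kg — a typical 15 %
elevation is about 2.2 mmoles/kg in gray matter, 1.3 in white matter.

The package provides:

* **`specproc`** — the spectral post-processing chain, in order:
  water-reference eddy-current correction, Hanning apodization (512 ms),
  zero filling (1024 → 2048), Fourier transformation, NAA-anchored
  frequency alignment, degree-6 polynomial baseline correction, zero-order
  phase correction (`process()` and the individual stages).
* **`peakfit`** — bounded Gaussian fitting inside the eight chemical-shift
  windows (Cr2, Ins2, Ins1, Cho, Cr1, Glx3, Glx4, NAA), with a joint fit
  resolving the overlapping Glx3/Glx4 pair (`fit_panel()`,
  `fit_glx_pair()`).
* **`hgquant`** — the elevation statistic, classification, and the
  concentration conversion (`quantify_voxel()`, `elevation()`,
  `estimate_concentration()`).
* **a simulator** — synthetic FIDs, water references, CSI grids and whole
  cohorts with known ground truth (`simulate_fid()`, `simulate_cohort()`).
* **cohort statistics** — Pearson correlation with case-resampling
  bootstrap, PPV/NPV, genotype subgroup comparison, and a packaged
  checksummed 11-patient clinical reference table (`run_cohort_analysis()`,
  `load_table1()`).
* **a CLI** — `exec/hgmrs` with `simulate`, `process`, `quantify`,
  `analyze`, and `reproduce-table1` subcommands over a plain-text
  CSV + JSON-sidecar spectrum format.

## Worked example

Simulate a tumor voxel carrying 2.235 mmoles/kg of 2-HG over the
gray-matter Glu + Gln pool of 14.9 mmoles/kg (true elevation exactly 15 %),
process and fit both voxels, and quantify:

```r
library(hgmrs)
acq <- mrs_acq()   # 1024 pts, 0.5 ms dwell, 3 T, TR/TE 1500/40 ms
conc <- default_concentrations("gray"); conc[["2HG"]] <- 2.235
tumor  <- process(simulate_fid(voxel_truth(conc), acq, seed = 1))
contra <- process(simulate_fid(voxel_truth(default_concentrations("gray")),
                               acq, seed = 2))
quantify_voxel(fit_panel(tumor), reference_ratio(fit_panel(contra)))
#> <hg_result> Glx3/Glx4 tumor 0.928 vs reference 0.809: elevation +14.7% -> positive
```

The tumor ratio 0.928 exceeds the fitted healthy reference 0.809 by
14.7 % — the injected 15 % recovered to within 0.4 points — and converting
back through the gray-matter pool gives
`estimate_concentration(14.7, 11.7, 3.2)` ≈ 2.19 mmoles/kg against the
injected 2.235.

Re-running the clinical cohort analysis:

```r
cmd_reproduce_table1()
#> Cohort analysis (n = 11)
#>   Pearson r (MRS % vs ex vivo 2-HG): 0.80 (p = 0.003), 95% CI 0.27..0.98
#>   Positive calls: 8; PPV 100%, NPV 33% (TP 8, FP 0, TN 1, FN 2)
#>   Ex vivo 2-HG: non-R132H mean 5.45 vs R132H mean 1.38 mmoles/kg (p = 0.079)
#>   Ex vivo median 1.73 mmoles/kg (IQR 0.71-2.92)
```

The in vivo elevations track the ex vivo (GC-MS) tissue concentrations
strongly; a positive call was always right in this cohort (PPV 100 %),
while a negative call was usually wrong (NPV 33 %), reflecting two
IDH-mutant tumors with low 2-HG that fell below the 0 % cut-off.

See `vignettes/hgmrs-methods.Rmd` for the model, the numerical design
choices, and what the simulator does and does not emulate.

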