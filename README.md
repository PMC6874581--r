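# cytocore

Processing pipeline for continuous underway flow cytometry of small
phytoplankton (< 5 µm), for oceanographers turning shipboard per-particle
optical measurements into curated records of cell abundance, equivalent
spherical diameter (ESD) and cellular carbon.

Sheathless underway cytometers measure particles anywhere in an open
sample stream; only particles inside the **virtual core** — located by two
position-sensitive detectors D1/D2 — are measured accurately. The package
implements the full chain:

1. **Filtration.** Optimally-positioned particles (OPP) satisfy, in log10
   bead-normalized space, |log₁₀(D1/D2)| ≤ τ (alignment) and
   D1, D2 at or below a two-piece boundary line in forward scatter
   (focus). The two segments of each boundary meet exactly at the
   1-µm-bead anchor, with slopes fit by anchored quantile regression
   (pinball loss) at the 2.5 / 50 / 97.5% confidence quantiles, so the
   OPP sets nest.
2. **Classification.** Sequential polygon gates (beads → *Synechococcus*
   → small *Crocosphaera*), a deterministic 2-D kernel-density mode
   finder for *Prochlorococcus*, and scatter/red-fluorescence thresholds
   for picoeukaryotes; every OPP gets exactly one label.
3. **Mie sizing.** A forward Mie model for homogeneous spheres
   (size parameter x = πDn_med/λ, λ = 457 nm, n_med = 1.34) integrated
   over a two-angle acceptance annulus calibrated to a bead ladder,
   monotonized by isotonic regression, and inverted to ESD at refractive
   indices 1.35 / 1.38 / 1.41 (beads: 1.60).
4. **Carbon.** fgC cell⁻¹ = 0.261 · V^0.860 with V = (π/6)·ESD³ µm³.
5. **Quantification.** abundance = count / (OPP ratio × flow × duration),
   with the flow-calibration SE propagated by the delta method and the
   Poisson SE reported separately.
6. **QC.** Stream-pressure (> 5% from cruise mean) and event-rate
   (> 18,000 s⁻¹) flags, plus single-pass Chauvenet screening
   (band probability 1 − 1/(2N)) of derived quantities.

A seeded cruise simulator (`simulate_cruise()`) emits ground-truthed event
streams, metadata, bead tables and matched gating specs for end-to-end
validation. See the vignette (`vignettes/virtual-core-processing.Rmd`) for
the model details and design rationale.

## Worked example

Simulate a 3-file cruise and run the full pipeline:

```r
library(cytocore)
dir <- file.path(tempdir(), "demo")
sim <- simulate_cruise(sim_config(seed = 1, n_files = 3), dir = dir)
res <- run_pipeline(list(
  input_dir   = file.path(dir, "events"),
  metadata    = file.path(dir, "metadata.csv"),
  bead_table  = file.path(dir, "beads.csv"),
  gating_spec = file.path(dir, "gating.yaml"),
  output_dir  = file.path(dir, "out")))
print(res$filtration)
#> Virtual-core filtration parameters [7481b2db]
#>   bead anchor (log10): fsc 3.0072, d1 2.6786, d2 2.6743 (935 beads)
#>   alignment tolerance |log10(d1/d2)| <= 0.4068
#>   q= 2.5%: d1 below/above 1.4645/-0.4769, d2 1.3937/-0.1777
#>   q=50.0%: d1 below/above 1.0040/0.9941, d2 0.9873/0.9841
#>   q=97.5%: d1 below/above 0.4145/3.0229, d2 0.5517/2.7210
```

The 50% slopes near 1 say position-detector signal tracks forward scatter
one-to-one across the bead cloud; the 2.5 / 97.5% slopes fan around the
anchor and define the nested confidence boundaries. The calibrated Mie
geometry and first file's records:

```r
print(res$model)
#> Mie detector model
#>   wavelength: 457 nm, medium index 1.340, bead index 1.600
#>   cell indices: 1.35, 1.38, 1.41
#>   acceptance annulus: 2.143 - 14.513 degrees
#>   calibrated on 7 beads, R^2 = 0.99989
#>   diameter grid: 2000 points on [0.20, 6.00] micron

r <- res$records
subset(r, file_id == r$file_id[1],
       select = c(population, n, abundance, abundance_se,
                  esd_n138_med, carbon_n138_med))
#>  population     n   abundance abundance_se esd_n138_med carbon_n138_med
#>       beads    89   0.9855856   0.04927928    2.1030249       1.0183988
#>     synecho  1842  20.3982990   1.01991495    1.1045942       0.1933938
#>       croco   177   1.9600971   0.09800486    2.9890724       2.5226868
#>   prochloro 18142 200.9044192  10.04522096    0.6020261       0.0404005
#>     picoeuk   850   9.4128958   0.47064479    1.9568443       0.8456578
```

The simulated truth was 200 / 20 / 10 / 2 cells µL⁻¹ for
*Prochlorococcus* / *Synechococcus* / picoeukaryotes / *Crocosphaera* and
1 bead µL⁻¹; recovered abundances sit within the reported standard errors
(5% flow-calibration SE), and median ESDs match the simulated sizes
(0.6 / 1.1 / 2.0 / 3.0 µm). ESD and carbon for the beads row use the
cell-index lookup and are flagged non-biological. The curated CSV, a
parameter record (filtration/gating ids, calibrated angles) and a JSON-line
run log land in `output_dir`; re-running the same config is byte-identical.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/cytocore simulate --out /tmp/cruise --seed 7
Rscript inst/cli/cytocore qc --metadata /tmp/cruise/metadata.csv
```

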