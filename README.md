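# sniqc — structured noise index QC for gamma-camera flood fields

Daily flood-field uniformity evaluation is the core of a nuclear-medicine
quality-control program, but the traditional pixel-value metric (integral
uniformity, IU) is dominated by counting noise at full resolution and
routinely misses the subtle structured patterns — a faint photomultiplier
dropout, a ripple, a band — that a trained eye would flag. `sniqc`
implements the **structured noise index (SNI)**, a frequency-domain metric
that separates *structured* noise from *quantum* (Poisson) noise and
weights both by a model of human contrast sensitivity, plus the automated
pipeline that puts it to work: DICOM ingest and sorting, a roving-ROI
sweep, Fourier-domain artifact visualization, two-level alerting, archival
by station, and validation statistics against a service log. A Poisson
flood simulator with parameterized sensitivity defects makes the whole
stack testable without clinical data.

## The metric

For an image patch with mean count $\bar I$ and pixel pitch
$\Delta x, \Delta y$, the 2D noise power spectrum is

$$NPS(u,v) = \frac{\Delta x\,\Delta y}{N_x N_y}\,
  \bigl|\mathrm{DFT}\{I - \bar I\}\bigr|^2 ,$$

and the quantum component of that spectrum is flat at
$\bar I\,\Delta x\,\Delta y$ because Poisson variance equals the mean.
With a visual weighting $V(r) = r^{1.3} e^{-c r^2}$ peaked at 4
cycles/degree (viewing distance 150 cm, display 6.5 cm; $c = 0.040625$),

$$\mathrm{SNI} = \frac{\int NPS_{\mathrm{structure}}\,V\,du\,dv}
                       {\int NPS_{\mathrm{input}}\,V\,du\,dv} \in [0,1].$$

An image is scored by the maximum SNI over two large central ROIs and a
64×64 window roving in 16-px steps (169 positions on a 256² flood). Alerts
fire above 0.50 (physics staff) and 0.60 (physics + clinical +
engineering).

## Worked example

```r
library(sniqc)

# a clean flood and one with a failing PMT (20% dip, FWHM 32 px)
clean <- simulate_flood(make_sensitivity_map(c(256, 256), list()),
                        total_counts = 5e6, seed = 11, station = "CAM_A")
bad   <- simulate_flood(make_sensitivity_map(c(256, 256), list(
           defect_spec("pmt_dropout", 0.20, center = c(96, 160), width = 32))),
         total_counts = 5e6, seed = 11, station = "CAM_A")

image_sni(clean)
#> <sni_result> image SNI 0.3170 at ROI (64,16) size 64 (170 ROIs)
res <- image_sni(bad)
res
#> <sni_result> image SNI 0.9104 at ROI (80,144) size 64 (170 ROIs)
classify_alert(res$image_sni, alert_config())
#> [1] "upper"
```

The clean flood scores 0.32 — the typical null level for a 5M-count
daily flood, well below the 0.50 alert threshold — while the defective one
scores 0.91, an upper-level alert, and the winning ROI (origin row 80,
col 144, 64 px) covers the injected defect at (96, 160). The traditional
IU barely separates the two, because at ~76 counts/pixel the smoothed
Poisson noise alone dwarfs a 20% local dip:

```r
integral_uniformity(clean)  #> 18.66  (percent, UFOV)
integral_uniformity(bad)    #> 25.44
res$artifact
#> <artifact_image> 256x256, 46 coefficients retained (cutoff 7446)
```

The artifact image retains only the 46 Fourier coefficients inconsistent
with counting noise (a clean flood retains ~1), rendering the dropout
visually. `process_image()` runs the whole chain — read, sort, score,
alert, archive, record — on a DICOM file; `render_quadrant_figure()` writes
the standard four-panel diagnostic (input / artifact image / worst ROI /
its NPS). A thin command-line front end lives at `inst/cli/sniqc`
(`analyze`, `simulate`, `report`).

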