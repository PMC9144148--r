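# renoperf

Quantitative analysis for preclinical studies of microcapsule delivery
through the renal artery. When polyelectrolyte microcapsules (a few
micrometres in diameter) are injected into a kidney's feeding artery, they
lodge in glomerular and peritubular capillaries; too large a capsule or too
high a dose arrests perfusion irreversibly. `renoperf` implements the three
readouts such a study rests on, together with synthetic-data generators
that make every step testable against known ground truth:

1. **Laser speckle contrast imaging (LSCI) flow analysis.** Spatial speckle
   contrast `K = sigma / mu` in a 5 x 5 sliding window, averaging of 25
   consecutive contrast frames, conversion to the flow index `1/K^2`,
   Gaussian smoothing (sigma 7 px), ROI statistics, normalization to each
   subject's pre-injection baseline, and a three-way safety classification
   (*physiological* / *reversible-drop* / *irreversible-drop*) around the
   rule that flow changes within 20% of baseline are physiologically
   normal.
2. **Optoacoustic (RSOM) frequency-band analysis.** Brick-wall spectral
   splitting of broadband acoustic signals into the low (11–33 MHz, large
   vessels) and high (33–99 MHz, capillaries) bands, per-band mean power,
   the alteration `A = 100 * I_t / I_0` relative to the pre-injection
   timepoint, and depth-resolved band profiles of two-channel reconstructed
   volumes.
3. **Biodistribution (%ID).** Imaging-based organ percent-injected-dose
   from total radiant efficiency with area-scaled autofluorescence
   correction,
   `TRE_organ = TRE_exp - (TRE_ctrl / Area_ctrl) * Area_exp`,
   `%ID_organ = 100 * TRE_organ / sum(TRE)`; and digest-based dye
   quantification via a linear calibration at the 785 nm emission peak,
   `%ID = 100 * mass_in_sample / mass_injected`.

The speckle generator produces dynamic fully developed speckle from a
complex circular-Gaussian field with a first-order autoregressive time
evolution, so the measured contrast follows the finite-exposure curve
`K^2 = beta * (e^(-2x) - 1 + 2x) / (2x^2)`, `x = T / tau_c` — the analytic
oracle the test suite checks against. Flow enters through the standard
single-scattering assumption `relative flow = baseline tau_c / tau_c`.

## Worked example

Simulate a flow experiment in which perfusion truly halves at 15 min and
recovers to 80% at 24 h, then run the full LSCI chain and classify it:

```r
library(renoperf)

cfg <- speckle_config(frame_height = 128, frame_width = 128, n_frames = 25)
ex  <- simulate_flow_experiment(
  baseline_tau_c_ms = 0.4,
  relative_flows    = c(baseline = 1, "15 min" = 0.5, "24 h" = 0.8),
  cfg = cfg, seed = 7)
series <- lsci_experiment_series(ex, roi = roi_spec(33, 33, 64, 64))
series
#> <flow_series> baseline = "baseline"
#>  timepoint roi_mean roi_sd percent_of_baseline
#>   baseline    28.31 0.2946              100.00
#>     15 min    14.69 0.1808               51.89
#>       24 h    22.74 0.3252               80.33
classify_flow_response(series, final_label = "24 h")
#> <safety_label> reversible-drop (threshold 20%)
```

The recovered percentages (51.9%, 80.3%) match the generator truth (50%,
80%) to within the pipeline's statistical precision, and the series is
classified reversible: an intermediate dip below 80% of baseline with a
recovered final point. A persistent final value below 80% would be
`irreversible-drop`.

Organ %ID recovery from a noisy synthetic dissection table (5% CV), with
the true shares alongside:

```r
truth <- c("left kidney" = 44, "right kidney" = 5, lungs = 6, heart = 2,
           liver = 25, spleen = 3, stomach = 5, intestines = 9, appendix = 1)
tabs <- simulate_organ_tables(truth, autofl_per_area = 1e5,
                              noise_cv = 0.05, seed = 1)
pid <- percent_id_from_tre(correct_organ_table(tabs$experimental, tabs$control))
#>          organ percent_id true
#> 1  left kidney      43.05   44
#> 2 right kidney       5.17    5
#> ...
#> 9     appendix       1.08    1
```

The dose–size trade-off arithmetic:

```r
relative_change(3.1, 4.0)    # +29% capsule diameter
relative_change(20e6, 10e6)  # -50% largest safe dose
```

A complete run (speckle + acoustics + biodistribution + plate) from one
YAML config:

```r
run_pipeline(system.file("extdata", "demo-config.yaml", package = "renoperf"),
             out_dir = "demo-out")
```

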