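# Demo configuration: one full synthetic run mirroring the in vivo study
# design (timepoint schedule, organ panel, six animal groups). All numbers
# here are generator inputs, not measurements.
output_dir: renoperf-demo
stages: [lsci, pa, biodist, plate]

lsci:
  baseline_tau_c_ms: 0.4
  # an unsafe-dose trajectory: flow at 47% of baseline at 15 min, 53% at 24 h
  relative_flows: {baseline: 1.0, "15 min": 0.47, "24 h": 0.53}
  final_label: "24 h"
  threshold_percent: 20
  speckle: {frame_height: 128, frame_width: 128, n_frames: 25,
            exposure_ms: 10, fps: 30}
  roi: {row: 33, col: 33, height: 64, width: 64}
  seed: 11

pa:
  reference: before
  fs_hz: 4.0e+8
  duration_s: 2.0e-5
  # [low, high] RMS amplitudes per timepoint: near-total signal loss at
  # 5-15 min, partial low-band recovery, high band persistently depressed
  timepoints:
    before: [2.0, 1.0]
    "5 min": [0.1, 0.05]
    "15 min": [0.2, 0.1]
    "1 h": [1.2, 0.4]
    "24 h": [2.6, 0.5]
    "5 days": [1.4, 0.3]
  seed: 12

biodist:
  true_percent_id: {left kidney: 44, right kidney: 5, lungs: 6, heart: 2,
                    liver: 25, spleen: 3, stomach: 5, intestines: 9,
                    appendix: 1}
  autofl_per_area: 1.0e+5
  noise_cv: 0.05
  seed: 13

plate:
  standard_masses: [0, 0.5, 1, 2, 4]
  sample_masses: [1.2]
  slope: 1200
  intercept: 300
  noise_sd: 12
  injected_mass: 4
  seed: 14

# The six-group in vivo design: control, sham (saline), and four capsule
# dose groups. Flow outcomes for the 30e6 small-capsule group are not
# asserted (illustrative NA).
dose_groups:
  threshold_percent: 20
  groups:
    - {role: control, label: "no injection"}
    - {role: sham, label: "saline"}
    - {role: capsules, diameter_um: 3.1, dose: 2.0e+7,
       percent_15min: 85, percent_24h: 95}
    - {role: capsules, diameter_um: 3.1, dose: 3.0e+7}
    - {role: capsules, diameter_um: 4.0, dose: 1.0e+7,
       percent_15min: 83, percent_24h: 92}
    - {role: capsules, diameter_um: 4.0, dose: 2.0e+7,
       percent_15min: 47, percent_24h: 53}
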