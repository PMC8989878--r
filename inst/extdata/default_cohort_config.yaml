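n_per_group:
  Control: 3.0
  CPA: 9.0
  CPA+Ab: 14.0
days:
- 0.0
- 1.0
- 2.0
- 3.0
- 4.0
- 5.0
- 6.0
- 9.0
- 12.0
- 15.0
- 18.0
- 21.0
- 24.0
- 27.0
- 30.0
baseline:
  volume: 250.0
  a: 1.2
  b: 1.3
  ctHbO2: 60.0
  ctHHb: 40.0
baseline_cv:
  volume: 0.05
  a: 0.08
  b: 0.05
  ctHbO2: 0.1
  ctHHb: 0.1
subject_sd: 0.15
day_noise_sd:
  a: 2.0
  b: 2.0
  ctHbO2: 4.0
  ctHHb: 5.0
  volume: 8.0
caliper_cv: 0.02
aspect_mean: 1.2
aspect_sd: 0.05
background:
  a: 1.0
  b: 1.3
  ctHbO2: 30.0
  ctHHb: 15.0
trajectories:
  Control:
    a:
      day:
      - 0.0
      - 3.0
      - 5.0
      - 9.0
      - 12.0
      pct:
      - 0.0
      - -4.0
      - -10.0
      - -12.0
      - -14.0
    b:
      day:
      - 0.0
      - 12.0
      pct:
      - 0.0
      - -4.0
    ctHbO2:
      day:
      - 0.0
      - 3.0
      - 6.0
      - 12.0
      pct:
      - 0.0
      - 10.0
      - 0.0
      - -10.0
    ctHHb:
      day:
      - 0.0
      - 3.0
      - 5.0
      - 6.0
      - 9.0
      - 12.0
      pct:
      - 0.0
      - 40.0
      - 60.0
      - 55.0
      - 35.0
      - 15.0
    volume:
      day:
      - 0.0
      - 1.0
      - 2.0
      - 3.0
      - 4.0
      - 5.0
      - 6.0
      - 9.0
      - 12.0
      pct:
      - 0.0
      - 15.0
      - 32.0
      - 70.0
      - 100.0
      - 150.0
      - 200.0
      - 400.0
      - 700.0
  CPA:
    a:
      day:
      - 0.0
      - 1.0
      - 3.0
      - 5.0
      - 9.0
      - 12.0
      - 21.0
      - 30.0
      pct:
      - 0.0
      - 0.0
      - 3.0
      - 9.0
      - 18.0
      - 25.0
      - 35.0
      - 45.0
    b:
      day:
      - 0.0
      - 30.0
      pct:
      - 0.0
      - -10.0
    ctHbO2:
      day:
      - 0.0
      - 6.0
      - 12.0
      - 30.0
      pct:
      - 0.0
      - 0.0
      - 10.0
      - 10.0
    ctHHb:
      day:
      - 0.0
      - 3.0
      - 5.0
      - 6.0
      - 9.0
      - 12.0
      - 15.0
      - 21.0
      - 30.0
      pct:
      - 0.0
      - -5.0
      - -5.0
      - 0.0
      - 15.0
      - 30.0
      - 40.0
      - 50.0
      - 50.0
    volume:
      day:
      - 0.0
      - 3.0
      - 5.0
      - 6.0
      - 9.0
      - 12.0
      - 30.0
      pct:
      - 0.0
      - 40.0
      - 28.0
      - 12.0
      - -25.0
      - -50.0
      - -70.0
  CPA+Ab:
    a:
      day:
      - 0.0
      - 1.0
      - 3.0
      - 5.0
      - 9.0
      - 12.0
      - 21.0
      - 30.0
      pct:
      - 0.0
      - 0.0
      - -6.0
      - -10.0
      - -13.0
      - -15.0
      - -18.0
      - -20.0
    b:
      day:
      - 0.0
      - 30.0
      pct:
      - 0.0
      - -4.0
    ctHbO2:
      day:
      - 0.0
      - 30.0
      pct:
      - 0.0
      - 5.0
    ctHHb:
      day:
      - 0.0
      - 3.0
      - 5.0
      - 6.0
      - 9.0
      - 12.0
      - 15.0
      - 21.0
      - 30.0
      pct:
      - 0.0
      - -5.0
      - -5.0
      - 0.0
      - 15.0
      - 30.0
      - 40.0
      - 25.0
      - 25.0
    volume:
      day:
      - 0.0
      - 3.0
      - 5.0
      - 9.0
      - 12.0
      - 30.0
      pct:
      - 0.0
      - 24.0
      - 40.0
      - 72.0
      - 80.0
      - 85.0
instrument:
  n_px: 64.0
  pixel_pitch_mm: 0.5
  wavelengths:
  - 659.0
  - 691.0
  - 731.0
  - 851.0
  fx:
  - 0.0
  - 0.1
  phases:
  - 0.0
  - 120.0
  - 240.0
  mtf_ac: 0.7
  noise_frac: 0.01
  drift_sd: 0.02
  height_gain_per_mm: -0.02
  n_rel: 1.4
seed: 1

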