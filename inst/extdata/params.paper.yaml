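# Study-default run configuration: 6 subjects x 5 training sessions x 9
# scheduled samplings; windows are hours relative to exposure onset.
design:
  n_subjects: 6
  n_sessions: 5
  windows:
    - {window_index: 1, t_min: -5.3, t_max: -2.3, t_mean: -4.2}
    - {window_index: 2, t_min: -1.0, t_max: -0.1, t_mean: -0.4}
    - {window_index: 3, t_min: 1.5, t_max: 2.4, t_mean: 2.0}
    - {window_index: 4, t_min: 2.5, t_max: 3.6, t_mean: 3.0}
    - {window_index: 5, t_min: 4.5, t_max: 5.6, t_mean: 5.2}
    - {window_index: 6, t_min: 7.4, t_max: 8.6, t_mean: 8.1}
    - {window_index: 7, t_min: 9.6, t_max: 12.8, t_mean: 11.2}
    - {window_index: 8, t_min: 11.6, t_max: 14.1, t_mean: 12.7}
    - {window_index: 9, t_min: 18.2, t_max: 21.8, t_mean: 20.1}
  exposure_duration: 0.75
  unscheduled_void_rate: 0.10
  urine_flow_mean: 0.06
  urine_flow_cv: 0.5
  creatinine_rate_mean: 0.0625
  creatinine_subject_cv: 0.2
  creatinine_void_cv: 0.3
  baseline_subject_cv: 0.4
  overnight_gap: 8
# LODs and assay CVs per the analytical method; ke from the reported mean
# elimination half-lives (6.6 / 6.2 / 5.2 / 7.7 h); ka and doses place the
# noise-free peak in window 4 (window 5 for PYR1) at the reported medians.
analytes:
  DHN:  {name: DHN,  lod: 0.3,  assay_cv: 0.094, baseline_rate: 0.19,
         dose_mean: 100,  dose_cv: 0.5, ka: 1.2,  ke: 0.105022300,  fe: 1}
  NAP1: {name: NAP1, lod: 0.1,  assay_cv: 0.128, baseline_rate: 0.031,
         dose_mean: 8.3,  dose_cv: 0.5, ka: 1.2,  ke: 0.111797932,  fe: 1}
  NAP2: {name: NAP2, lod: 0.1,  assay_cv: 0.142, baseline_rate: 0.125,
         dose_mean: 6.1,  dose_cv: 0.5, ka: 1.2,  ke: 0.133297535,  fe: 1}
  PYR1: {name: PYR1, lod: 0.02, assay_cv: 0.156, baseline_rate: 0.0031,
         dose_mean: 0.37, dose_cv: 0.5, ka: 0.40, ke: 0.090019114,  fe: 1}
options:
  seed: 1
  baseline_window: 2
  ar1: order
  percentiles: linear
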