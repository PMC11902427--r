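# Synthetic exoskeleton parameter file.
#
# These values are a plausible, internally consistent stand-in for a
# commercial active lumbar exoskeleton, intended as ground truth for
# simulation and round-trip calibration studies. They are NOT measurements
# of any physical device.
#
# Units: angles deg, velocities deg/s, torques N*m (per side), lever arms m,
# weight kgf. Active rows satisfy intercept = -slope * vel_lim and
# vel_max = (tau_a_max - intercept) / slope.
schema_version: 1
passive:
  characteristic_angles: [10.0, 30.0, 50.0, 65.0, 80.0]
  torque_ratios: [0.0, 0.2, 0.5, 0.8, 1.0]
  tau_max:
    "0": 0.0
    "10": 3.0
    "20": 6.0
    "30": 9.0
    "40": 12.0
    "50": 15.0
    "60": 18.0
    "70": 21.0
    "80": 24.0
    "90": 27.0
    "100": 30.0
active:
  psi_a: 30.0
  rows:
    "0":   {tau_a_max: 0.0,  vel_lim: 30.0, slope: 0.0,  intercept: 0.0}
    "10":  {tau_a_max: 2.0,  vel_lim: 30.0, slope: 0.05, intercept: -1.5}
    "20":  {tau_a_max: 4.0,  vel_lim: 30.0, slope: 0.1,  intercept: -3.0}
    "30":  {tau_a_max: 6.0,  vel_lim: 30.0, slope: 0.15, intercept: -4.5}
    "40":  {tau_a_max: 8.0,  vel_lim: 30.0, slope: 0.2,  intercept: -6.0}
    "50":  {tau_a_max: 10.0, vel_lim: 28.0, slope: 0.25, intercept: -7.0}
    "60":  {tau_a_max: 12.0, vel_lim: 26.0, slope: 0.3,  intercept: -7.8}
    "70":  {tau_a_max: 14.0, vel_lim: 24.0, slope: 0.35, intercept: -8.4}
    "80":  {tau_a_max: 16.0, vel_lim: 22.0, slope: 0.4,  intercept: -8.8}
    "90":  {tau_a_max: 18.0, vel_lim: 20.0, slope: 0.45, intercept: -9.0}
    "100": {tau_a_max: 20.0, vel_lim: 18.0, slope: 0.5,  intercept: -9.0}
body:
  d_tt: 0.45
  d_mt: 0.25
device:
  weight_kgf: 7.5
  shoulder_fraction: 0.5
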