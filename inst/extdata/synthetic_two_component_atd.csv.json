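{
  "truth": [
    {
      "component": 1,
      "amplitude": 60000,
      "center_ms": 5.81020833333333,
      "sigma_ms": 0.219751233938746
    },
    {
      "component": 2,
      "amplitude": 90000,
      "center_ms": 7.2126724137931,
      "sigma_ms": 0.307916807071696
    }
  ],
  "charge": 7,
  "noise": "poisson",
  "slack": [1, 1],
  "instrument": {
    "drift_length": 0.2505,
    "drift_voltage": 150,
    "temperature": 298,
    "pressure": 400,
    "injection_pulse": 0.00015,
    "buffer_gas_mass": 4.002602,
    "coulomb_factor": 1,
    "number_density_ref": 2.68678011179844e+25
  }
}
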