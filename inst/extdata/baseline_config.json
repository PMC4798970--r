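{
  "parameters": {
    "d_K": 9.64,
    "n": 1,
    "d": 0.163,
    "gamma": 0.514,
    "d_I": 0.806,
    "p": 25.1,
    "a": 173,
    "kappa": 0.218,
    "k_I": 13.3,
    "d_RI": 2.41,
    "k_on_I": 4.68,
    "k_on0_I": 0.0908,
    "k_off_I": 11.8,
    "k_off0_I": 0.189,
    "k_on_A": 4.52,
    "k_on0_A": 0.00948,
    "k_off_A": 19.6,
    "k_off0_A": 0.308,
    "d_RA": 17.9,
    "k_A": 1.47,
    "d_A": 1.28
  },
  "repressor_active": true,
  "degrees": {
    "d_K": 0.3,
    "n": 1,
    "d": 0.3,
    "gamma": 0.3,
    "d_I": 0.3,
    "p": 0.3,
    "a": 0.3,
    "kappa": 0.3,
    "k_I": 0.3,
    "d_RI": 0.3,
    "k_on_I": 1,
    "k_on0_I": 1,
    "k_off_I": 1,
    "k_off0_I": 1,
    "k_on_A": 1,
    "k_on0_A": 1,
    "k_off_A": 1,
    "k_off0_A": 1,
    "d_RA": 1,
    "k_A": 1,
    "d_A": 1
  },
  "forcings": {
    "constant_D10": {
      "kind": "constant",
      "S_high": 2,
      "S_low": 0,
      "pulse_len": 15,
      "decay_halflife": 30,
      "t_start": 0
    },
    "Tf90_D10": {
      "kind": "square",
      "S_high": 2,
      "S_low": 0,
      "T1": 45,
      "T2": 45,
      "pulse_len": 15,
      "decay_halflife": 30,
      "t_start": 0
    },
    "Tf180_T1_30": {
      "kind": "square",
      "S_high": 2,
      "S_low": 0,
      "T1": 30,
      "T2": 150,
      "pulse_len": 15,
      "decay_halflife": 30,
      "t_start": 0
    },
    "sawtooth_Tf90": {
      "kind": "sawtooth",
      "S_high": 2,
      "S_low": 0,
      "period": 90,
      "pulse_len": 15,
      "decay_halflife": 30,
      "t_start": 0
    }
  }
}
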