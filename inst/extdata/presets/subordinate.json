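{
  "status": "subordinate",
  "cells": {
    "E": {
      "C": 20,
      "gK": 8,
      "gL": 2,
      "gCa": 4,
      "gKCa": 0.25,
      "vK": -84,
      "vL": -60,
      "vCa": 120,
      "k1": 10,
      "v1": -1.2,
      "v2": 18,
      "v3": 12,
      "v4": 17,
      "phi": 0.23,
      "eps": 0.005,
      "mu": 0.19,
      "kCa": 1
    },
    "GA": {
      "C": 20,
      "gK": 8,
      "gL": 2,
      "gCa": 4,
      "gKCa": 0.25,
      "vK": -84,
      "vL": -60,
      "vCa": 120,
      "k1": 10,
      "v1": -1.2,
      "v2": 18,
      "v3": 12,
      "v4": 17,
      "phi": 0.23,
      "eps": 0.005,
      "mu": 0.19,
      "kCa": 1
    },
    "GL": {
      "C": 20,
      "gK": 8,
      "gL": 2,
      "gCa": 4,
      "gKCa": 0.25,
      "vK": -84,
      "vL": -60,
      "vCa": 120,
      "k1": 10,
      "v1": -1.2,
      "v2": 18,
      "v3": 12,
      "v4": 17,
      "phi": 0.23,
      "eps": 0.005,
      "mu": 0.19,
      "kCa": 1
    },
    "M": {
      "C": 1,
      "gK": 8,
      "gL": 2,
      "gCa": 4,
      "gKCa": 0.3,
      "vK": -84,
      "vL": -60,
      "vCa": 120,
      "k1": 10,
      "v1": -1.2,
      "v2": 18,
      "v3": 12,
      "v4": 17,
      "phi": 0.23,
      "eps": 0.005,
      "mu": 0.19,
      "kCa": 0.9
    }
  },
  "kinetics": {
    "E": {
      "alpha": 15,
      "beta": 0.1,
      "theta_s": 0,
      "sigma_s": 4
    },
    "GA": {
      "alpha": 4,
      "beta": 0.08,
      "theta_s": 0,
      "sigma_s": 4
    },
    "GL": {
      "alpha": 8,
      "beta": 0.08,
      "theta_s": 0,
      "sigma_s": 4
    }
  },
  "connections": {
    "gE_GA": 0.3,
    "vE_GA": 40,
    "gE_GL": 0.3,
    "vE_GL": 40,
    "gGA_GL": 0.4,
    "vGA_GL": -50,
    "gE_M": 0.24,
    "vE_M": 40,
    "gGA_M": 0.4,
    "gGL_M": 0.2,
    "vG_M": -50,
    "gM_M": 0.1,
    "vM_M": -50,
    "sM_const": 0.029
  },
  "modulation": {
    "D1_M": 0.015,
    "D1_GL": 0.25,
    "gI_max": 15,
    "k2": 10,
    "rho": 10000
  },
  "drives": {
    "E": 43.9,
    "GA": 36,
    "GL": 36,
    "M": 19.5
  },
  "gI_law": "saturating"
}
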