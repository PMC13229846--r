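{
  "version": "1.0",
  "note": "Published PLS prediction equations for carrot pigment contents (mg/100 g FW) from the five CIELab/Ch colour parameters. Coefficients are transcribed verbatim; the two printed versions of the default-condition total-carotenoid model (eq9 vs table3) differ and both are kept.",
  "models": {
    "eq8": {
      "pigment": "tac",
      "light_condition": "WF0",
      "coefficients": {
        "L_star": 0.524,
        "a_star": -255.3,
        "b_star": -239.0,
        "C_star": 437.4,
        "h_deg": 25.2
      }
    },
    "eq9": {
      "pigment": "tcc",
      "light_condition": "WF0",
      "coefficients": {
        "L_star": -1.71,
        "a_star": 2.56,
        "b_star": -9.70,
        "C_star": 7.90,
        "h_deg": 5.43
      }
    },
    "eq10": {
      "pigment": "tac",
      "light_condition": "PF0",
      "coefficients": {
        "L_star": 20.1,
        "a_star": -458.5,
        "b_star": -402.6,
        "C_star": 794.5,
        "h_deg": 10.0
      }
    },
    "eq11": {
      "pigment": "tcc",
      "light_condition": "PF0",
      "coefficients": {
        "L_star": -2.77,
        "a_star": 2.65,
        "b_star": -11.2,
        "C_star": 9.31,
        "h_deg": 6.55
      }
    },
    "table3:tac": {
      "pigment": "tac",
      "light_condition": "WF0",
      "coefficients": {
        "L_star": 0.524,
        "a_star": -255.3,
        "b_star": -239.0,
        "C_star": 437.4,
        "h_deg": 25.2
      }
    },
    "table3:tcc": {
      "pigment": "tcc",
      "light_condition": "WF0",
      "coefficients": {
        "L_star": 1.211,
        "a_star": 4.877,
        "b_star": -13.41,
        "C_star": 16.13,
        "h_deg": 6.480
      }
    },
    "table3:lutein": {
      "pigment": "lutein",
      "light_condition": "WF0",
      "coefficients": {
        "L_star": -0.01415,
        "a_star": -0.06352,
        "b_star": -0.04511,
        "C_star": -0.07839,
        "h_deg": -0.003790
      }
    },
    "table3:alpha_carotene": {
      "pigment": "alpha_carotene",
      "light_condition": "WF0",
      "coefficients": {
        "L_star": 0.02682,
        "a_star": -2.898,
        "b_star": -12.42,
        "C_star": 9.467,
        "h_deg": 4.052
      }
    },
    "table3:beta_carotene": {
      "pigment": "beta_carotene",
      "light_condition": "WF0",
      "coefficients": {
        "L_star": 0.354,
        "a_star": -5.917,
        "b_star": -24.53,
        "C_star": 19.89,
        "h_deg": 6.291
      }
    }
  }
}
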