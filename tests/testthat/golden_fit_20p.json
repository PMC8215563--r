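{
  "beta": {
    "(Intercept)": 346.552210668432,
    "time_s": -0.556660245373606,
    "exposureA/T": 28.626077190396,
    "exposureA/A": 10.2196960682177,
    "time_s:exposureA/T": -0.107245010580897,
    "time_s:exposureA/A": -0.0835081332047822
  },
  "reml_loglik": -5935.20539187395,
  "sd_weight": 102.822390951718,
  "icc": 0.907743728332886
}
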