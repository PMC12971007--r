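{
  "comment": "Quadratic relaxivity law 1/T2 = a + b*(1-Y) + c*(1-Y)^2 (s^-1) with haematocrit polynomials a = a1 + a2*h + a3*h^2, b = b1*h + b2*h^2, c = c1*h*(1-h); published 3 T TRUST blood calibration, CPMG inter-echo spacing 10 ms.",
  "a": [-13.5, 80.2, -75.9],
  "b": [-0.5, 3.4],
  "c": [247.4],
  "valid_y_range": [0.4, 0.95]
}
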