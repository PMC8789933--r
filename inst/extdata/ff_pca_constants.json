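{
  "feature_names": ["CS1_FW1", "CS1_FW2", "CS1_FW3", "CS1_G",
                    "CS2_FW1", "CS2_FW2", "CS2_FW3", "CS2_G"],
  "mu_ff":    [45.3, 33.1, 18.8, 80.6, 44.1, 32.2, 18.4, 79.8],
  "sigma_ff": [11.8,  5.8,  3.6, 21.7, 23.1,  9.1,  6.5, 18.9],
  "eigenvalues": [3.6423, 1.7643, 1.5316, 0.4671, 0.3226, 0.1748, 0.0606, 0.0368],
  "eigenvectors": [
    [ 0.4309,  0.3716,  0.3411,  0.2385,  0.3313,  0.4475,  0.3517,  0.2632],
    [-0.2169, -0.0757, -0.0983,  0.6501,  0.0487, -0.2390, -0.2191,  0.1026],
    [ 0.0818,  0.5303,  0.5431, -0.0157, -0.2471, -0.2924, -0.5142, -0.0768],
    [-0.2179,  0.0431,  0.0444, -0.2122,  0.8958, -0.1628, -0.2650, -0.0662],
    [ 0.8062, -0.0306, -0.4364,  0.0212,  0.0977, -0.3044, -0.2357, -0.0207],
    [-0.2394,  0.6778, -0.6126,  0.0986, -0.0299,  0.2633, -0.1047, -0.1308],
    [-0.0499,  0.2873, -0.1001, -0.5500, -0.0699, -0.3928,  0.3750,  0.5506],
    [ 0.0616, -0.1735, -0.0375, -0.4031, -0.0944,  0.5607, -0.5353,  0.4386]
  ]
}
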