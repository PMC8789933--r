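{
  "components": [
    {"label": "MR",  "pi": 0.1947, "mu": [0.7056, 2.7126, 1.4950],
     "sigma": [[ 0.0425, -0.0007,  0.0013],
               [-0.0007,  0.2343, -0.0126],
               [ 0.0013, -0.0126,  0.2122]]},
    {"label": "MS",  "pi": 0.0827, "mu": [3.2981, -2.6064, -3.7382],
     "sigma": [[ 0.3310, -0.0094, -0.0122],
               [-0.0094,  0.3906, -0.0210],
               [-0.0122, -0.0210,  0.5386]]},
    {"label": "ASD", "pi": 0.1130, "mu": [2.3453, -0.3484, 0.5773],
     "sigma": [[ 0.5373, -0.0172, -0.0039],
               [-0.0172,  0.0608, -0.0053],
               [-0.0039, -0.0053,  0.1883]]},
    {"label": "NM",  "pi": 0.1683, "mu": [2.7874, 1.8620, -0.9829],
     "sigma": [[ 0.1403,  0.0107,  0.0063],
               [ 0.0107,  0.2549,  0.0016],
               [ 0.0063,  0.0016,  0.1301]]},
    {"label": "AS",  "pi": 0.0783, "mu": [0.7511, 0.3199, -0.5341],
     "sigma": [[ 0.0972,  0.0077, -0.0161],
               [ 0.0077,  0.0344, -0.0050],
               [-0.0161, -0.0050,  0.2634]]},
    {"label": "AR",  "pi": 0.2676, "mu": [-1.2294, 0.1198, 0.3222],
     "sigma": [[ 0.3301, -0.0011,  0.0025],
               [-0.0011,  0.0230,  0.0005],
               [ 0.0025,  0.0005,  0.3255]]},
    {"label": "VSD", "pi": 0.0954, "mu": [-0.1631, -1.1167, 0.9454],
     "sigma": [[ 0.1338,  0.0048, -0.0155],
               [ 0.0048,  0.1449, -0.0095],
               [-0.0155, -0.0095,  0.1573]]}
  ],
  "beta": [0.87, 0.65, 0.67, 0.65, 0.67, 0.79, 0.87],
  "mdc_printed": [5.6489, 3.2831, 3.4297, 3.2831, 3.4297, 4.5258, 5.6489]
}
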