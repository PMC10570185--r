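{
  "format": "gridpde-config",
  "version": 1,
  "species": [
    {
      "name": "u",
      "role": "differential",
      "algebraic_rhs": null
    },
    {
      "name": "v",
      "role": "differential",
      "algebraic_rhs": null
    }
  ],
  "diffusion": {
    "u": {
      "u": "1"
    },
    "v": {
      "v": "20"
    }
  },
  "kinetics": {
    "u": "u - u^3 - v",
    "v": "eps*(u - aa*v)"
  },
  "bcs": {
    "u": {
      "left": {
        "kind": "periodic",
        "data": null
      },
      "right": {
        "kind": "periodic",
        "data": null
      },
      "top": {
        "kind": "periodic",
        "data": null
      },
      "bottom": {
        "kind": "periodic",
        "data": null
      }
    },
    "v": {
      "left": {
        "kind": "periodic",
        "data": null
      },
      "right": {
        "kind": "periodic",
        "data": null
      },
      "top": {
        "kind": "periodic",
        "data": null
      },
      "bottom": {
        "kind": "periodic",
        "data": null
      }
    }
  },
  "domain": {
    "dimension": 2,
    "L_x": 100,
    "L_y": 100,
    "indicator": null
  },
  "numerics": {
    "dx": 1,
    "dt": 0.0050000000000000001,
    "schedule": [
      {
        "t": 0,
        "scheme": "forward_euler"
      }
    ],
    "steps_per_frame": 500
  },
  "params": {
    "eps": 2.2000000000000002,
    "aa": 0.5
  },
  "initial": {
    "u": "0.1*(2*rand() - 1)",
    "v": "0"
  },
  "views": [
    {
      "name": "u",
      "expression": "u",
      "colormap": "viridis",
      "scaling": "adaptive",
      "colorbar": true
    }
  ],
  "brush_events": [],
  "images": [],
  "seed": 1
}
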