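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
      "name": "w",
      "role": "algebraic",
      "algebraic_rhs": "u^3 - u - gamma*(u_xx + u_yy)"
    }
  ],
  "diffusion": {
    "u": {
      "w": "1"
    }
  },
  "kinetics": [],
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
    "w": {
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
    "L_x": 32,
    "L_y": 32,
    "indicator": null
  },
  "numerics": {
    "dx": 0.5,
    "dt": 0.002,
    "schedule": [
      {
        "t": 0,
        "scheme": "rk4"
      }
    ],
    "steps_per_frame": 500
  },
  "params": {
    "gamma": 0.5
  },
  "initial": {
    "u": "0.05*(2*rand() - 1)"
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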