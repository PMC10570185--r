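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
      "algebraic_rhs": "u_xx + u_yy"
    }
  ],
  "diffusion": {
    "u": {
      "u": "-1",
      "w": "-1"
    }
  },
  "kinetics": {
    "u": "-0.5*(u_x^2 + u_y^2)"
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
    "L_x": 64,
    "L_y": 64,
    "indicator": null
  },
  "numerics": {
    "dx": 1,
    "dt": 0.01,
    "schedule": [
      {
        "t": 0,
        "scheme": "rk4"
      }
    ],
    "steps_per_frame": 500
  },
  "params": [],
  "initial": {
    "u": "0.1*(2*rand() - 1)"
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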