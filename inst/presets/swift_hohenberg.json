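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
  "diffusion": [],
  "kinetics": {
    "u": "(r - 1)*u - 2*w - (w_xx + w_yy) + s*u^2 - u^3"
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
    "L_x": 60,
    "L_y": 60,
    "indicator": null
  },
  "numerics": {
    "dx": 0.5,
    "dt": 0.001,
    "schedule": [
      {
        "t": 0,
        "scheme": "rk4"
      }
    ],
    "steps_per_frame": 500
  },
  "params": {
    "r": -0.29999999999999999,
    "s": 1.8
  },
  "initial": {
    "u": "1.2*exp(-((x - 30)^2 + (y - 30)^2)/8)*cos(x - 30)"
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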