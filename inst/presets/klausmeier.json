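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
      "role": "differential",
      "algebraic_rhs": null
    }
  ],
  "diffusion": {
    "u": {
      "u": "1"
    }
  },
  "kinetics": {
    "u": "w*u^2 - m*u",
    "w": "a - w - w*u^2 + v*w_x_f"
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
      }
    }
  },
  "domain": {
    "dimension": 1,
    "L_x": 100,
    "L_y": null,
    "indicator": null
  },
  "numerics": {
    "dx": 0.5,
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
    "a": 2,
    "m": 0.45000000000000001,
    "v": 20
  },
  "initial": {
    "u": "0.8 + 0.4*rand()",
    "w": "1"
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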