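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
      "v": "50"
    }
  },
  "kinetics": {
    "u": "a + u^2/v - b*u",
    "v": "u^2 - v"
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
    "L_x": 96,
    "L_y": 96,
    "indicator": null
  },
  "numerics": {
    "dx": 1,
    "dt": 0.0040000000000000001,
    "schedule": [
      {
        "t": 0,
        "scheme": "forward_euler"
      }
    ],
    "steps_per_frame": 2500
  },
  "params": {
    "a": 0.5,
    "b": 1.5
  },
  "initial": {
    "u": "1 + 0.2*cos(2*pi*6*y/96) + 0.02*(rand() - 0.5)",
    "v": "1"
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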