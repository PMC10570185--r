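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
      "u": "2"
    },
    "v": {
      "v": "16"
    }
  },
  "kinetics": {
    "u": "a - (b + 1)*u + u^2*v",
    "v": "b*u - u^2*v"
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
    "L_x": 50,
    "L_y": 50,
    "indicator": null
  },
  "numerics": {
    "dx": 0.5,
    "dt": 0.002,
    "schedule": [
      {
        "t": 0,
        "scheme": "forward_euler"
      }
    ],
    "steps_per_frame": 500
  },
  "params": {
    "a": 3,
    "b": 9
  },
  "initial": {
    "u": "3 + 0.1*(rand() - 0.5)",
    "v": "3"
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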