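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
    },
    {
      "name": "w",
      "role": "differential",
      "algebraic_rhs": null
    }
  ],
  "diffusion": {
    "u": {
      "u": "D"
    },
    "v": {
      "v": "D"
    },
    "w": {
      "w": "D"
    }
  },
  "kinetics": {
    "u": "u*(1 - u - alpha*v - beta*w)",
    "v": "v*(1 - v - alpha*w - beta*u)",
    "w": "w*(1 - w - alpha*u - beta*v)"
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
    "dx": 1,
    "dt": 0.050000000000000003,
    "schedule": [
      {
        "t": 0,
        "scheme": "forward_euler"
      }
    ],
    "steps_per_frame": 200
  },
  "params": {
    "D": 0.10000000000000001,
    "alpha": 1.8,
    "beta": 0.40000000000000002
  },
  "initial": {
    "u": "rand()",
    "v": "rand()",
    "w": "rand()"
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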