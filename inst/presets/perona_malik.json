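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
      "name": "s",
      "role": "algebraic",
      "algebraic_rhs": "u_x^2 + u_y^2"
    }
  ],
  "diffusion": {
    "u": {
      "u": "1/(1 + s/K^2)"
    }
  },
  "kinetics": [],
  "bcs": {
    "u": {
      "left": {
        "kind": "neumann",
        "data": null
      },
      "right": {
        "kind": "neumann",
        "data": null
      },
      "top": {
        "kind": "neumann",
        "data": null
      },
      "bottom": {
        "kind": "neumann",
        "data": null
      }
    },
    "s": {
      "left": {
        "kind": "neumann",
        "data": null
      },
      "right": {
        "kind": "neumann",
        "data": null
      },
      "top": {
        "kind": "neumann",
        "data": null
      },
      "bottom": {
        "kind": "neumann",
        "data": null
      }
    }
  },
  "domain": {
    "dimension": 2,
    "L_x": 1,
    "L_y": 1,
    "indicator": null
  },
  "numerics": {
    "dx": 0.015625,
    "dt": 4.0000000000000003e-05,
    "schedule": [
      {
        "t": 0,
        "scheme": "forward_euler"
      }
    ],
    "steps_per_frame": 100
  },
  "params": {
    "K": 2
  },
  "initial": {
    "u": "0.25 + 0.5*heaviside(x - 0.5) + 0.08*(2*rand() - 1)"
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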