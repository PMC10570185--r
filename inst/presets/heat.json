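{
  "format": "gridpde-config",
  "version": 1,
  "species": [
    {
      "name": "u",
      "role": "differential",
      "algebraic_rhs": null
    }
  ],
  "diffusion": {
    "u": {
      "u": "1"
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
    }
  },
  "domain": {
    "dimension": 2,
    "L_x": 1,
    "L_y": 1,
    "indicator": null
  },
  "numerics": {
    "dx": 0.02,
    "dt": 5.0000000000000002e-05,
    "schedule": [
      {
        "t": 0,
        "scheme": "forward_euler"
      }
    ],
    "steps_per_frame": 200
  },
  "params": [],
  "initial": {
    "u": "cos(pi*x) * cos(pi*y)"
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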