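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
      "u": "1",
      "v": "-chi*u"
    },
    "v": {
      "v": "1"
    }
  },
  "kinetics": {
    "u": "u*(1 - u)",
    "v": "u - v"
  },
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
    "v": {
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
    "L_x": 20,
    "L_y": 20,
    "indicator": null
  },
  "numerics": {
    "dx": 0.25,
    "dt": 0.001,
    "schedule": [
      {
        "t": 0,
        "scheme": "forward_euler"
      }
    ],
    "steps_per_frame": 500
  },
  "params": {
    "chi": 5
  },
  "initial": {
    "u": "1 + 0.1*(rand() - 0.5)",
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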