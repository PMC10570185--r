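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
    "v": {
      "u": "1 + 3*heaviside(x - 0.5)"
    }
  },
  "kinetics": {
    "u": "v"
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
      }
    }
  },
  "domain": {
    "dimension": 1,
    "L_x": 1,
    "L_y": null,
    "indicator": null
  },
  "numerics": {
    "dx": 0.00390625,
    "dt": 0.00050000000000000001,
    "schedule": [
      {
        "t": 0,
        "scheme": "rk4"
      }
    ],
    "steps_per_frame": 50
  },
  "params": [],
  "initial": {
    "u": "exp(-(x - 0.3)^2/(2*0.03^2)) * heaviside(0.05 - (x-0.3)^2)",
    "v": "0"
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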