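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
  "kinetics": {
    "u": "u*(u - alpha)*(1 - u)"
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
    "alpha": 0.20000000000000001
  },
  "initial": {
    "u": "heaviside(10 - abs(x - 50))"
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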