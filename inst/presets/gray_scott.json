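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
      "u": "0.4"
    },
    "v": {
      "v": "0.2"
    }
  },
  "kinetics": {
    "u": "-u*v^2 + F*(1 - u)",
    "v": "u*v^2 - (F + k)*v"
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
    "L_x": 64,
    "L_y": 64,
    "indicator": null
  },
  "numerics": {
    "dx": 1,
    "dt": 0.20000000000000001,
    "schedule": [
      {
        "t": 0,
        "scheme": "forward_euler"
      }
    ],
    "steps_per_frame": 1000
  },
  "params": {
    "F": 0.0545,
    "k": 0.062
  },
  "initial": {
    "u": "1 - 0.5*heaviside(2 - abs(x - 32))*heaviside(2 - abs(y - 32))",
    "v": "0.5*heaviside(2 - abs(x - 32))*heaviside(2 - abs(y - 32)) + 0.01*rand()"
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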