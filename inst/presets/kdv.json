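{
  "format": "gridpde-config",
  "version": 1,
  "species": [
    {
      "name": "phi",
      "role": "differential",
      "algebraic_rhs": null
    },
    {
      "name": "v",
      "role": "algebraic",
      "algebraic_rhs": "phi_x"
    }
  ],
  "diffusion": [],
  "kinetics": {
    "phi": "-v_xx - 6*v*phi"
  },
  "bcs": {
    "phi": {
      "left": {
        "kind": "periodic",
        "data": null
      },
      "right": {
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
      }
    }
  },
  "domain": {
    "dimension": 1,
    "L_x": 40,
    "L_y": null,
    "indicator": null
  },
  "numerics": {
    "dx": 0.078125,
    "dt": 5.0000000000000002e-05,
    "schedule": [
      {
        "t": 0,
        "scheme": "rk4"
      }
    ],
    "steps_per_frame": 1000
  },
  "params": [],
  "initial": {
    "phi": "2*(1 - tanh(1*(x - 10))^2) + 1*(1 - tanh(0.7071067811865476*(x - 22))^2)"
  },
  "views": [
    {
      "name": "phi",
      "expression": "phi",
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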