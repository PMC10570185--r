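# gridpde

`gridpde` is a scriptable finite-difference solver for coupled time-dependent
PDE systems in one and two space dimensions, aimed at the reaction–diffusion
models of mathematical biology and nonlinear physics. Simulations are posed
declaratively — every coefficient is a text expression — and run
deterministically from a JSON configuration file, so a complete numerical
experiment (model, domain, boundary conditions, numerics, views) is a single
shareable document.

Systems of up to four species `u, v, w, q` (renamable) take the general
reaction–cross-diffusion form

    du_i/dt = Σ_j ∇·(D_ij ∇u_j) + f_i,

where the diffusivities `D_ij` may depend on the unknowns, space, time and
parameters, and the kinetics `f_i` may additionally reference first and second
unmixed spatial derivatives (`u_x`, `u_yy`, upwind variants `u_x_b`/`u_x_f`;
mixed derivatives are not supported). Any species may instead be *algebraic* —
defined instantaneously by an expression of the others — which is how
higher-order operators are posed: the Korteweg–de Vries equation becomes
`phi_t = -v_xx - 6 v phi` with `v = phi_x`, Swift–Hohenberg and
Cahn–Hilliard use `w = ∇²u`, and Keller–Segel chemotaxis enters through the
cross-diffusion slot `D_uv = -χ(u)`.

Space is discretised on a cell-centred lattice (`N = floor(L/dx)` nodes per
axis) with central differences; the variable-coefficient diffusion term uses
the second-order stencil

    ∇·(D∇u) ≈ (1/2Δx²) { D(x)[u(x−Δx) − 2u(x) + u(x+Δx)]
                        + D(x−Δx)[u(x−Δx) − u(x)]
                        + D(x+Δx)[u(x+Δx) − u(x)] } + (y terms),

which is algebraically the antisymmetric flux form, so periodic transport-free
dynamics conserve mass to rounding. Boundary conditions (periodic, Neumann,
Robin, Dirichlet; per species, per edge, arbitrary inhomogeneous data) are
enforced through ghost nodes; non-rectangular domains are carved from the
rectangle by an indicator expression with zero-flux mask edges. Time
integration is explicit and fixed-step: forward Euler, two-step
Adams–Bashforth, midpoint, or classical RK4, with blow-up detection,
checkpoints, paint-style brush events and frame capture.

## Worked example

Decay of a cosine profile under the heat equation, compared with the exact
solution `u = exp(-π²t) cos(πx)`:

```r
library(gridpde)

cfg <- pde_config(
  species   = "u",
  diffusion = list(u = list(u = "1")),
  initial   = list(u = "cos(pi*x)"),
  dimension = 1, L_x = 1, dx = 1/256, dt = 3.8e-6)

res <- pde_run(cfg, t_end = (1/pi)^2)   # one e-folding of the slowest mode
res
#> <pde_run: t = 0.101323, 26664 steps, 268 frames, 0 checkpoints>

g     <- build_grid(cfg$domain, cfg$numerics$dx)
exact <- exp(-pi^2 * res$state$t) * cos(pi * g$X)
max(abs(res$state$fields$u - exact)) / max(abs(exact))
#> [1] 6.202563e-06
```

The terminal field matches the separation-of-variables solution to about
6×10⁻⁶ in relative maximum norm: the spatial error vanishes here because the
sampled cosine is an exact eigenvector of the discrete operator, leaving only
the first-order-in-`dt` forward-Euler error.

Sixteen classic systems ship as presets (`list_presets()`): Gray–Scott,
Gierer–Meinhardt, Keller–Segel, KdV solitons, Fisher–KPP and Allee invasions,
Swift–Hohenberg, Cahn–Hilliard, Kuramoto–Sivashinsky, Klausmeier,
rock–paper–scissors Lotka–Volterra, Perona–Malik denoising, Brusselator,
FitzHugh–Nagumo, and the heat and inhomogeneous wave equations:

```r
run <- pde_run(get_preset("gray_scott"), t_end = 2000)
plot(run)                      # rendered spot pattern
compute_integral(run$state$fields$u, build_grid(run$cfg$domain, 1))
```

A thin command-line wrapper lives at `inst/cli/gridpde.R`:

```sh
Rscript inst/cli/gridpde.R run gray_scott --t-end 2000 --out out/
Rscript inst/cli/gridpde.R presets
Rscript inst/cli/gridpde.R validate my_model.json
Rscript inst/cli/gridpde.R render out/final_state.json gray_scott "u - v"
```

`run` writes PNG frames, a JSON final state and a reproducibility manifest;
exit codes are 0 (success), 2 (validation failure, diagnostics printed) and
3 (blow-up, with the failure time and partial outputs kept).

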