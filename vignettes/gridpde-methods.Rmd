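---
title: "Numerical methods and design choices in gridpde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical methods and design choices in gridpde}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpde)
```

# The model class

`gridpde` integrates systems of up to four scalar fields on a rectangle
$\Omega = [0, L_x] \times [0, L_y]$ (or an interval in 1D). Each
*differential* species $u_i$ obeys

$$\frac{\partial u_i}{\partial t} \;=\; \sum_j \nabla \cdot \big(D_{ij}\,
\nabla u_j\big) \;+\; f_i,$$

while an *algebraic* species is an explicit assignment
$u_k = g_k(u, \nabla u, x, y, t)$, recomputed from the differential fields
before every right-hand-side evaluation (a topological sort over the
algebraic dependencies guarantees a well-defined order; cycles are rejected
at validation). Algebraic species are the mechanism for exceeding second
spatial order within a second-order solver: with $w = \nabla^2 u$ the
biharmonic $\nabla^4 u$ becomes $\nabla^2 w$, which covers Swift–Hohenberg,
Cahn–Hilliard and Kuramoto–Sivashinsky; with $v = \partial\phi/\partial x$
the KdV equation $\phi_t = -\phi_{xxx} - 6\phi\phi_x$ becomes
$\phi_t = -v_{xx} - 6v\phi$. Cross-diffusion ($D_{ij}$, $i \neq j$) covers
chemotaxis: the Keller–Segel flux $-\nabla\cdot(\chi(u)\nabla v)$ is the
entry $D_{uv} = -\chi(u)$.

The diffusivities may depend on the unknowns, space, time and parameters but
not on derivatives; the kinetics $f_i$ may additionally reference first and
second *unmixed* derivative tokens (`u_x`, `u_y`, `u_xx`, `u_yy`) and the
explicitly one-sided `u_x_b`, `u_x_f`, `u_y_b`, `u_y_f` for upwinding. Mixed
derivatives are not representable and are rejected with a named diagnostic.
Advection can therefore be written either centred (`v*u_x`) or upwinded
(`v*u_x_b` when the flow is rightward); the package never chooses the side
automatically — which side is correct depends on the sign of the local
velocity, and that is modelling information the author has and the solver
does not.

## The expression grammar

Every coefficient — diffusivities, kinetics, boundary data, indicator,
initial conditions, views — is a text expression in conventional calculator
syntax: `+ - * / ^` (with `^` right-associative), parentheses, the constant
`pi`, the functions `sin cos tan exp log sqrt abs tanh min max heaviside`,
image functions `I_S(x,y)` / `I_T(x,y)`, and (initial conditions only) the
seeded noise fields `rand()` / `randn()`. `heaviside(0) = 1` by convention,
so `heaviside(x - a)` includes the locus `x = a`; the closed convention
matters for indicator functions, where a node is simulated iff the indicator
is *strictly positive* — `heaviside(...)` yields {0, 1} and selects exactly
the nodes where its argument is non-negative. Parsing is delegated to R's
own parser and then the syntax tree is validated against a whitelist
(structure, function names, arity, free symbols), so the grammar is exactly
conventional infix arithmetic with no surprises; evaluation is a pure
elementwise computation over grid-shaped arrays, with scalars broadcast.
Division by zero and logs of non-positive values deliberately produce
non-finite values that *flow through* rather than raising: blow-up detection
at step boundaries owns the user-facing error, so a transient `Inf` in a
sub-expression is reported as "solution blew up at t = ...", with the model
time attached.

The grammar, in EBNF (whitespace insignificant):

```
expr      = term , { ("+" | "-") , term } ;
term      = unary , { ("*" | "/") , unary } ;
unary     = [ "-" | "+" ] , power ;
power     = atom , [ "^" , unary ] ;            (* right-associative *)
atom      = number | symbol | call | "(" , expr , ")" ;
call      = funcname , "(" , [ expr , { "," , expr } ] , ")" ;
funcname  = "sin" | "cos" | "tan" | "exp" | "log" | "sqrt" | "abs"
          | "tanh" | "min" | "max" | "heaviside" | "I_S" | "I_T"
          | "rand" | "randn" ;
symbol    = species | "x" | "y" | "t" | "pi" | parameter | derivtoken ;
derivtoken = species , "_" , ("x"|"y"|"xx"|"yy"|"x_b"|"x_f"|"y_b"|"y_f") ;
```

# Spatial discretisation

## Grid

For a requested step `dx`, each axis gets $N = \lfloor L/dx \rfloor$ nodes
(a single step size for both axes) with *effective* spacing
$\Delta x = L/N$, and nodes at cell centres $x_i = (i - \tfrac12)\Delta x$.
Cell-centre placement was chosen (the alternative being vertex-centred
nodes) because it makes three things uniform: periodic wrap needs no
duplicated seam node, the indicator mask classifies whole cells, and the
integral readout is exact midpoint quadrature. Analytic comparisons must use
the same convention; all fixtures in this package do. Stencils need at least
3 nodes along any axis they differentiate; validation enforces this for the
axes the model actually uses.

## The diffusion stencil

The variable-coefficient term is discretised with $D$ evaluated at nodes:

$$\nabla\cdot(D\nabla u)\big|_{x} \approx \frac{1}{2\Delta x^2}\Big\{
D_0\,[u_{-} - 2u_0 + u_{+}] + D_{-}[u_{-} - u_0] + D_{+}[u_{+} - u_0]
\Big\} + (\text{y terms}),$$

with subscripts $-/0/+$ denoting the $x\pm\Delta x$ neighbours. This is
algebraically identical to the flux form
$\sum_{\text{nbr}} \tfrac{D_0 + D_{\text{nbr}}}{2}\,
\tfrac{u_{\text{nbr}} - u_0}{\Delta x^2}$, whose antisymmetry in (node,
neighbour) makes the stencil sum to zero over a periodic grid — discrete
mass conservation to rounding, which the tests verify at $10^{-11}$ relative
over $10^4$ steps for all four schemes. For constant $D$ it reduces to $D$
times the 5-point Laplacian and is second-order accurate; the test suite
measures the order from the residual of an exact solution at two
resolutions. Summation order within the stencil is arranged symmetrically
(`(u_- + u_+) - 2u_0`), so mirror-symmetric problems stay mirror-symmetric
*bitwise*, not just approximately.

Diffusivity fields are extended into the ghost layer by mirroring on
non-periodic edges and wrapping on periodic ones. Mirroring is the natural
choice for a quantity with no boundary data of its own; it keeps the
boundary-adjacent stencil well-defined for state-dependent $D$.

## Ghost nodes and boundary conditions

One ghost layer per edge encodes the boundary conditions so interior
stencils need no modification:

* **periodic** — the ghost copies the opposite side's boundary node (both
  edges of the axis must be periodic; validation enforces the pairing);
* **Neumann / Robin** — `ghost = u_adj + h·g`, where `u_adj` is the
  boundary-adjacent node, `h` the spacing along the normal and `g` the
  outward-normal-derivative data evaluated at the boundary-adjacent nodes.
  On a cell-centred lattice the ghost sits at the mirror image of the
  boundary-adjacent node across the wall, so `g = 0` is an exact reflection
  and even cosine modes are exact eigenvectors of the discrete operator —
  the property the heat-equation validation relies on. Robin data may
  reference the species itself; the ghost uses the current iterate (explicit
  treatment), the natural choice in an explicit-in-time code. A
  vertex-centred variant of this formula (mirroring across the
  boundary-adjacent node with a `2h` weight) was considered and rejected:
  on a cell-centred grid it imposes the flux condition half a cell inside
  the wall and degrades the operator to first order at the boundary.
* **Dirichlet** — implemented by *pinning*: the boundary-adjacent node is
  set to the data value (re-evaluated at each stage time, so time-dependent
  data work) and its time-derivative forced to zero; the operators are left
  untouched. With cell-centred nodes there is no node exactly on the wall,
  so the pinned value converges to the wall condition at $O(\Delta x)$ —
  a documented trade-off of the cell-centre convention.

Boundary data expressions are evaluated over the whole grid context and
sliced at the boundary-adjacent nodes, so data may depend on `x`, `y`, `t`,
parameters and species values ("arbitrary inhomogeneous boundary terms").

## Masked (non-rectangular) domains

An indicator expression over `(x, y)` selects the simulated subset: a node
is active iff the indicator is positive at its centre. Edges between an
active and an excluded node are handled by the same ghost mechanism as the
outer boundary, defaulting to zero flux (the excluded neighbour's value is
mirrored). Excluded nodes are frozen (zero time-derivative) and render as
no-data. Boundary conditions involving derivatives on jagged indicator
boundaries are first-order at best; for quantitative work near curved
boundaries, refine the grid.

# Time integration

Four explicit fixed-step schemes advance the method-of-lines system:
forward Euler (first order), the midpoint / modified Euler method (second),
two-step Adams–Bashforth (second; its first step is delegated to midpoint so
the startup does not degrade the order — the history is cleared whenever
`dt` or the scheme changes), and classical RK4 (fourth). Convergence orders
are verified by Richardson triples — $\log_2$ of the ratio of successive
solution differences under `dt`-halving — which cancels the (fixed) spatial
error exactly. Algebraic species are recomputed at *every stage evaluation*,
not once per step: this is the choice consistent with the differential-
algebraic reduction of the system to an ODE on the differential fields
alone. Dirichlet nodes are re-pinned at each stage time.

`dt` is never adapted. A stability advisory based on the explicit diffusion
heuristic $dt \le h^2/(2\,d\,\max|D|)$ in $d$ dimensions is logged when
violated, but not enforced — guidance, not enforcement, because the
heuristic ignores kinetics and cross terms in both directions. Blow-up
(any non-finite value in any field) is checked after every step and converts
to an error carrying the failure time and the partial result. Note the
stability interval of two-step Adams–Bashforth on the negative real axis is
half forward Euler's; the conservation tests run all four schemes at a `dt`
inside the narrowest interval.

# Runs, reproducibility and sharing

A run is fully determined by its configuration: initial conditions are
expressions, and the noise generators `rand()`/`randn()` draw from a
generator seeded by the config's `seed`, so interactive-style randomness is
reproducible from the file alone. Checkpoints store a full state copy plus
the configuration hash; restoring one and continuing reproduces the direct
trajectory bit-identically for the single-history schemes (Adams–Bashforth
restarts lose one step of history and restart through midpoint — a
documented, order-preserving difference). Brush events (disc set/add,
Gaussian add) fire at their model times inside the run loop and are recorded
in the event log; scheme switches are declarative (a time-segmented
schedule) rather than interactive, again for reproducibility.

Configurations serialize to JSON with expression sources verbatim and
numbers at 17 significant digits (lossless for doubles). The "share" profile
excludes brush events — a shared document reproduces the simulation *given
its initial conditions*, not the interactive painting history; the "full"
profile keeps them. Unknown fields anywhere in a document are rejected with
the offending path named. States and checkpoints are written as JSON
named-array containers (fields with dimensions, clock, step index, config
hash).

# Views, rendering and image functions

A view maps the state to the displayed scalar field via any expression over
species, coordinates, time and derivative tokens. Adaptive scaling maps the
frame minimum/maximum to the colormap ends (a flat field maps to the
midpoint); fixed scaling clamps. Non-finite values render as a magenta
sentinel rather than erroring. Colormaps include a viridis-style
perceptually uniform map (the default, chosen for colour-vision
accessibility), a blue–white–red diverging map for signed fields, a
multi-hue map, and greyscale. The image top row corresponds to $y = L_y$;
1D runs render as line plots. PNG export is deterministic: identical frames
give identical bytes.

Uploaded images become spatial functions: PNG only, converted to luminance
with the Rec. 601 weights ($0.299R + 0.587G + 0.114B$), clamped to $[0,1]$,
sampled bilinearly between pixel centres with the image x axis mapped to
$[0, L_x]$ and the top row to $y = L_y$. Rec. 601 plus bilinear is a
documented convention choice — nothing downstream depends on the exact
luminance formula.

# The preset library and what the tests show

Sixteen classic systems ship as validated configurations (JSON under
`inst/presets/`, identical schema to user configs). Where a system has a
standard literature formulation the preset uses it, with the source noted in
the registry's provenance column; parameter values are standard choices
placed in the documented dynamical regime:

* **Gierer–Meinhardt** uses $f_u = a + u^2/v - bu$, $f_v = u^2 - v$ with
  $a = 0.5$, $b = 1.5$: the uniform state $(1, 1)$ is stable without
  diffusion and Turing-unstable for $D_v/D_u > 27.9$ (from the Jacobian
  $f_u = 0.5, f_v = -1, g_u = 2, g_v = -1$); the preset uses $D_v = 50$ with
  a stripe initial condition whose wavelength matches the fastest-growing
  mode, so stripes break into spots — quantified by the growth of the
  along-stripe variance.
* **Gray–Scott** sits at $F = 0.0545$, $k = 0.062$ with $D_u/D_v = 2$. The
  homogeneous state is linearly *stable* here — Gray–Scott patterns are
  finite-amplitude structures — so the preset seeds a small square
  perturbation from which the pattern grows to fill the domain; the test
  asserts the spatial variance grows by more than an order of magnitude.
* **Perona–Malik** uses $g(s) = 1/(1 + s/K^2)$ with the squared gradient
  magnitude as an algebraic species so that $g$ sits in the (state-
  dependent) diffusion slot. $K = 2$ lies between the gradient scale of the
  seeded pixel noise and that of the step edge (about 32 in these units),
  which is the regime where the model denoises while *sharpening* the edge;
  the test asserts the total variation collapses while the step height
  retains at least 90%.
* **KdV** validation uses $\phi_0 = \tfrac{c}{2}\,\mathrm{sech}^2
  (\tfrac{\sqrt c}{2}(x - x_0))$ (written via $1 - \tanh^2$; the grammar has
  no `cosh`), on a periodic domain sized so the tails are below $10^{-8}$ at
  the seam. A single soliton retains height and speed within 2% over a full
  transit, and two solitons ($c = 4, 1$) regain their heights within 2%
  after colliding. The explicit, non-symplectic schemes conserve none of the
  model's invariants exactly, so small fluctuations are expected and the 2%
  bands are the honest statement of what this discretisation achieves at
  $\Delta x = L/192$.

Problem sizes throughout the suite (grids of 16–512 nodes per axis, up to
$2\times10^4$ steps) were chosen as the smallest at which each property is
cleanly measurable — convergence orders within $\pm 0.1$, conservation at
$10^{-11}$ — and are stated in each test.

## What the synthetic cases do and do not show

The analytic fixtures (decaying cosine, d'Alembert pulse, KdV solitons) are
smooth, well-resolved, and built so a closed form is available; they
exercise the operator, the ghost machinery and the steppers quantitatively.
They do not exercise stiff kinetics, steep under-resolved fronts, or noisy
state-dependent diffusivities — for those, the preset smoke and qualitative
tests only assert boundedness and the documented regime behaviour
(patterns emerge, stripes break, edges survive), which is the level of claim
a fixed-step explicit method supports. Passing this suite says the solver
integrates these model classes correctly at adequate resolution; it does not
say any particular under-resolved run is trustworthy — the stability
advisory and the convergence tooling (`make_heat_cosine_case`, Richardson
orders) are provided so users can check their own configurations.

# Numerical conventions, degenerate inputs, limitations

* Double precision throughout. (GPU-oriented interactive solvers of this
  class often run single precision for device compatibility; that is a
  platform constraint, not a method choice, and this package does not
  emulate it.)
* `floor` in the grid rule uses a $10^{-9}$ relative guard so exact
  quotients like $2.5/0.5$ do not round down.
* Degenerate adaptive colour ranges (flat fields) map to the colormap
  midpoint; all-false masks, empty frame lists, unknown species in brush
  events, and unknown scheme names are errors with named diagnostics.
* `validate_config()` is total: syntax errors, unresolved symbols,
  mixed-derivative tokens, derivative tokens inside diffusivities, unpaired
  periodic edges, missing Dirichlet data, non-positive lengths/steps and
  under-resolved axes all come back as a list of messages, never a throw.
* Known limitations: no implicit or adaptive timestepping (explicitly out of
  scope), no mixed spatial derivatives, no curved-boundary stencil
  modification (masks are jagged), Dirichlet data applied at cell centres
  ($O(\Delta x)$ to the wall), JPEG images unsupported (PNG only), and
  animation export is a PNG sequence (no MP4/GIF encoding).
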