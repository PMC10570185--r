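Package: gridpde
Title: Finite-Difference Simulation of Reaction-Cross-Diffusion PDE Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable finite-difference solver for coupled time-dependent
    partial differential equation systems in one and two spatial dimensions.
    Systems of up to four species are posed declaratively as text expressions:
    a matrix of (possibly state- and space-dependent) diffusivities, reaction
    kinetics that may reference first and second unmixed spatial derivatives,
    algebraic species defined instantaneously in terms of the others, per-edge
    periodic, Neumann, Robin and Dirichlet boundary conditions enforced through
    ghost nodes, and non-rectangular domains carved from a rectangle by an
    indicator function. Four explicit fixed-step time integrators (forward
    Euler, two-step Adams-Bashforth, midpoint, classical RK4) advance the
    method-of-lines system, with blow-up detection, checkpoints, brush events
    and frame capture. Ships a registry of classic model presets (Gray-Scott,
    Gierer-Meinhardt, Keller-Segel chemotaxis, Korteweg-de Vries solitons,
    Perona-Malik denoising and others), colormap rendering to PNG, greyscale
    image functions usable inside equations, and JSON (de)serialization of
    complete simulation configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
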