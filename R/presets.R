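# Ready-to-run model presets. The systems' structure (species, couplings,
# algebraic reductions) follows the classic formulations; parameter values are
# standard literature choices recorded in each entry's provenance note.
# Higher-order operators (Swift-Hohenberg, Cahn-Hilliard,
# Kuramoto-Sivashinsky) are reduced to the general second-order-in-space form
# through algebraic species; chemotaxis enters through the cross-diffusion
# slot.

.preset_builders <- function() list(

  heat = list(
    title = "Heat equation (2D, homogeneous Neumann)",
    provenance = "canonical linear diffusion; cosine mode decay is the teaching example",
    build = function() pde_config(
      species = "u",
      diffusion = list(u = list(u = "1")),
      initial = list(u = "cos(pi*x) * cos(pi*y)"),
      dimension = 2, L_x = 1, L_y = 1, dx = 0.02, dt = 5e-5,
      scheme = "forward_euler", steps_per_frame = 200L)),

  wave_inhomogeneous = list(
    title = "Inhomogeneous wave equation (piecewise wave speed)",
    provenance = "second-order wave equation reduced to the first-order system du/dt = v, dv/dt = div(f(x) grad u); f piecewise constant",
    build = function() pde_config(
      species = c("u", "v"),
      kinetics = list(u = "v"),
      diffusion = list(v = list(u = "1 + 3*heaviside(x - 0.5)")),
      initial = list(u = "exp(-(x - 0.3)^2/(2*0.03^2)) * heaviside(0.05 - (x-0.3)^2)",
                     v = "0"),
      dimension = 1, L_x = 1, dx = 1/256, dt = 5e-4,
      scheme = "rk4", steps_per_frame = 50L)),

  kdv = list(
    title = "Korteweg-de Vries solitons (periodic)",
    provenance = "phi_t = -phi_xxx - 6 phi phi_x recast with algebraic v = phi_x; two-soliton initial data, sech^2 profiles",
    build = function() pde_config(
      species = c("phi", "v"),
      algebraic = list(v = "phi_x"),
      kinetics = list(phi = "-v_xx - 6*v*phi"),
      initial = list(phi = paste0(
        "2*(1 - tanh(1*(x - 10))^2)",          # c1 = 4: (c/2) sech^2(sqrt(c)/2 (x-x0))
        " + 1*(1 - tanh(0.7071067811865476*(x - 22))^2)")),  # c2 = 2
      bcs = list(phi = "periodic", v = "periodic"),
      dimension = 1, L_x = 40, dx = 40/512, dt = 5e-5,
      scheme = "rk4", steps_per_frame = 1000L)),

  keller_segel = list(
    title = "Keller-Segel chemotaxis with logistic growth",
    provenance = "u_t = lap u - div(chi u grad v) + u(1-u); v_t = D lap v + u - v; chemotaxis through the cross-diffusion slot D_uv = -chi*u",
    build = function() pde_config(
      species = c("u", "v"),
      diffusion = list(u = list(u = "1", v = "-chi*u"),
                       v = list(v = "1")),
      kinetics = list(u = "u*(1 - u)", v = "u - v"),
      params = list(chi = 5),
      initial = list(u = "1 + 0.1*(rand() - 0.5)", v = "1"),
      dimension = 2, L_x = 20, L_y = 20, dx = 0.25, dt = 1e-3,
      scheme = "forward_euler", steps_per_frame = 500L)),

  gray_scott = list(
    title = "Gray-Scott model (pattern-growth regime)",
    provenance = "Pearson's parameter plane; F = 0.0545, k = 0.062 with Du/Dv = 2 and a small finite-amplitude seed (the homogeneous state is linearly stable; patterns nucleate from localized perturbations)",
    build = function() pde_config(
      species = c("u", "v"),
      diffusion = list(u = list(u = "0.4"), v = list(v = "0.2")),
      kinetics = list(u = "-u*v^2 + F*(1 - u)", v = "u*v^2 - (F + k)*v"),
      params = list(F = 0.0545, k = 0.062),
      bcs = list(u = "periodic", v = "periodic"),
      initial = list(
        u = "1 - 0.5*heaviside(2 - abs(x - 32))*heaviside(2 - abs(y - 32))",
        v = "0.5*heaviside(2 - abs(x - 32))*heaviside(2 - abs(y - 32)) + 0.01*rand()"),
      dimension = 2, L_x = 64, L_y = 64, dx = 1, dt = 0.2,
      scheme = "forward_euler", steps_per_frame = 1000L)),

  gierer_meinhardt = list(
    title = "Gierer-Meinhardt activator-inhibitor (stripe-to-spot regime)",
    provenance = "u_t = lap u + a + u^2/v - b u; v_t = D lap v + u^2 - v; a = 0.5, b = 1.5, D = 50 (above the Turing threshold D_c ~ 27.9)",
    build = function() pde_config(
      species = c("u", "v"),
      diffusion = list(u = list(u = "1"), v = list(v = "50")),
      kinetics = list(u = "a + u^2/v - b*u", v = "u^2 - v"),
      params = list(a = 0.5, b = 1.5),
      bcs = list(u = "periodic", v = "periodic"),
      initial = list(u = "1 + 0.2*cos(2*pi*6*y/96) + 0.02*(rand() - 0.5)",
                     v = "1"),
      dimension = 2, L_x = 96, L_y = 96, dx = 1, dt = 4e-3,
      scheme = "forward_euler", steps_per_frame = 2500L)),

  fisher_kpp = list(
    title = "Fisher-Kolmogorov travelling invasion wave",
    provenance = "u_t = D lap u + r u(1-u); pulled front speed 2 sqrt(rD)",
    build = function() pde_config(
      species = "u",
      diffusion = list(u = list(u = "1")),
      kinetics = list(u = "u*(1 - u)"),
      initial = list(u = "heaviside(5 - x)"),
      dimension = 1, L_x = 100, dx = 0.5, dt = 0.05,
      scheme = "forward_euler", steps_per_frame = 200L)),

  allee_invasion = list(
    title = "Strong Allee effect invasion",
    provenance = "bistable kinetics u(u - alpha)(1 - u), alpha = 0.2; persistence depends on initial mass",
    build = function() pde_config(
      species = "u",
      diffusion = list(u = list(u = "1")),
      kinetics = list(u = "u*(u - alpha)*(1 - u)"),
      params = list(alpha = 0.2),
      initial = list(u = "heaviside(10 - abs(x - 50))"),
      dimension = 1, L_x = 100, dx = 0.5, dt = 0.05,
      scheme = "forward_euler", steps_per_frame = 200L)),

  swift_hohenberg = list(
    title = "Swift-Hohenberg equation (quadratic-cubic)",
    provenance = "u_t = r u - (1 + lap)^2 u + s u^2 - u^3 via algebraic w = lap u (fourth-order operator reduced to second order)",
    build = function() pde_config(
      species = c("u", "w"),
      algebraic = list(w = "u_xx + u_yy"),
      kinetics = list(u = "(r - 1)*u - 2*w - (w_xx + w_yy) + s*u^2 - u^3"),
      params = list(r = -0.3, s = 1.8),
      bcs = list(u = "periodic", w = "periodic"),
      initial = list(
        u = "1.2*exp(-((x - 30)^2 + (y - 30)^2)/8)*cos(x - 30)"),
      dimension = 2, L_x = 60, L_y = 60, dx = 0.5, dt = 1e-3,
      scheme = "rk4", steps_per_frame = 500L)),

  cahn_hilliard = list(
    title = "Cahn-Hilliard coarsening",
    provenance = "u_t = lap(u^3 - u - gamma lap u) written as u_t = div(grad w) with algebraic chemical potential w",
    build = function() pde_config(
      species = c("u", "w"),
      algebraic = list(w = "u^3 - u - gamma*(u_xx + u_yy)"),
      diffusion = list(u = list(w = "1")),
      params = list(gamma = 0.5),
      bcs = list(u = "periodic", w = "periodic"),
      initial = list(u = "0.05*(2*rand() - 1)"),
      dimension = 2, L_x = 32, L_y = 32, dx = 0.5, dt = 2e-3,
      scheme = "rk4", steps_per_frame = 500L)),

  kuramoto_sivashinsky = list(
    title = "Kuramoto-Sivashinsky spatiotemporal chaos",
    provenance = "u_t = -lap u - lap^2 u - |grad u|^2/2 via algebraic w = lap u; chaotic for domain sizes beyond ~50",
    build = function() pde_config(
      species = c("u", "w"),
      algebraic = list(w = "u_xx + u_yy"),
      diffusion = list(u = list(u = "-1", w = "-1")),
      kinetics = list(u = "-0.5*(u_x^2 + u_y^2)"),
      bcs = list(u = "periodic", w = "periodic"),
      initial = list(u = "0.1*(2*rand() - 1)"),
      dimension = 2, L_x = 64, L_y = 64, dx = 1, dt = 0.01,
      scheme = "rk4", steps_per_frame = 500L)),

  klausmeier = list(
    title = "Klausmeier semi-arid vegetation stripes",
    provenance = "water w_t = a - w - w u^2 + v w_x (downhill advection, one-sided difference); plants u_t = lap u + w u^2 - m u; a = 2, m = 0.45",
    build = function() pde_config(
      species = c("u", "w"),
      diffusion = list(u = list(u = "1")),
      kinetics = list(u = "w*u^2 - m*u",
                      w = "a - w - w*u^2 + v*w_x_f"),
      params = list(a = 2, m = 0.45, v = 20),
      bcs = list(u = "periodic", w = "periodic"),
      initial = list(u = "0.8 + 0.4*rand()", w = "1"),
      dimension = 1, L_x = 100, dx = 0.5, dt = 5e-3,
      scheme = "forward_euler", steps_per_frame = 500L)),

  cyclic_lv = list(
    title = "Cyclic Lotka-Volterra (rock-paper-scissors) spirals",
    provenance = "May-Leonard three-species competition with cyclic dominance; equal mobilities",
    build = function() pde_config(
      species = c("u", "v", "w"),
      diffusion = list(u = list(u = "D"), v = list(v = "D"), w = list(w = "D")),
      kinetics = list(u = "u*(1 - u - alpha*v - beta*w)",
                      v = "v*(1 - v - alpha*w - beta*u)",
                      w = "w*(1 - w - alpha*u - beta*v)"),
      params = list(D = 0.1, alpha = 1.8, beta = 0.4),
      bcs = list(u = "periodic", v = "periodic", w = "periodic"),
      initial = list(u = "rand()", v = "rand()", w = "rand()"),
      dimension = 2, L_x = 60, L_y = 60, dx = 1, dt = 0.05,
      scheme = "forward_euler", steps_per_frame = 200L)),

  perona_malik = list(
    title = "Perona-Malik edge-preserving denoising",
    provenance = "u_t = div(g(|grad u|^2) grad u), g(s) = 1/(1 + s/K^2); gradient magnitude as an algebraic species so g sits in the diffusion slot",
    build = function() pde_config(
      species = c("u", "s"),
      algebraic = list(s = "u_x^2 + u_y^2"),
      diffusion = list(u = list(u = "1/(1 + s/K^2)")),
      params = list(K = 2),
      initial = list(u = "0.25 + 0.5*heaviside(x - 0.5) + 0.08*(2*rand() - 1)"),
      dimension = 2, L_x = 1, L_y = 1, dx = 1/64, dt = 4e-5,
      scheme = "forward_euler", steps_per_frame = 100L)),

  brusselator = list(
    title = "Brusselator Turing patterns",
    provenance = "f_u = a - (b+1)u + u^2 v, f_v = b u - u^2 v; a = 3, b = 9, Du = 2, Dv = 16",
    build = function() pde_config(
      species = c("u", "v"),
      diffusion = list(u = list(u = "2"), v = list(v = "16")),
      kinetics = list(u = "a - (b + 1)*u + u^2*v", v = "b*u - u^2*v"),
      params = list(a = 3, b = 9),
      bcs = list(u = "periodic", v = "periodic"),
      initial = list(u = "3 + 0.1*(rand() - 0.5)", v = "3"),
      dimension = 2, L_x = 50, L_y = 50, dx = 0.5, dt = 2e-3,
      scheme = "forward_euler", steps_per_frame = 500L)),

  fitzhugh_nagumo = list(
    title = "FitzHugh-Nagumo Turing patterns",
    provenance = "u_t = lap u + u - u^3 - v; v_t = D lap v + eps(u - a v); a = 0.5, eps = 2.2, D = 20 (above threshold ~6.4)",
    build = function() pde_config(
      species = c("u", "v"),
      diffusion = list(u = list(u = "1"), v = list(v = "20")),
      kinetics = list(u = "u - u^3 - v", v = "eps*(u - aa*v)"),
      params = list(eps = 2.2, aa = 0.5),
      bcs = list(u = "periodic", v = "periodic"),
      initial = list(u = "0.1*(2*rand() - 1)", v = "0"),
      dimension = 2, L_x = 100, L_y = 100, dx = 1, dt = 5e-3,
      scheme = "forward_euler", steps_per_frame = 500L))
)

#' List the preset registry
#'
#' @return data frame with columns `id`, `title`, `provenance`, in stable
#'   registry order.
#' @export
list_presets <- function() {
  reg <- .preset_builders()
  data.frame(id = names(reg),
             title = vapply(reg, function(e) e$title, ""),
             provenance = vapply(reg, function(e) e$provenance, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fetch a preset configuration
#'
#' Presets are complete, validated configurations reproducing classic systems:
#' linear heat and (inhomogeneous) wave equations, KdV solitons, Keller-Segel
#' chemotaxis, Gray-Scott, Gierer-Meinhardt, Fisher-KPP and Allee invasions,
#' Swift-Hohenberg, Cahn-Hilliard, Kuramoto-Sivashinsky, Klausmeier,
#' rock-paper-scissors Lotka-Volterra, Perona-Malik denoising, Brusselator and
#' FitzHugh-Nagumo. Matching JSON documents ship under
#' `system.file("presets", package = "gridpde")`.
#'
#' @param id preset id (see [list_presets()]).
#' @return a [pde_config()].
#' @export
get_preset <- function(id) {
  reg <- .preset_builders()
  if (!id %in% names(reg))
    stop(sprintf("unknown preset '%s'; available: %s", id,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  reg[[id]]$build()
}

#' Write all presets as JSON config files
#'
#' @param dir output directory.
#' @return invisibly, the files written.
#' @keywords internal
#' @export
export_presets <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- .preset_builders()
  files <- character(0)
  for (id in names(reg)) {
    f <- file.path(dir, paste0(id, ".json"))
    serialize_config(reg[[id]]$build(), f)
    files <- c(files, f)
  }
  invisible(files)
}
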