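# Analytic validation cases and synthetic test inputs. Each case bundles a
# runnable configuration with the exact solution it discretises, so the suite
# can quantify spatial/temporal error without external data.

#' Heat equation with a cosine initial condition
#'
#' `u_t = D u_xx` on `[0, L]` with homogeneous Neumann walls and
#' `u(x, 0) = cos(k pi x / L)`; the exact solution is the decaying mode
#' `u = exp(-D (k pi / L)^2 t) cos(k pi x / L)`. Doubling the wavenumber
#' quadruples the decay exponent, the classic teaching example. On the
#' cell-centre lattice the cosine is an exact eigenvector of the discrete
#' operator, so the temporal error can be isolated cleanly.
#'
#' @param k mode number (integer >= 1).
#' @param D diffusivity.
#' @param L domain length.
#' @param dx,dt,scheme numerics for the bundled config.
#' @return object of class `pde_case`: `cfg`, `exact` (a `pde_expr` in
#'   `x`, `t`), `describe`.
#' @export
make_heat_cosine_case <- function(k = 1, D = 1, L = 1,
                                  dx = L / 256, dt = NULL,
                                  scheme = "forward_euler") {
  stopifnot(k >= 1, k == round(k), D > 0, L > 0)
  if (is.null(dt)) dt <- 0.5 * dx^2 / (2 * D)   # half the 1D explicit limit
  cfg <- pde_config(
    species = "u",
    diffusion = list(u = list(u = format(D, digits = 17))),
    initial = list(u = sprintf("cos(%d*pi*x/%s)", as.integer(k), format(L, digits = 17))),
    dimension = 1, L_x = L, dx = dx, dt = dt, scheme = scheme,
    steps_per_frame = 10000L)
  exact <- parse_expr(sprintf("exp(-%s*(%d*pi/%s)^2*t) * cos(%d*pi*x/%s)",
                              format(D, digits = 17), as.integer(k),
                              format(L, digits = 17), as.integer(k),
                              format(L, digits = 17)),
                      allowed = c("x", "t"))
  structure(list(cfg = cfg, exact = exact,
                 describe = sprintf("heat cosine mode k=%d, D=%g, L=%g", k, D, L)),
            class = "pde_case")
}

#' Travelling-pulse wave equation case (d'Alembert solution)
#'
#' The wave equation `u_tt = c^2 u_xx` as the first-order system
#' `u_t = v`, `v_t = div(c^2 grad u)`, with a compact-support Gaussian pulse
#' centred at `L/2` and zero initial velocity. Before any boundary
#' interaction the exact solution is the d'Alembert superposition
#' `u(x, t) = (g(x - ct) + g(x + ct)) / 2`, each travelling copy carrying
#' half the initial peak. The pulse is truncated where it falls below 1e-12
#' of its peak so the compact support avoids seam artefacts.
#'
#' @param width Gaussian standard deviation.
#' @param c wave speed.
#' @param L domain length.
#' @param dx,dt numerics (RK4 is used; centred waves are neutrally stable
#'   under it at modest CFL numbers).
#' @return `pde_case` whose `exact` is an expression in `x`, `t`.
#' @export
make_dalembert_case <- function(width = 0.03, c = 1, L = 1,
                                dx = 1 / 512, dt = NULL) {
  stopifnot(width > 0, c > 0)
  if (is.null(dt)) dt <- 0.5 * dx / c
  x0 <- L / 2
  R2 <- 2 * width^2 * log(1e12)   # truncation radius^2: g < 1e-12 beyond
  g <- function(arg) sprintf(
    "exp(-((%s) - %s)^2/(2*%s^2)) * heaviside(%s - ((%s) - %s)^2)",
    arg, format(x0, digits = 17), format(width, digits = 17),
    format(R2, digits = 17), arg, format(x0, digits = 17))
  cfg <- pde_config(
    species = c("u", "v"),
    kinetics = list(u = "v"),
    diffusion = list(v = list(u = format(c^2, digits = 17))),
    initial = list(u = g("x"), v = "0"),
    dimension = 1, L_x = L, dx = dx, dt = dt,
    scheme = "rk4", steps_per_frame = 10000L)
  cs <- format(c, digits = 17)
  exact <- parse_expr(sprintf("0.5*(%s) + 0.5*(%s)",
                              g(sprintf("x - %s*t", cs)),
                              g(sprintf("x + %s*t", cs))),
                      allowed = c("x", "t"))
  structure(list(cfg = cfg, exact = exact,
                 describe = sprintf("d'Alembert pulse, c=%g, width=%g", c, width)),
            class = "pde_case")
}

#' KdV soliton case
#'
#' Single soliton `phi = (c/2) sech^2(sqrt(c)/2 (x - x0 - ct))` of
#' `phi_t = -phi_xxx - 6 phi phi_x` on a periodic domain (the sech^2 is
#' written via `1 - tanh^2`). The exact solution is the translate at speed
#' `c`; the two-soliton variant superposes well-separated solitons with
#' `c1 > c2`, which pass through one another with unchanged heights and
#' speeds.
#'
#' @param c soliton speed (= twice the peak height); for the two-soliton
#'   variant a vector `c(c1, c2)` with `c1 > c2`.
#' @param L periodic domain length; must be large enough that the sech^2
#'   tails are below 1e-8 at the seam.
#' @param x0 initial peak position(s).
#' @param dx,dt numerics (RK4; the dispersive term demands `dt` of order
#'   `dx^3`).
#' @return `pde_case`; for a single soliton `exact` is an expression in
#'   `x`, `t` valid modulo the periodic wrap.
#' @export
make_kdv_soliton_case <- function(c = 4, L = 40, x0 = NULL,
                                  dx = L / 512, dt = NULL) {
  stopifnot(all(c > 0), length(c) %in% 1:2)
  if (is.null(x0)) x0 <- if (length(c) == 1L) L / 4 else c(L / 4, L / 2)
  # seam check: sech^2 tail at distance L/2
  tail <- min((c / 2) * (1 - tanh(sqrt(c) / 2 * (L / 2 - 1e-6))^2))
  if (tail > 1e-8) stop("domain too small: soliton tails exceed 1e-8 at the seam",
                        call. = FALSE)
  hump <- function(ci, xi, arg = "x") sprintf(
    "%s*(1 - tanh(%s*((%s) - %s))^2)",
    format(ci / 2, digits = 17), format(sqrt(ci) / 2, digits = 17), arg,
    format(xi, digits = 17))
  ic <- paste(mapply(hump, c, x0), collapse = " + ")
  if (is.null(dt)) {
    kmax <- pi / dx
    dt <- 0.5 * 2.8 / kmax^3    # RK4 imaginary-axis stability for the k^3 branch
  }
  cfg <- pde_config(
    species = c("phi", "v"),
    algebraic = list(v = "phi_x"),
    kinetics = list(phi = "-v_xx - 6*v*phi"),
    initial = list(phi = ic),
    bcs = list(phi = "periodic", v = "periodic"),
    dimension = 1, L_x = L, dx = dx, dt = dt,
    scheme = "rk4", steps_per_frame = 100000L)
  exact <- if (length(c) == 1L)
    parse_expr(hump(c, x0, sprintf("x - %s*t", format(c, digits = 17))),
               allowed = c("x", "t"))
  else NULL
  structure(list(cfg = cfg, exact = exact, c = c, x0 = x0,
                 describe = sprintf("KdV soliton(s) c = %s on [0, %g]",
                                    paste(c, collapse = ", "), L)),
            class = "pde_case")
}

#' Two-level step image with seeded Gaussian noise
#'
#' Synthetic denoising input: an `n` by `n` greyscale PNG whose left half is
#' 0.25 and right half 0.75, plus iid Gaussian noise, clamped to [0, 1]. A
#' fixed seed yields identical bytes.
#'
#' @param n image side (pixels).
#' @param noise_sd noise standard deviation (0 gives exactly two levels).
#' @param seed RNG seed.
#' @param path output PNG path (default: a tempfile).
#' @return the path, with the pixel matrix attached as attribute `pixels`.
#' @export
make_noisy_step_image <- function(n = 64, noise_sd = 0.08, seed = 1L,
                                  path = tempfile(fileext = ".png")) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  base <- matrix(0.25, n, n)
  base[, (n %/% 2 + 1L):n] <- 0.75   # columns = x: right half high
  img <- base
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)   # rows = image rows, columns = x; step runs along x
  attr(path, "pixels") <- img
  path
}

#' @export
print.pde_case <- function(x, ...) {
  cat(sprintf("<pde_case: %s>\n", x$describe))
  invisible(x)
}
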