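grid_1d <- function(N = 64, L = 1) build_grid(list(dimension = 1, L_x = L), dx = L / N)
grid_2d <- function(N = 16, L = 1) build_grid(list(dimension = 2, L_x = L, L_y = L), dx = L / N)
bc_all <- function(kind, edges) stats::setNames(rep(list(list(kind = kind, data = NULL)),
                                                    length(edges)), edges)

test_that("ghost padding implements periodic wrap and Neumann mirror", {
  g <- build_grid(list(dimension = 1, L_x = 4), dx = 1)
  F <- matrix(c(1, 2, 3, 4), 4, 1)   # [a, b, c, d]
  P <- pad_with_ghosts(F, bc_all("periodic", c("left", "right")), g)
  expect_equal(P[1L, 2L], 4)   # left ghost = d
  expect_equal(P[6L, 2L], 1)   # right ghost = a

  P <- pad_with_ghosts(F, bc_all("neumann", c("left", "right")), g)
  expect_equal(P[1L, 2L], F[1L, 1L])  # mirror across the wall
  expect_equal(P[6L, 2L], F[4L, 1L])
})

test_that("inhomogeneous Neumann data enters the ghost with the grid spacing", {
  g <- grid_1d(N = 10)
  F <- matrix(0, 10, 1)
  bc <- list(left = list(kind = "neumann", data = parse_expr("3", allowed = character(0))),
             right = list(kind = "neumann", data = NULL))
  P <- pad_with_ghosts(F, bc, g)
  expect_equal(P[1L, 2L], 0 + g$dx_eff * 3)
})

test_that("Robin data may reference the species itself (explicit treatment)", {
  g <- grid_1d(N = 10)
  F <- matrix(seq(0.1, 1, length.out = 10), 10, 1)
  bc <- list(left = list(kind = "robin", data = parse_expr("-2*u", allowed = "u")),
             right = list(kind = "neumann", data = NULL))
  P <- pad_with_ghosts(F, bc, g, ctx = list(u = F))
  expect_equal(P[1L, 2L], F[1L] + g$dx_eff * (-2 * F[1L]))
})

test_that("first-derivative stencils are exact on their polynomial classes", {
  g <- grid_1d(N = 32)
  x <- g$X
  per <- bc_all("periodic", c("left", "right"))
  interior <- 2:(g$N_x - 1L)

  # constant field: all derivatives vanish everywhere
  Pc <- pad_with_ghosts(matrix(5, g$N_x, 1), per, g)
  expect_equal(central_first_derivative(Pc, "x", g), matrix(0, g$N_x, 1))
  expect_equal(upwind_first_derivative(Pc, "x", "backward", g), matrix(0, g$N_x, 1))
  expect_equal(second_derivative(Pc, "x", g), matrix(0, g$N_x, 1))

  # central difference exact for quadratics (interior)
  P <- pad_with_ghosts(x^2, bc_all("neumann", c("left", "right")), g)
  d1 <- central_first_derivative(P, "x", g)
  expect_equal(d1[interior, 1L], 2 * x[interior, 1L], tolerance = 1e-12)
  d2 <- second_derivative(P, "x", g)
  expect_equal(d2[interior, 1L], rep(2, length(interior)), tolerance = 1e-12)

  # upwind exact for linears; for x^2: backward gives 2x - h exactly
  Pl <- pad_with_ghosts(x, bc_all("neumann", c("left", "right")), g)
  expect_equal(upwind_first_derivative(Pl, "x", "backward", g)[interior, 1L],
               rep(1, length(interior)))
  expect_equal(upwind_first_derivative(Pl, "x", "forward", g)[interior, 1L],
               rep(1, length(interior)))
  db <- upwind_first_derivative(P, "x", "backward", g)
  expect_equal(db[interior, 1L], 2 * x[interior, 1L] - g$dx_eff, tolerance = 1e-12)
})

test_that("derivative stencils meet their Taylor-remainder bounds on sin", {
  g <- grid_1d(N = 64)
  x <- g$X
  per <- bc_all("periodic", c("left", "right"))
  h <- g$dx_eff
  F <- sin(2 * pi * x)
  P <- pad_with_ghosts(F, per, g)
  d1 <- central_first_derivative(P, "x", g)
  expect_lt(max(abs(d1 - 2 * pi * cos(2 * pi * x))), (2 * pi)^3 * h^2 / 6)
  d2 <- second_derivative(P, "x", g)
  expect_lt(max(abs(d2 + (2 * pi)^2 * F)), (2 * pi)^4 * h^2 / 12 * 1.01)
})

test_that("variable-coefficient diffusion stencil is exact on the printed cases", {
  g <- grid_2d(N = 16)
  nb <- bc_all("neumann", c("left", "right", "top", "bottom"))
  U <- g$X^2 + g$Y^2
  D2 <- matrix(2, g$N_x, g$N_y)
  r <- div_D_grad(pad_with_ghosts(D2, NULL, g), pad_with_ghosts(U, nb, g), g)
  ii <- 2:(g$N_x - 1L); jj <- 2:(g$N_y - 1L)
  expect_equal(r[ii, jj], matrix(8, length(ii), length(jj)), tolerance = 1e-12)

  # U constant: zero for any D
  Dv <- 1 + g$X + g$Y^2
  Uc <- matrix(3, g$N_x, g$N_y)
  r <- div_D_grad(pad_with_ghosts(Dv, NULL, g), pad_with_ghosts(Uc, nb, g), g)
  expect_equal(r, matrix(0, g$N_x, g$N_y))

  # D = x, U = x: div(x grad x) = 1 exactly (stencil exact for linear D, U)
  r <- div_D_grad(pad_with_ghosts(g$X, NULL, g), pad_with_ghosts(g$X, nb, g), g)
  expect_equal(r[ii, jj], matrix(1, length(ii), length(jj)), tolerance = 1e-12)
})

test_that("constant-D stencil reduces to D times the 5-point Laplacian", {
  g <- grid_2d(N = 12)
  per <- bc_all("periodic", c("left", "right", "top", "bottom"))
  set.seed(42)
  U <- matrix(rnorm(g$N_x * g$N_y), g$N_x, g$N_y)
  cD <- 1.7
  P <- pad_with_ghosts(U, per, g)
  r <- div_D_grad(pad_with_ghosts(matrix(cD, g$N_x, g$N_y), per, g), P, g)
  lap <- second_derivative(P, "x", g) + second_derivative(P, "y", g)
  expect_lt(max(abs(r - cD * lap)) / max(abs(r)), 1e-14)
})

test_that("periodic flux-form conservation: RHS sums to zero for smooth D", {
  cfg <- pde_config(
    species = "u",
    diffusion = list(u = list(u = "1 + 0.5*sin(2*pi*x)*cos(2*pi*y)")),
    bcs = list(u = "periodic"),
    initial = list(u = "exp(sin(2*pi*x) + cos(4*pi*y))"),
    dimension = 2, L_x = 1, L_y = 1, dx = 1 / 24, dt = 1e-5)
  rt <- compile_config(cfg)
  st <- pde_init(rt)
  r <- assemble_rhs(st, rt)$u
  expect_lt(abs(sum(r)) / sum(abs(r)), 1e-12)
})

test_that("assembled RHS matches analytic eigenfunction relation for heat", {
  for (N in c(64, 128)) {
    cfg <- heat_config_1d(dx = 1 / N)
    rt <- compile_config(cfg)
    st <- pde_init(rt)
    r <- assemble_rhs(st, rt)$u
    u <- st$fields$u
    relerr <- max(abs(r + pi^2 * u)) / pi^2
    expect_lt(relerr, 2 * (pi / N)^2)
  }
})

test_that("pure-kinetics RHS reproduces f (f = 1, D = 0)", {
  cfg <- pde_config(species = "u", kinetics = list(u = "1"),
                    dimension = 1, L_x = 1, dx = 0.1, dt = 1e-3)
  rt <- compile_config(cfg)
  r <- assemble_rhs(pde_init(rt), rt)$u
  expect_equal(r, matrix(1, rt$grid$N_x, 1L))
})

test_that("KdV RHS recomputes the algebraic gradient first and matches the analytic form", {
  L <- 2 * pi
  cfg <- pde_config(
    species = c("phi", "v"),
    algebraic = list(v = "phi_x"),
    kinetics = list(phi = "-v_xx - 6*v*phi"),
    bcs = list(phi = "periodic", v = "periodic"),
    initial = list(phi = "sin(x)"),
    dimension = 1, L_x = L, dx = L / 256, dt = 1e-6)
  rt <- compile_config(cfg)
  st <- pde_init(rt)
  r <- assemble_rhs(st, rt)
  x <- rt$grid$X
  # v must equal the discrete gradient of phi (recomputed before use)
  expect_equal(attr(r, "fields")$v,
               central_first_derivative(
                 pad_with_ghosts(st$fields$phi, rt$cfg$bcs$phi, rt$grid),
                 "x", rt$grid))
  # analytic: phi = sin -> v = cos, v_xx = -cos, rhs = cos - 6 sin cos, + O(h^2)
  exact <- cos(x) - 6 * sin(x) * cos(x)
  expect_lt(max(abs(r$phi - exact)), 30 * rt$grid$dx_eff^2)
})

test_that("RHS equals the action of an independently built dense operator", {
  dom <- list(dimension = 2, L_x = 1.2, L_y = 1)
  g <- build_grid(dom, dx = 0.2)
  expect_identical(c(g$N_x, g$N_y), c(6L, 5L))
  set.seed(7)
  u0 <- matrix(rnorm(30), 6, 5)
  v0 <- matrix(rnorm(30), 6, 5)

  run_case <- function(diffusion, kinetics = list()) {
    cfg <- pde_config(species = c("u", "v"), diffusion = diffusion,
                      kinetics = kinetics,
                      bcs = list(u = "periodic", v = "periodic"),
                      dimension = 2, L_x = 1.2, L_y = 1, dx = 0.2, dt = 1e-5)
    rt <- compile_config(cfg)
    st <- pde_init(rt)
    st$fields$u <- u0; st$fields$v <- v0
    assemble_rhs(st, rt)
  }
  scale <- function(m) max(abs(m))

  # constant D
  r <- run_case(list(u = list(u = "0.7"), v = list(v = "1.3")))
  A <- dense_diffusion_operator(matrix(0.7, 6, 5), g)
  B <- dense_diffusion_operator(matrix(1.3, 6, 5), g)
  expect_lt(scale(r$u - matrix(A %*% as.vector(u0), 6, 5)) / scale(r$u), 1e-12)
  expect_lt(scale(r$v - matrix(B %*% as.vector(v0), 6, 5)) / scale(r$v), 1e-12)

  # variable D(x, y)
  Dxy <- 1 + 0.5 * sin(2 * pi * g$X / 1.2) * cos(2 * pi * g$Y)
  r <- run_case(list(u = list(u = "1 + 0.5*sin(2*pi*x/1.2)*cos(2*pi*y)")))
  A <- dense_diffusion_operator(Dxy, g)
  expect_lt(scale(r$u - matrix(A %*% as.vector(u0), 6, 5)) / scale(r$u), 1e-12)

  # cross-diffusion with linear kinetics
  r <- run_case(list(u = list(u = "1", v = "0.4"), v = list(v = "2")),
                kinetics = list(u = "0.3*v", v = "-0.2*u"))
  I1 <- dense_diffusion_operator(matrix(1, 6, 5), g)
  C <- dense_diffusion_operator(matrix(0.4, 6, 5), g)
  B <- dense_diffusion_operator(matrix(2, 6, 5), g)
  ru <- matrix(I1 %*% as.vector(u0) + C %*% as.vector(v0), 6, 5) + 0.3 * v0
  rv <- matrix(B %*% as.vector(v0), 6, 5) - 0.2 * u0
  expect_lt(scale(r$u - ru) / scale(ru), 1e-12)
  expect_lt(scale(r$v - rv) / scale(rv), 1e-12)
})

test_that("periodic RHS assembly is translation-equivariant", {
  cfg <- pde_config(
    species = "u",
    diffusion = list(u = list(u = "1")),
    kinetics = list(u = "u^2 - u + 0.1*u_x"),
    bcs = list(u = "periodic"),
    dimension = 1, L_x = 1, dx = 1 / 32, dt = 1e-5)
  rt <- compile_config(cfg)
  st <- pde_init(rt)
  set.seed(3)
  st$fields$u <- matrix(rnorm(32), 32, 1)
  r0 <- assemble_rhs(st, rt)$u
  m <- 5L
  shift <- function(F, m) F[c((length(F) - m + 1L):length(F), 1:(length(F) - m)), , drop = FALSE]
  st2 <- st
  st2$fields$u <- shift(st$fields$u, m)
  r1 <- assemble_rhs(st2, rt)$u
  expect_identical(r1, shift(r0, m))
})

test_that("masked-out nodes are frozen and mask edges carry no flux", {
  cfg <- pde_config(
    species = "u",
    diffusion = list(u = list(u = "1")),
    indicator = "heaviside(0.2 - abs(x - 0.5))",   # a vertical strip
    initial = list(u = "1 + sin(2*pi*x)*sin(2*pi*y)"),
    dimension = 2, L_x = 1, L_y = 1, dx = 1 / 20, dt = 1e-4,
    bcs = list(u = "periodic"))
  rt <- compile_config(cfg)
  st <- pde_init(rt)
  r <- assemble_rhs(st, rt)$u
  expect_true(all(r[!rt$mask$inside] == 0))
  # strip with zero-flux sides: total mass inside is conserved by the RHS
  expect_lt(abs(sum(r[rt$mask$inside])) / sum(abs(r[rt$mask$inside])), 1e-12)
})

test_that("Dirichlet pins boundary-adjacent nodes and zeroes their derivative", {
  cfg <- pde_config(
    species = "u",
    diffusion = list(u = list(u = "1")),
    bcs = list(u = list(left = list(kind = "dirichlet", data = "0.25"),
                        right = list(kind = "dirichlet", data = "0.25"))),
    initial = list(u = "sin(pi*x)"),
    dimension = 1, L_x = 1, dx = 1 / 32, dt = 1e-4)
  rt <- compile_config(cfg)
  st <- pde_init(rt)
  expect_equal(st$fields$u[1L, 1L], 0.25)
  expect_equal(st$fields$u[32L, 1L], 0.25)
  r <- assemble_rhs(st, rt)$u
  expect_identical(r[1L, 1L], 0)
  expect_identical(r[32L, 1L], 0)
  res <- pde_run(rt, t_end = 100 * cfg$numerics$dt, quiet = TRUE)
  expect_equal(res$state$fields$u[1L, 1L], 0.25)
  expect_equal(res$state$fields$u[32L, 1L], 0.25)
})
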