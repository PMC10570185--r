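# A diffusion-free single-species config makes the stepper act on the scalar
# surrogate du/dt = f(u), so one step is hand-checkable per scheme.
ode_config <- function(f = "-u", dt = 0.1, scheme = "forward_euler") {
  pde_config(species = "u", kinetics = list(u = f),
             initial = list(u = "1"),
             dimension = 1, L_x = 1, dx = 1 / 4, dt = dt, scheme = scheme)
}

test_that("one step of each scheme matches the hand-computed value for du/dt = -u", {
  cases <- list(
    forward_euler = 0.9,                         # 1 - h
    midpoint = 0.905,                            # 1 - h + h^2/2
    rk4 = 0.9048375                              # 1 - h + h^2/2 - h^3/6 + h^4/24
  )
  for (scheme in names(cases)) {
    rt <- compile_config(ode_config(scheme = scheme))
    st <- pde_step(pde_init(rt), rt, make_stepper(scheme), dt = 0.1)
    expect_equal(st$fields$u[1L, 1L], cases[[scheme]], tolerance = 1e-15,
                 label = scheme)
    expect_equal(st$t, 0.1)
    expect_identical(st$step_index, 1L)
  }
})

test_that("two-step Adams-Bashforth starts with midpoint then uses its history", {
  rt <- compile_config(ode_config(scheme = "adams_bashforth2"))
  stp <- make_stepper("adams_bashforth2")
  s1 <- pde_step(pde_init(rt), rt, stp, dt = 0.1)
  expect_equal(s1$fields$u[1L, 1L], 0.905)       # first step == midpoint
  s2 <- pde_step(s1, rt, stp, dt = 0.1)
  # u2 = u1 + h (3/2 f(u1) - 1/2 f(u0)) = 0.905 + 0.1(-1.3575 + 0.5)
  expect_equal(s2$fields$u[1L, 1L], 0.81925, tolerance = 1e-15)
  # changing dt clears the history (falls back to the midpoint start)
  s3 <- pde_step(s2, rt, stp, dt = 0.05)
  expect_equal(s3$fields$u[1L, 1L], 0.81925 * (1 - 0.05 + 0.05^2 / 2),
               tolerance = 1e-12)
})

test_that("temporal convergence orders match each scheme's design order", {
  case <- make_heat_cosine_case(k = 1, D = 1, L = 1, dx = 1 / 16)
  t_end <- 0.2
  dt0 <- t_end / 256
  expected <- c(forward_euler = 1, midpoint = 2, adams_bashforth2 = 2, rk4 = 4)
  for (scheme in names(expected)) {
    u_h <- run_heat_terminal(case, dt0, t_end, scheme)
    u_h2 <- run_heat_terminal(case, dt0 / 2, t_end, scheme)
    u_h4 <- run_heat_terminal(case, dt0 / 4, t_end, scheme)
    p <- richardson_order(u_h, u_h2, u_h4)
    expect_lt(abs(p - expected[[scheme]]), 0.1, label = sprintf("%s order %.3f", scheme, p))
  }
})

test_that("blow-up is detected from non-finite values and unstable timesteps", {
  rt <- compile_config(ode_config())
  st <- pde_init(rt)
  expect_false(detect_blowup(st))
  st$fields$u[2L, 1L] <- NaN
  expect_true(detect_blowup(st))
  st$fields$u[2L, 1L] <- Inf
  expect_true(detect_blowup(st))

  # heat equation far above the explicit stability limit
  dx <- 1 / 16
  cfg <- pde_config(species = "u", diffusion = list(u = list(u = "1")),
                    initial = list(u = "cos(pi*x)*cos(pi*y)"),
                    dimension = 2, L_x = 1, L_y = 1,
                    dx = dx, dt = 10 * dx^2)    # stability needs dt <= dx^2/4
  err <- tryCatch(pde_run(cfg, t_end = 200 * cfg$numerics$dt, quiet = TRUE),
                  gridpde_blowup = function(e) e)
  expect_s3_class(err, "gridpde_blowup")
  expect_match(conditionMessage(err), "blew up at t =")
  expect_lte(err$result$state$step_index, 200L)
})

test_that("brush events set, add, and touch exactly the nodes within radius", {
  cfg <- pde_config(species = "u", diffusion = list(u = list(u = "1")),
                    initial = list(u = "0"),
                    dimension = 2, L_x = 1, L_y = 1, dx = 1 / 32, dt = 1e-4)
  rt <- compile_config(cfg)
  st <- pde_init(rt)

  # disc covering the whole domain sets everything
  big <- apply_brush(st, list(species = "u", shape = "disc", centre = c(0.5, 0.5),
                              radius = 2, value = 1, mode = "set"), rt)
  expect_true(all(big$fields$u == 1))

  # add with value 0 is a no-op
  same <- apply_brush(st, list(species = "u", shape = "disc", centre = c(0.5, 0.5),
                               radius = 0.2, value = 0, mode = "add"), rt)
  expect_identical(same$fields$u, st$fields$u)

  # modified-node count equals the brute-force distance count
  r <- 0.23
  touched <- apply_brush(st, list(species = "u", shape = "disc",
                                  centre = c(0.4, 0.6), radius = r,
                                  value = 7, mode = "set"), rt)
  n_mod <- sum(touched$fields$u == 7)
  count <- 0L
  g <- rt$grid
  for (j in seq_len(g$N_y)) for (i in seq_len(g$N_x)) {
    if (((i - 0.5) * g$dx_eff - 0.4)^2 + ((j - 0.5) * g$dy_eff - 0.6)^2 <= r^2)
      count <- count + 1L
  }
  expect_identical(n_mod, count)

  # gaussian adds the kernel
  gau <- apply_brush(st, list(species = "u", shape = "gaussian",
                              centre = c(0.5, 0.5), radius = 0.1, value = 2), rt)
  r2 <- (g$X - 0.5)^2 + (g$Y - 0.5)^2
  expect_equal(gau$fields$u, 2 * exp(-r2 / (2 * 0.1^2)))

  expect_error(apply_brush(st, list(species = "zz", shape = "disc",
                                    centre = c(0.5, 0.5), radius = 0.1,
                                    value = 1, mode = "set"), rt),
               "unknown species 'zz'")
})

test_that("run with t_end = 0 returns the initial state after zero steps", {
  cfg <- heat_config_1d()
  res <- pde_run(cfg, t_end = 0, quiet = TRUE)
  expect_identical(res$state$step_index, 0L)
  expect_identical(res$state$fields, pde_init(cfg)$fields)
  expect_length(res$frames, 1L)
})

test_that("checkpoint restore reproduces the trajectory bit-identically", {
  for (scheme in c("forward_euler", "rk4")) {
    cfg <- heat_config_1d(dx = 1 / 32, scheme = scheme)
    T_half <- 64 * cfg$numerics$dt
    T_full <- 128 * cfg$numerics$dt
    direct <- pde_run(cfg, T_full, quiet = TRUE)
    first <- pde_run(cfg, T_half, checkpoint_times = T_half, quiet = TRUE)
    expect_length(first$checkpoints, 1L)
    cp <- first$checkpoints[[1L]]
    expect_identical(cp$config_hash, config_hash(cfg))
    resumed <- pde_run(cfg, T_full, init_state = cp$state, quiet = TRUE)
    expect_identical(resumed$state$fields, direct$state$fields)
    expect_equal(resumed$state$t, direct$state$t)
  }
})

test_that("runs are deterministic given the config seed", {
  cfg <- pde_config(species = "u", diffusion = list(u = list(u = "1")),
                    initial = list(u = "rand()"),
                    bcs = list(u = "periodic"),
                    dimension = 1, L_x = 1, dx = 1 / 32, dt = 1e-4, seed = 11L)
  a <- pde_run(cfg, 50 * cfg$numerics$dt, quiet = TRUE)
  b <- pde_run(cfg, 50 * cfg$numerics$dt, quiet = TRUE)
  expect_identical(a$state$fields, b$state$fields)
  cfg2 <- cfg; cfg2$seed <- 12L
  c2 <- pde_run(cfg2, 50 * cfg$numerics$dt, quiet = TRUE)
  expect_false(identical(a$state$fields, c2$state$fields))
})

test_that("scheme schedules switch the integrator mid-run and are logged", {
  cfg <- heat_config_1d(dx = 1 / 32)
  cfg$numerics$schedule <- list(list(t = 0, scheme = "forward_euler"),
                                list(t = 20 * cfg$numerics$dt, scheme = "rk4"))
  res <- pde_run(cfg, 40 * cfg$numerics$dt, quiet = TRUE)
  expect_true(any(grepl("scheme switch to rk4", res$events)))
  expect_true(all(is.finite(res$state$fields$u)))
})

test_that("mass is conserved in time under periodic transport-free dynamics", {
  cfg <- pde_config(
    species = "u",
    diffusion = list(u = list(u = "1 + 0.5*sin(2*pi*x)*cos(2*pi*y)")),
    bcs = list(u = "periodic"),
    initial = list(u = "1 + 0.3*sin(2*pi*x) + 0.2*cos(2*pi*y)"),
    dimension = 2, L_x = 1, L_y = 1, dx = 1 / 16, dt = 5e-4)
  rt <- compile_config(cfg)
  g <- rt$grid
  for (scheme in c("forward_euler", "midpoint")) {
    st <- pde_init(rt)
    m0 <- compute_integral(st$fields$u, g)
    stp <- make_stepper(scheme)
    for (i in 1:500) st <- pde_step(st, rt, stp)
    expect_lt(abs(compute_integral(st$fields$u, g) - m0) / abs(m0), 1e-11,
              label = scheme)
  }
})

test_that("mirror-symmetric configurations stay mirror-symmetric exactly", {
  cfg <- pde_config(species = "u",
                    diffusion = list(u = list(u = "1")),
                    kinetics = list(u = "u - u^3"),
                    initial = list(u = "cos(2*pi*(x - 0.5))"),
                    bcs = list(u = "periodic"),
                    dimension = 1, L_x = 1, dx = 1 / 32, dt = 1e-4)
  res <- pde_run(cfg, 200 * cfg$numerics$dt, quiet = TRUE)
  for (fr in res$frames) {
    u <- fr$fields$u[, 1L]
    expect_identical(u, rev(u))   # exact, by symmetric stencil construction
  }
})

test_that("the stability advisory warns about oversized timesteps", {
  cfg <- heat_config_1d(dx = 1 / 32)
  cfg$numerics$dt <- 1   # far beyond h^2/2
  expect_message(
    tryCatch(pde_run(cfg, 1, quiet = FALSE), gridpde_blowup = function(e) NULL),
    "stability advisory")
})
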