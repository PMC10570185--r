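# Shared fixtures and independent oracles, built in code.

# Minimal 1D heat-equation config (the canonical "runnable" fixture).
heat_config_1d <- function(dx = 1 / 64, dt = NULL, D = 1, L = 1,
                           scheme = "forward_euler", ic = "cos(pi*x)") {
  if (is.null(dt)) dt <- 0.25 * dx^2 / D
  pde_config(species = "u",
             diffusion = list(u = list(u = format(D, digits = 17))),
             initial = list(u = ic),
             dimension = 1, L_x = L, dx = dx, dt = dt, scheme = scheme,
             steps_per_frame = 100000L)
}

# A uniform-field state for a runtime (all species set to `value`).
flat_state <- function(rt, value = 0) {
  st <- pde_init(rt)
  for (nm in names(st$fields)) st$fields[[nm]][] <- value
  st
}

# Independent dense diffusion operator: explicit loops over nodes and
# neighbour pairs in flux form, (L u)_node = sum_nbr (D0+Dnb)/2 (Unb-U0)/h^2.
# Completely separate from the package's vectorised stencil path.
dense_diffusion_operator <- function(Dfield, grid, periodic = TRUE) {
  nx <- grid$N_x; ny <- grid$N_y
  n <- nx * ny
  id <- function(i, j) (j - 1L) * nx + i
  A <- matrix(0, n, n)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    me <- id(i, j)
    nbrs <- list(
      list(i = i - 1L, j = j, h = grid$dx_eff),
      list(i = i + 1L, j = j, h = grid$dx_eff))
    if (grid$dimension == 2L) {
      nbrs <- c(nbrs, list(
        list(i = i, j = j - 1L, h = grid$dy_eff),
        list(i = i, j = j + 1L, h = grid$dy_eff)))
    }
    for (nb in nbrs) {
      ii <- nb$i; jj <- nb$j
      if (periodic) {
        ii <- ((ii - 1L) %% nx) + 1L
        jj <- ((jj - 1L) %% ny) + 1L
      } else {
        # zero-flux wall: skip the edge entirely (mirror ghost cancels)
        if (ii < 1L || ii > nx || jj < 1L || jj > ny) next
      }
      w <- (Dfield[i, j] + Dfield[ii, jj]) / (2 * nb$h^2)
      A[me, me] <- A[me, me] - w
      A[me, id(ii, jj)] <- A[me, id(ii, jj)] + w
    }
  }
  A
}

# Estimate a convergence order from errors at a step-halving triple by
# Richardson differences: log2(|u_h - u_{h/2}| / |u_{h/2} - u_{h/4}|).
richardson_order <- function(u_h, u_h2, u_h4) {
  log2(max(abs(u_h - u_h2)) / max(abs(u_h2 - u_h4)))
}

# Final heat-cosine field integrated with a given scheme and dt.
run_heat_terminal <- function(case, dt, t_end, scheme) {
  cfg <- case$cfg
  cfg$numerics$dt <- dt
  cfg$numerics$schedule <- list(list(t = 0, scheme = scheme))
  res <- pde_run(cfg, t_end, quiet = TRUE)
  res$state$fields$u
}
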