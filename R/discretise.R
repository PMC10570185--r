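# Spatial finite differences: ghost-node padding, the central/upwind/second
# derivative stencils, the variable-coefficient diffusion stencil
#
#   div(D grad u) ~ (1/2 dx^2) { D0 [u(x-dx) - 2 u + u(x+dx)]
#                              + D(x-dx) [u(x-dx) - u]
#                              + D(x+dx) [u(x+dx) - u] }  (+ analogous y terms)
#
# which is algebraically the flux form  sum_nbr (D0+Dnbr)/2 (Unbr-U0)/h^2 and
# reduces to D times the 5-point Laplacian for constant D, and the
# method-of-lines right-hand-side assembly.

.as_field <- function(v, grid) {
  if (is.matrix(v) && nrow(v) == grid$N_x && ncol(v) == grid$N_y) return(v)
  if (length(v) == 1L) return(matrix(as.numeric(v), grid$N_x, grid$N_y))
  if (length(v) == grid$N_x * grid$N_y) return(matrix(as.numeric(v), grid$N_x, grid$N_y))
  stop("field has the wrong shape for the grid", call. = FALSE)
}

# Evaluate a boundary data expression over the grid context and return the
# full-grid matrix (slices are taken per edge). NULL data means 0.
.bc_data_field <- function(data, env, grid) {
  if (is.null(data)) return(NULL)
  .as_field(eval_expr(data, env), grid)
}

#' Pad a field with one layer of ghost nodes
#'
#' Ghost values encode the boundary conditions so that the interior stencils
#' need no modification. Per edge: periodic wraps the opposite side;
#' Neumann/Robin set `ghost = u_adj + h * g`, where `u_adj` is the
#' boundary-adjacent node (its mirror image across the wall on this
#' cell-centred lattice), `h` the spacing on the normal axis and `g` the
#' outward-normal-derivative data evaluated at the boundary-adjacent nodes
#' (`g` may reference the species itself, which is the Robin case, treated
#' explicitly with the current iterate); Dirichlet mirrors (`ghost = u_adj`) —
#' Dirichlet is enforced not through ghosts but by pinning the
#' boundary-adjacent nodes to the data value and zeroing their
#' time-derivative.
#'
#' @param F grid-shaped field matrix.
#' @param bc per-edge boundary conditions for this species (the per-species
#'   entry of a config's `bcs`), or `NULL` for mirror padding on all edges
#'   (used to extend diffusivity fields).
#' @param grid a [build_grid()] result.
#' @param t model time (boundary data may depend on it).
#' @param ctx named list/environment with species values and parameters for
#'   boundary data expressions (coordinates and `t` are added here).
#' @return `(N_x+2) x (N_y+2)` matrix.
#' @export
pad_with_ghosts <- function(F, bc = NULL, grid, t = 0, ctx = list()) {
  nx <- grid$N_x; ny <- grid$N_y
  P <- matrix(0, nx + 2L, ny + 2L)
  ii <- 2:(nx + 1L); jj <- 2:(ny + 1L)
  P[ii, jj] <- F
  env <- NULL
  need_env <- !is.null(bc) &&
    (!is.null(bc$left$data) || !is.null(bc$right$data) ||
     !is.null(bc$top$data) || !is.null(bc$bottom$data))
  if (need_env) {
    base <- if (is.environment(ctx)) as.list(ctx) else as.list(ctx)
    base$x <- grid$X; base$t <- t
    if (grid$dimension == 2L) base$y <- grid$Y
    env <- list2env(base, parent = .expr_funcs_env())
  }
  kind <- function(edge) {
    b <- if (is.null(bc)) NULL else bc[[edge]]
    if (is.null(b)) "mirror" else b$kind
  }
  gdata <- function(edge) .bc_data_field(bc[[edge]]$data, env, grid)

  k <- kind("left")
  P[1L, jj] <- if (k == "periodic") F[nx, ]
    else if (k == "neumann" || k == "robin") {
      g <- gdata("left"); if (is.null(g)) F[1L, ] else F[1L, ] + grid$dx_eff * g[1L, ]
    } else F[1L, ]
  k <- kind("right")
  P[nx + 2L, jj] <- if (k == "periodic") F[1L, ]
    else if (k == "neumann" || k == "robin") {
      g <- gdata("right"); if (is.null(g)) F[nx, ] else F[nx, ] + grid$dx_eff * g[nx, ]
    } else F[nx, ]
  if (grid$dimension == 2L) {
    # y = 0 edge is "bottom", y = L_y edge is "top"
    k <- kind("bottom")
    P[ii, 1L] <- if (k == "periodic") F[, ny]
      else if (k == "neumann" || k == "robin") {
        g <- gdata("bottom"); if (is.null(g)) F[, 1L] else F[, 1L] + grid$dy_eff * g[, 1L]
      } else F[, 1L]
    k <- kind("top")
    P[ii, ny + 2L] <- if (k == "periodic") F[, 1L]
      else if (k == "neumann" || k == "robin") {
        g <- gdata("top"); if (is.null(g)) F[, ny] else F[, ny] + grid$dy_eff * g[, ny]
      } else F[, ny]
  } else {
    P[ii, 1L] <- F[, 1L]; P[ii, ny + 2L] <- F[, ny]
  }
  # corners are never read by the unmixed stencils; copy for tidiness
  P[1L, 1L] <- P[2L, 1L]; P[nx + 2L, 1L] <- P[nx + 1L, 1L]
  P[1L, ny + 2L] <- P[2L, ny + 2L]; P[nx + 2L, ny + 2L] <- P[nx + 1L, ny + 2L]
  P
}

# Interior + four shifted neighbour views of a padded field, with excluded
# (masked-out) neighbours replaced by the centre value, i.e. zero-flux /
# zero-gradient across mask edges.
.nbrs <- function(P, grid, mask = NULL) {
  nx <- grid$N_x; ny <- grid$N_y
  ii <- 2:(nx + 1L); jj <- 2:(ny + 1L)
  F0 <- P[ii, jj, drop = FALSE]
  out <- list(F0 = F0,
              xm = P[ii - 1L, jj, drop = FALSE], xp = P[ii + 1L, jj, drop = FALSE],
              ym = P[ii, jj - 1L, drop = FALSE], yp = P[ii, jj + 1L, drop = FALSE])
  if (!is.null(mask) && isTRUE(mask$any_excluded)) {
    out$xm[mask$excl_xm] <- F0[mask$excl_xm]
    out$xp[mask$excl_xp] <- F0[mask$excl_xp]
    out$ym[mask$excl_ym] <- F0[mask$excl_ym]
    out$yp[mask$excl_yp] <- F0[mask$excl_yp]
  }
  out
}

#' Central first derivative of a padded field
#'
#' `(F(x+h) - F(x-h)) / (2h)` at every node; exact for quadratics.
#'
#' @param P padded field from [pad_with_ghosts()].
#' @param axis `"x"` or `"y"`.
#' @param grid a [build_grid()] result.
#' @param mask optional [build_mask()] result (mask edges are zero-gradient).
#' @return grid-shaped matrix.
#' @export
central_first_derivative <- function(P, axis = c("x", "y"), grid, mask = NULL) {
  axis <- match.arg(axis)
  n <- .nbrs(P, grid, mask)
  if (axis == "x") (n$xp - n$xm) / (2 * grid$dx_eff)
  else (n$yp - n$ym) / (2 * grid$dy_eff)
}

#' One-sided (upwind) first derivative
#'
#' `backward`: `(F(x) - F(x-h)) / h`; `forward`: `(F(x+h) - F(x)) / h`.
#' First-order accurate; the side is chosen explicitly by the model author
#' through the expression tokens `u_x_b`, `u_x_f`, `u_y_b`, `u_y_f`.
#'
#' @inheritParams central_first_derivative
#' @param side `"backward"` or `"forward"`.
#' @return grid-shaped matrix.
#' @export
upwind_first_derivative <- function(P, axis = c("x", "y"),
                                    side = c("backward", "forward"),
                                    grid, mask = NULL) {
  axis <- match.arg(axis); side <- match.arg(side)
  n <- .nbrs(P, grid, mask)
  h <- if (axis == "x") grid$dx_eff else grid$dy_eff
  if (axis == "x") {
    if (side == "backward") (n$F0 - n$xm) / h else (n$xp - n$F0) / h
  } else {
    if (side == "backward") (n$F0 - n$ym) / h else (n$yp - n$F0) / h
  }
}

#' Second derivative of a padded field
#'
#' `(F(x-h) - 2 F(x) + F(x+h)) / h^2`; exact for quadratics; backs the
#' `u_xx` / `u_yy` derivative tokens.
#'
#' @inheritParams central_first_derivative
#' @return grid-shaped matrix.
#' @export
second_derivative <- function(P, axis = c("x", "y"), grid, mask = NULL) {
  axis <- match.arg(axis)
  n <- .nbrs(P, grid, mask)
  if (axis == "x") ((n$xm + n$xp) - 2 * n$F0) / grid$dx_eff^2
  else ((n$ym + n$yp) - 2 * n$F0) / grid$dy_eff^2
}

#' Variable-coefficient diffusion stencil
#'
#' Discretises `div(D grad u)` with the second-order stencil that evaluates
#' `D` at nodes (see the header of this file for the printed form). For
#' spatially constant `D` it reduces to `D` times the 5-point Laplacian; in
#' flux form it is antisymmetric, so with periodic boundaries the stencil sums
#' to zero over the grid (discrete mass conservation).
#'
#' @param D_padded padded diffusivity field (pad with `bc = NULL` for
#'   mirror/wrap extension, or with the species' BCs for periodic wrap).
#' @param U_padded padded species field.
#' @inheritParams central_first_derivative
#' @return grid-shaped matrix.
#' @export
div_D_grad <- function(D_padded, U_padded, grid, mask = NULL) {
  u <- .nbrs(U_padded, grid, mask)
  d <- .nbrs(D_padded, grid, mask)
  r <- (d$F0 * ((u$xm + u$xp) - 2 * u$F0) +
        (d$xm * (u$xm - u$F0) + d$xp * (u$xp - u$F0))) / (2 * grid$dx_eff^2)
  if (grid$dimension == 2L) {
    r <- r + (d$F0 * ((u$ym + u$yp) - 2 * u$F0) +
              (d$ym * (u$ym - u$F0) + d$yp * (u$yp - u$F0))) / (2 * grid$dy_eff^2)
  }
  r
}

# Runtime compilation -------------------------------------------------------

#' Compile a configuration into a reusable runtime
#'
#' Precomputes everything the right-hand side and the steppers need: the
#' grid, the domain mask, the algebraic evaluation order, Dirichlet pin
#' masks, the bound function environment (image samplers), and per-expression
#' derivative-token requirements. All run/step entry points accept either a
#' config (compiling on the fly) or a prepared runtime.
#'
#' @param cfg a valid [pde_config()].
#' @return environment of class `pde_runtime`.
#' @export
compile_config <- function(cfg) {
  diags <- validate_config(cfg)
  if (length(diags))
    stop(paste(c("configuration is not runnable:", unlist(diags)), collapse = "\n  "),
         call. = FALSE)
  rt <- new.env(parent = emptyenv())
  rt$cfg <- cfg
  rt$grid <- build_grid(cfg$domain, cfg$numerics$dx)
  rt$mask <- build_mask(cfg$domain$indicator, rt$grid, cfg$params)
  rt$alg_order <- algebraic_order(cfg)
  rt$diff_names <- .differential_names(cfg)
  rt$funcs <- .expr_funcs_env()
  for (slot in intersect(names(cfg$images), c("I_S", "I_T"))) {
    if (is.null(cfg$images[[slot]])) next
    img <- load_image_function(cfg$images[[slot]])
    local({
      sampler <- img; Lx <- rt$grid$L_x
      Ly <- if (rt$grid$dimension == 2L) rt$grid$L_y else 1
      assign(slot, function(x, y) sample_image(sampler, x, y, Lx, Ly), envir = rt$funcs)
    })
  }
  # Dirichlet pinning: boundary-adjacent slices per species
  nx <- rt$grid$N_x; ny <- rt$grid$N_y
  rt$pin <- list()
  for (nm in .species_names(cfg)) {
    pm <- matrix(FALSE, nx, ny)
    dir_edges <- character(0)
    for (ed in .edges_for(cfg$domain$dimension)) {
      if (cfg$bcs[[nm]][[ed]]$kind == "dirichlet") {
        dir_edges <- c(dir_edges, ed)
        switch(ed,
               left = { pm[1L, ] <- TRUE }, right = { pm[nx, ] <- TRUE },
               bottom = { pm[, 1L] <- TRUE }, top = { pm[, ny] <- TRUE })
      }
    }
    if (length(dir_edges)) rt$pin[[nm]] <- list(mask = pm, edges = dir_edges)
  }
  rt$zero_rhs <- !rt$mask$inside
  # precomputed token symbol table: "u_xx" -> list(species, suffix)
  rt$token_map <- new.env(parent = emptyenv())
  for (nm in .species_names(cfg)) for (suf in .token_suffixes)
    assign(paste0(nm, "_", suf), list(species = nm, suffix = suf),
           envir = rt$token_map)
  rt$stale_tokens <- lapply(stats::setNames(nm = .species_names(cfg)), function(nm)
    paste(nm, .token_suffixes, sep = "_"))
  class(rt) <- "pde_runtime"
  rt
}

# Evaluation environment for one (fields, t): species matrices + coords +
# params, parented by the bound function env. Token fields are added lazily.
.make_env <- function(fields, rt, t) {
  env <- new.env(parent = rt$funcs)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = env)
  env$x <- rt$grid$X; env$t <- t
  if (rt$grid$dimension == 2L) env$y <- rt$grid$Y
  for (p in names(rt$cfg$params)) assign(p, rt$cfg$params[[p]], envir = env)
  env
}

# Compute any derivative tokens that `e` needs and bind them in `env`.
# `pads` is an environment caching padded fields per species for this call.
.ensure_tokens <- function(e, env, rt, pads, t) {
  for (s in e$syms) {
    if (exists(s, envir = env, inherits = FALSE)) next
    tok <- if (exists(s, envir = rt$token_map, inherits = FALSE))
      get(s, envir = rt$token_map) else NULL
    if (is.null(tok)) next
    P <- if (exists(tok$species, envir = pads, inherits = FALSE))
      get(tok$species, envir = pads) else NULL
    if (is.null(P)) {
      P <- pad_with_ghosts(get(tok$species, envir = env), rt$cfg$bcs[[tok$species]],
                           rt$grid, t, env)
      assign(tok$species, P, envir = pads)
    }
    n <- .nbrs(P, rt$grid, rt$mask)
    g <- rt$grid
    val <- switch(tok$suffix,
      x   = (n$xp - n$xm) / (2 * g$dx_eff),
      y   = (n$yp - n$ym) / (2 * g$dy_eff),
      xx  = ((n$xm + n$xp) - 2 * n$F0) / g$dx_eff^2,
      yy  = ((n$ym + n$yp) - 2 * n$F0) / g$dy_eff^2,
      x_b = (n$F0 - n$xm) / g$dx_eff,
      x_f = (n$xp - n$F0) / g$dx_eff,
      y_b = (n$F0 - n$ym) / g$dy_eff,
      y_f = (n$yp - n$F0) / g$dy_eff)
    assign(s, val, envir = env)
  }
}

# Recompute all algebraic species (topological order) in fields/env.
# Invalidates pad/token caches of the species it updates.
.update_algebraic <- function(fields, env, rt, pads, t) {
  for (nm in rt$alg_order) {
    e <- rt$cfg$species[[nm]]$algebraic_rhs
    .ensure_tokens(e, env, rt, pads, t)
    val <- .as_field(eval_expr(e, env), rt$grid)
    fields[[nm]] <- val
    assign(nm, val, envir = env)
    if (exists(nm, envir = pads, inherits = FALSE)) rm(list = nm, envir = pads)
    stale <- rt$stale_tokens[[nm]]
    for (s in stale) if (exists(s, envir = env, inherits = FALSE)) rm(list = s, envir = env)
  }
  fields
}

#' Assemble the method-of-lines right-hand side
#'
#' Recomputes the algebraic species in dependency order, then for each
#' differential species `i` evaluates
#' \eqn{\sum_j \nabla\cdot(D_{ij}\nabla u_j) + f_i}
#' with the stencils of this module; the result is zeroed at masked-out nodes
#' and at Dirichlet-pinned boundary nodes. Non-finite values are allowed to
#' propagate (blow-up detection owns the error).
#'
#' @param state a `pde_state` (see [pde_init()]); its algebraic fields are
#'   refreshed as a side effect of the returned attribute `fields`.
#' @param cfg a [pde_config()] or a [compile_config()] runtime.
#' @param t model time (defaults to the state clock).
#' @return named list of grid-shaped `du_i/dt` matrices, one per differential
#'   species, with attribute `fields` holding the refreshed field set.
#' @export
assemble_rhs <- function(state, cfg, t = state$t) {
  rt <- if (inherits(cfg, "pde_runtime")) cfg else compile_config(cfg)
  fields <- state$fields
  env <- .make_env(fields, rt, t)
  pads <- new.env(parent = emptyenv())
  fields <- .update_algebraic(fields, env, rt, pads, t)
  cfg <- rt$cfg
  out <- vector("list", length(rt$diff_names))
  names(out) <- rt$diff_names
  for (i in rt$diff_names) {
    r <- matrix(0, rt$grid$N_x, rt$grid$N_y)
    for (j in names(cfg$diffusion[[i]])) {
      Dfield <- .as_field(eval_expr(cfg$diffusion[[i]][[j]], env), rt$grid)
      Dpad <- pad_with_ghosts(Dfield, .mirror_wrap_bc(cfg$bcs[[j]]), rt$grid, t, env)
      Upad <- if (exists(j, envir = pads, inherits = FALSE)) get(j, envir = pads) else NULL
      if (is.null(Upad)) {
        Upad <- pad_with_ghosts(get(j, envir = env), cfg$bcs[[j]], rt$grid, t, env)
        assign(j, Upad, envir = pads)
      }
      r <- r + div_D_grad(Dpad, Upad, rt$grid, rt$mask)
    }
    f <- cfg$kinetics[[i]]
    if (!is.null(f)) {
      .ensure_tokens(f, env, rt, pads, t)
      r <- r + .as_field(eval_expr(f, env), rt$grid)
    }
    r[rt$zero_rhs] <- 0
    if (!is.null(rt$pin[[i]])) r[rt$pin[[i]]$mask] <- 0
    out[[i]] <- r
  }
  attr(out, "fields") <- fields
  out
}

# Diffusivities are extended by mirroring on non-periodic edges and wrapping
# on periodic ones: reuse the species' BC kinds with data stripped.
.mirror_wrap_bc <- function(bc) {
  lapply(bc, function(b)
    if (b$kind == "periodic") list(kind = "periodic", data = NULL)
    else list(kind = "dirichlet", data = NULL))  # "dirichlet" pads as plain mirror
}

# Pin Dirichlet boundary-adjacent nodes to their data values at time t.
.apply_pins <- function(fields, rt, t) {
  if (length(rt$pin) == 0L) return(fields)
  env <- .make_env(fields, rt, t)
  grid <- rt$grid; nx <- grid$N_x; ny <- grid$N_y
  for (nm in names(rt$pin)) {
    for (ed in rt$pin[[nm]]$edges) {
      data <- rt$cfg$bcs[[nm]][[ed]]$data
      val <- if (is.null(data)) matrix(0, nx, ny) else .bc_data_field(data, env, grid)
      F <- fields[[nm]]
      switch(ed,
             left = { F[1L, ] <- val[1L, ] }, right = { F[nx, ] <- val[nx, ] },
             bottom = { F[, 1L] <- val[, 1L] }, top = { F[, ny] <- val[, ny] })
      fields[[nm]] <- F
    }
  }
  fields
}
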