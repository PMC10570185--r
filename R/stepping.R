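# Explicit fixed-step time integration of the method-of-lines system, plus
# the run loop: initial conditions, brush events, frame capture, checkpoints,
# scheme schedules and blow-up detection.

#' Initialise the field state from a configuration
#'
#' Evaluates the initial-condition expressions at the cell-centre nodes
#' (missing entries are zero), computes the algebraic species, and pins
#' Dirichlet nodes at `t = 0`. The noise generators `rand()` / `randn()`
#' available in initial conditions draw grid-shaped uniform(0,1) / standard
#' normal fields from a generator seeded with `cfg$seed`, so initial data are
#' reproducible from the configuration alone.
#'
#' @param cfg a [pde_config()] or [compile_config()] runtime.
#' @return object of class `pde_state`: named list `fields` of grid-shaped
#'   matrices, model time `t`, and `step_index`.
#' @export
pde_init <- function(cfg) {
  rt <- if (inherits(cfg, "pde_runtime")) cfg else compile_config(cfg)
  cfg <- rt$cfg
  grid <- rt$grid
  nx <- grid$N_x; ny <- grid$N_y
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  funcs <- new.env(parent = rt$funcs)
  funcs$rand <- function() matrix(stats::runif(nx * ny), nx, ny)
  funcs$randn <- function() matrix(stats::rnorm(nx * ny), nx, ny)
  base <- list(x = grid$X)
  if (grid$dimension == 2L) base$y <- grid$Y
  base <- c(base, cfg$params)
  env <- list2env(base, parent = funcs)
  fields <- list()
  for (nm in .differential_names(cfg)) {
    e <- cfg$initial[[nm]]
    fields[[nm]] <- if (is.null(e)) matrix(0, nx, ny)
                    else .as_field(eval_expr(e, env), grid)
  }
  for (nm in .algebraic_names(cfg)) fields[[nm]] <- matrix(0, nx, ny)
  state <- structure(list(fields = fields, t = 0, step_index = 0L),
                     class = "pde_state")
  state$fields <- .apply_pins(state$fields, rt, 0)
  state$fields <- .refresh_algebraic(state$fields, rt, 0)
  state
}

# Recompute algebraic species for a plain field set (outside assemble_rhs).
.refresh_algebraic <- function(fields, rt, t) {
  if (length(rt$alg_order) == 0L) return(fields)
  env <- .make_env(fields, rt, t)
  pads <- new.env(parent = emptyenv())
  .update_algebraic(fields, env, rt, pads, t)
}

#' Create a timestepper
#'
#' @param scheme one of `"forward_euler"`, `"adams_bashforth2"`, `"midpoint"`,
#'   `"rk4"`.
#' @return environment of class `pde_stepper` carrying the scheme id and the
#'   previous right-hand side (two-step Adams-Bashforth only). The history is
#'   cleared whenever `dt` changes or the stepper is recreated at a scheme
#'   switch.
#' @export
make_stepper <- function(scheme = "forward_euler") {
  if (!(scheme %in% .schemes))
    stop(sprintf("unknown scheme '%s' (known: %s)", scheme,
                 paste(.schemes, collapse = ", ")), call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$scheme <- scheme
  st$prev_rhs <- NULL
  st$prev_dt <- NULL
  class(st) <- "pde_stepper"
  st
}

.advance_fields <- function(fields, rhs, dt, diff_names) {
  for (nm in diff_names) fields[[nm]] <- fields[[nm]] + dt * rhs[[nm]]
  fields
}

# Weighted combination used by RK4: fields + dt * sum(w_k * k_k).
.advance_combo <- function(fields, ks, ws, dt, diff_names) {
  for (nm in diff_names) {
    acc <- ws[[1L]] * ks[[1L]][[nm]]
    for (k in seq_along(ks)[-1L]) acc <- acc + ws[[k]] * ks[[k]][[nm]]
    fields[[nm]] <- fields[[nm]] + dt * acc
  }
  fields
}

#' Advance the state by one timestep
#'
#' Forward Euler: `u <- u + dt * rhs(u, t)`. Midpoint (modified Euler): full
#' step with the right-hand side evaluated at the half-step Euler predictor.
#' Two-step Adams-Bashforth: `u <- u + dt * (3/2 rhs_n - 1/2 rhs_{n-1})`, the
#' first step delegated to midpoint to preserve second order. RK4: the
#' classical four-stage tableau. Algebraic species are recomputed at every
#' stage evaluation and after the final update; Dirichlet nodes are re-pinned
#' at each stage time; `t` and `step_index` advance.
#'
#' @param state a `pde_state`.
#' @param cfg a [pde_config()] or [compile_config()] runtime.
#' @param stepper a [make_stepper()] object (created from the config's scheme
#'   if omitted).
#' @param dt timestep (defaults to the config's).
#' @return the advanced `pde_state`. Blow-up is *not* checked here; callers
#'   use [detect_blowup()].
#' @export
pde_step <- function(state, cfg, stepper = NULL, dt = NULL) {
  rt <- if (inherits(cfg, "pde_runtime")) cfg else compile_config(cfg)
  if (is.null(dt)) dt <- rt$cfg$numerics$dt
  if (is.null(stepper)) stepper <- make_stepper(rt$cfg$numerics$schedule[[1L]]$scheme)
  if (!is.null(stepper$prev_dt) && !identical(stepper$prev_dt, dt)) {
    stepper$prev_rhs <- NULL   # history invalid after a dt change
  }
  dn <- rt$diff_names
  t0 <- state$t
  f0 <- state$fields
  rhs_of <- function(fields, t) {
    s <- list(fields = fields, t = t)
    r <- assemble_rhs(s, rt, t)
    list(r = r, fields = attr(r, "fields"))
  }
  stage <- function(base_fields, rhs, h, t_stage) {
    f <- .advance_fields(base_fields, rhs, h, dn)
    .apply_pins(f, rt, t_stage)
  }

  k1 <- rhs_of(f0, t0)
  f0 <- k1$fields   # algebraic species refreshed

  fn <- switch(stepper$scheme,
    forward_euler = .advance_fields(f0, k1$r, dt, dn),
    midpoint = {
      fh <- stage(f0, k1$r, dt / 2, t0 + dt / 2)
      k2 <- rhs_of(fh, t0 + dt / 2)
      .advance_fields(f0, k2$r, dt, dn)
    },
    adams_bashforth2 = {
      if (is.null(stepper$prev_rhs)) {
        fh <- stage(f0, k1$r, dt / 2, t0 + dt / 2)
        k2 <- rhs_of(fh, t0 + dt / 2)
        .advance_fields(f0, k2$r, dt, dn)
      } else {
        .advance_combo(f0, list(k1$r, stepper$prev_rhs), c(1.5, -0.5), dt, dn)
      }
    },
    rk4 = {
      f2 <- stage(f0, k1$r, dt / 2, t0 + dt / 2)
      k2 <- rhs_of(f2, t0 + dt / 2)
      f3 <- stage(f0, k2$r, dt / 2, t0 + dt / 2)
      k3 <- rhs_of(f3, t0 + dt / 2)
      f4 <- stage(f0, k3$r, dt, t0 + dt)
      k4 <- rhs_of(f4, t0 + dt)
      .advance_combo(f0, list(k1$r, k2$r, k3$r, k4$r),
                     c(1, 2, 2, 1) / 6, dt, dn)
    },
    stop(sprintf("unknown scheme '%s'", stepper$scheme), call. = FALSE))

  if (stepper$scheme == "adams_bashforth2") {
    stepper$prev_rhs <- k1$r
    stepper$prev_dt <- dt
  }
  t1 <- t0 + dt
  fn <- .apply_pins(fn, rt, t1)
  fn <- .refresh_algebraic(fn, rt, t1)
  structure(list(fields = fn, t = t1, step_index = state$step_index + 1L),
            class = "pde_state")
}

#' Detect numerical blow-up
#'
#' @param state a `pde_state`.
#' @return `TRUE` iff any species field contains a non-finite value. The run
#'   loop converts this into a "solution blew up at t = ..." error.
#' @export
detect_blowup <- function(state) {
  for (F in state$fields) if (anyNA(F) || !all(is.finite(F))) return(TRUE)
  FALSE
}

#' Apply a brush event to the state
#'
#' Mirrors interactive painting: a `disc` sets (mode `"set"`) or adds (mode
#' `"add"`) `value` at all nodes within `radius` of `centre`; a `gaussian`
#' adds `value * exp(-r^2 / (2 radius^2))`.
#'
#' @param state a `pde_state`.
#' @param ev `list(species=, shape= "disc"|"gaussian", centre = c(x, y),
#'   radius=, value=, mode = "set"|"add", time=)` (`time` is used by the run
#'   loop, not here).
#' @param cfg a [pde_config()] or runtime (for the grid geometry).
#' @return the modified `pde_state` (algebraic species refreshed).
#' @export
apply_brush <- function(state, ev, cfg) {
  rt <- if (inherits(cfg, "pde_runtime")) cfg else compile_config(cfg)
  if (!(ev$species %in% names(state$fields)))
    stop(sprintf("brush: unknown species '%s'", ev$species), call. = FALSE)
  grid <- rt$grid
  cx <- ev$centre[[1L]]
  r2 <- (grid$X - cx)^2
  if (grid$dimension == 2L) r2 <- r2 + (grid$Y - ev$centre[[2L]])^2
  F <- state$fields[[ev$species]]
  shape <- ev$shape %||% "disc"
  mode <- ev$mode %||% "set"
  if (shape == "disc") {
    idx <- r2 <= ev$radius^2
    if (mode == "set") F[idx] <- ev$value else F[idx] <- F[idx] + ev$value
  } else if (shape == "gaussian") {
    F <- F + ev$value * exp(-r2 / (2 * ev$radius^2))
  } else stop(sprintf("brush: unknown shape '%s'", shape), call. = FALSE)
  state$fields[[ev$species]] <- F
  state$fields <- .refresh_algebraic(state$fields, rt, state$t)
  state
}

# Scheme in force at model time t under the config's schedule.
.scheme_at <- function(schedule, t) {
  sch <- schedule[[1L]]$scheme
  for (seg in schedule) if (t >= seg$t - 1e-12) sch <- seg$scheme
  sch
}

#' Run a simulation
#'
#' Orchestrates the full run: initial conditions (or a supplied/checkpointed
#' state), stepping with the scheduled scheme(s), brush events at their model
#' times, frame capture every `steps_per_frame` steps, checkpoints, and
#' blow-up detection. Runs are deterministic given the configuration (and its
#' seed): re-running, or restoring a checkpoint and continuing, reproduces the
#' trajectory bit-identically for the single-history schemes.
#'
#' A stability advisory (explicit-diffusion heuristic `dt <= h^2 / (2 d
#' max|D|)` in `d` dimensions) is emitted as a message when violated; it is
#' guidance, never enforcement.
#'
#' @param cfg a [pde_config()] or [compile_config()] runtime.
#' @param t_end model time to integrate to (`>= state$t`); `t_end = 0` returns
#'   the initial state after 0 steps.
#' @param init_state optional `pde_state` to continue from (e.g. a
#'   checkpoint's) instead of evaluating initial conditions.
#' @param checkpoint_times numeric vector of model times at which to store
#'   full state copies (tagged with the config hash).
#' @param capture_frames capture field snapshots every `steps_per_frame`
#'   steps (the initial state is always frame 1).
#' @param on_blowup `"error"` (default) to stop with a condition of class
#'   `gridpde_blowup`, or `"return"` to return the partial result with
#'   `$blowup` set.
#' @param quiet suppress the stability advisory.
#' @return object of class `pde_run`: `state` (final), `frames` (list of
#'   `list(t, fields)`), `checkpoints`, `events` (character log), `cfg`,
#'   `blowup` (`NULL` or `list(t, step)`).
#' @export
pde_run <- function(cfg, t_end, init_state = NULL, checkpoint_times = numeric(0),
                    capture_frames = TRUE, on_blowup = c("error", "return"),
                    quiet = FALSE) {
  on_blowup <- match.arg(on_blowup)
  rt <- if (inherits(cfg, "pde_runtime")) cfg else compile_config(cfg)
  cfg <- rt$cfg
  dt <- cfg$numerics$dt
  spf <- max(1L, cfg$numerics$steps_per_frame)
  state <- if (is.null(init_state)) pde_init(rt) else init_state
  events <- character(0)
  if (!quiet) {
    adv <- .stability_advisory(rt, state)
    if (!is.null(adv)) { message(adv); events <- c(events, adv) }
  }
  frames <- if (capture_frames) list(list(t = state$t, fields = state$fields)) else list()
  checkpoints <- list()
  cp_pending <- sort(checkpoint_times)
  brush_pending <- cfg$brush_events
  if (length(brush_pending))
    brush_pending <- brush_pending[order(vapply(brush_pending, function(e) e$time, 0))]
  scheme <- .scheme_at(cfg$numerics$schedule, state$t)
  stepper <- make_stepper(scheme)
  hash <- config_hash(cfg)
  blowup <- NULL
  n_steps <- max(0L, as.integer(ceiling((t_end - state$t) / dt - 1e-9)))

  take_checkpoints <- function(state) {
    while (length(cp_pending) && state$t >= cp_pending[[1L]] - 1e-12) {
      checkpoints[[length(checkpoints) + 1L]] <<-
        list(t = state$t, state = state, config_hash = hash)
      cp_pending <<- cp_pending[-1L]
    }
  }
  take_checkpoints(state)

  for (i in seq_len(n_steps)) {
    while (length(brush_pending) && state$t >= brush_pending[[1L]]$time - 1e-12) {
      ev <- brush_pending[[1L]]
      state <- apply_brush(state, ev, rt)
      events <- c(events, sprintf("brush on '%s' at t=%g", ev$species, state$t))
      brush_pending <- brush_pending[-1L]
    }
    sch <- .scheme_at(cfg$numerics$schedule, state$t)
    if (!identical(sch, scheme)) {
      scheme <- sch
      stepper <- make_stepper(scheme)
      events <- c(events, sprintf("scheme switch to %s at t=%g", scheme, state$t))
    }
    state <- pde_step(state, rt, stepper, dt)
    if (detect_blowup(state)) {
      blowup <- list(t = state$t, step = state$step_index)
      events <- c(events, sprintf("solution blew up at t=%g (step %d)",
                                  state$t, state$step_index))
      break
    }
    if (capture_frames && (state$step_index %% spf == 0L || i == n_steps))
      frames[[length(frames) + 1L]] <- list(t = state$t, fields = state$fields)
    take_checkpoints(state)
  }

  res <- structure(list(state = state, frames = frames, checkpoints = checkpoints,
                        events = events, cfg = cfg, blowup = blowup),
                   class = "pde_run")
  if (!is.null(blowup) && on_blowup == "error") {
    cond <- structure(class = c("gridpde_blowup", "error", "condition"),
                      list(message = sprintf("solution blew up at t = %g (step %d)",
                                             blowup$t, blowup$step),
                           call = NULL, result = res))
    stop(cond)
  }
  res
}

# Heuristic explicit-stability advisory for the diffusion part.
.stability_advisory <- function(rt, state) {
  cfg <- rt$cfg
  if (length(cfg$diffusion) == 0L) return(NULL)
  env <- .make_env(state$fields, rt, state$t)
  maxD <- 0
  for (i in names(cfg$diffusion)) for (j in names(cfg$diffusion[[i]])) {
    v <- tryCatch(eval_expr(cfg$diffusion[[i]][[j]], env), error = function(e) NULL)
    if (!is.null(v) && any(is.finite(v))) maxD <- max(maxD, max(abs(v[is.finite(v)])))
  }
  if (maxD == 0) return(NULL)
  d <- rt$grid$dimension
  h <- min(rt$grid$dx_eff, if (d == 2L) rt$grid$dy_eff else Inf)
  dt_max <- h^2 / (2 * d * maxD)
  if (cfg$numerics$dt > dt_max)
    sprintf("stability advisory: dt = %g exceeds the explicit diffusion heuristic %g = h^2/(%d max|D|)",
            cfg$numerics$dt, dt_max, 2L * d)
  else NULL
}

#' @export
print.pde_state <- function(x, ...) {
  cat(sprintf("<pde_state at t = %g (step %d): %s>\n", x$t, x$step_index,
              paste(sprintf("%s[%dx%d]", names(x$fields),
                            vapply(x$fields, nrow, 1L),
                            vapply(x$fields, ncol, 1L)), collapse = ", ")))
  invisible(x)
}

#' @export
print.pde_run <- function(x, ...) {
  cat(sprintf("<pde_run: t = %g, %d steps, %d frames, %d checkpoints%s>\n",
              x$state$t, x$state$step_index, length(x$frames), length(x$checkpoints),
              if (!is.null(x$blowup)) sprintf(", BLEW UP at t=%g", x$blowup$t) else ""))
  invisible(x)
}

#' @export
summary.pde_run <- function(object, ...) {
  cat(sprintf("Simulation run to t = %g in %d steps\n",
              object$state$t, object$state$step_index))
  for (nm in names(object$state$fields)) {
    F <- object$state$fields[[nm]]
    cat(sprintf("  %s: range [%g, %g], mean %g\n", nm, min(F), max(F), mean(F)))
  }
  if (length(object$events)) cat("events:\n", paste(" -", object$events, collapse = "\n"), "\n")
  invisible(object)
}

#' @export
plot.pde_run <- function(x, view = NULL, frame = NULL, ...) {
  st <- if (is.null(frame)) x$state
        else structure(list(fields = x$frames[[frame]]$fields,
                            t = x$frames[[frame]]$t, step_index = NA_integer_),
                       class = "pde_state")
  v <- if (is.null(view)) x$cfg$views[[1L]]
       else list(name = view, expression = .as_expr(view, "view"),
                 colormap = "viridis", scaling = "adaptive", colorbar = FALSE)
  field <- evaluate_view(st, v, x$cfg)
  grid <- build_grid(x$cfg$domain, x$cfg$numerics$dx)
  if (grid$dimension == 1L) {
    graphics::plot(grid$X[, 1L], field[, 1L], type = "l",
                   xlab = "x", ylab = v$name,
                   main = sprintf("t = %g", st$t), ...)
  } else {
    graphics::image(x = grid$X[, 1L], y = grid$Y[1L, ], z = field,
                    xlab = "x", ylab = "y", main = sprintf("%s, t = %g", v$name, st$t),
                    col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...)
  }
  invisible(x)
}
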