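.schemes <- c("forward_euler", "adams_bashforth2", "midpoint", "rk4")
.bc_kinds <- c("periodic", "dirichlet", "neumann", "robin")

# Normalise a boundary-condition entry into list(kind, data = pde_expr|NULL).
.norm_bc <- function(x, field) {
  if (is.character(x) && length(x) == 1L) x <- list(kind = x)
  if (!is.list(x) || is.null(x$kind))
    stop(sprintf("%s: boundary condition must be a kind string or list(kind=, data=)", field),
         call. = FALSE)
  data <- if (!is.null(x$data)) .as_expr(x$data, field) else NULL
  list(kind = x$kind, data = data)
}

.edges_for <- function(dimension) {
  if (dimension == 1L) c("left", "right") else c("left", "right", "top", "bottom")
}

#' Declare a complete PDE simulation
#'
#' Builds the declarative description of one simulation: the coupled system
#' \deqn{\partial u_i/\partial t = \sum_j \nabla\cdot(D_{ij}\nabla u_j) + f_i}
#' for the differential species, explicit assignments for algebraic species,
#' the rectangular (possibly indicator-masked) domain, per-species/per-edge
#' boundary conditions, numerics, views and brush events. All coefficient
#' entries are expression strings over species values, coordinates `x`/`y`,
#' time `t`, parameters, and the image functions `I_S(x,y)` / `I_T(x,y)`;
#' kinetics and views may additionally use the spatial-derivative tokens
#' (`u_x`, `u_yy`, `u_x_b`, ...). Mixed spatial derivatives are not supported.
#'
#' The returned object is *not* guaranteed runnable: call
#' [validate_config()] to obtain diagnostics (it returns an empty list iff the
#' configuration is well-posed).
#'
#' @param species character vector of species names in positional order
#'   (defaults follow `u, v, w, q`).
#' @param algebraic named list mapping a subset of `species` to their defining
#'   expressions (these species carry no time derivative).
#' @param kinetics named list of reaction expressions `f_i`, one per
#'   differential species (missing entries default to `0`).
#' @param diffusion nested named list: `diffusion[[i]][[j]]` is the expression
#'   for the diffusivity \eqn{D_{ij}} multiplying \eqn{\nabla u_j} in the
#'   equation for species `i`. Absent entries are zero. Diffusivity
#'   expressions must not contain derivative tokens.
#' @param bcs named list per species; each entry either a single kind string
#'   applied to all edges (`"periodic"`, `"neumann"`, `"dirichlet"`,
#'   `"robin"`), or a per-edge list with entries `left`/`right` (and
#'   `top`/`bottom` in 2D), each a kind string or `list(kind=, data=)`. `data`
#'   is the boundary value for Dirichlet and the outward normal derivative
#'   for Neumann/Robin (Robin data may reference the species itself).
#'   Default: homogeneous Neumann everywhere.
#' @param initial named list of initial-condition expressions per differential
#'   species over `x`, `y`, parameters, image functions and the seeded noise
#'   generators `rand()`/`randn()`. Missing entries default to `0`.
#' @param dimension 1 or 2.
#' @param L_x,L_y domain side lengths (model units); `L_y` ignored in 1D.
#' @param indicator optional expression over `x`, `y`, parameters; nodes with
#'   value > 0 are simulated (absent = full rectangle).
#' @param dx requested spatial step; the grid uses `floor(L/dx)` nodes per
#'   axis (single step size for both axes).
#' @param dt timestep.
#' @param scheme one of `"forward_euler"`, `"adams_bashforth2"`, `"midpoint"`,
#'   `"rk4"`; or a schedule `list(list(t = 0, scheme = ...), ...)` switching
#'   scheme at the given model times.
#' @param steps_per_frame frame-capture cadence for [pde_run()].
#' @param params named numeric vector/list of model parameters. Optional
#'   slider metadata may be attached as `attr(params, "ranges")`; it is inert.
#' @param views list of view specifications (see [evaluate_view()]); default a
#'   single identity view of the first species.
#' @param brush_events list of brush events (see [apply_brush()]), each
#'   `list(time=, species=, shape=, centre=, radius=, value=, mode=)`.
#' @param images named list with optional `I_S` and/or `I_T` file paths (PNG).
#' @param seed integer seed controlling `rand()`/`randn()` in initial
#'   conditions.
#' @return object of class `pde_config`.
#' @examples
#' cfg <- pde_config(species = "u", diffusion = list(u = list(u = "1")),
#'                   initial = list(u = "cos(pi*x)"),
#'                   dimension = 1, L_x = 1, dx = 0.01, dt = 2e-5)
#' validate_config(cfg)   # list()
#' @export
pde_config <- function(species = c("u", "v"),
                       algebraic = list(),
                       kinetics = list(),
                       diffusion = list(),
                       bcs = list(),
                       initial = list(),
                       dimension = 2,
                       L_x = 1, L_y = 1,
                       indicator = NULL,
                       dx = 0.01, dt = 1e-5,
                       scheme = "forward_euler",
                       steps_per_frame = 100L,
                       params = numeric(0),
                       views = NULL,
                       brush_events = list(),
                       images = list(),
                       seed = 1L) {
  dimension <- as.integer(dimension)
  species <- as.character(species)
  sp_defs <- lapply(species, function(nm) {
    if (nm %in% names(algebraic))
      list(name = nm, role = "algebraic",
           algebraic_rhs = .as_expr(algebraic[[nm]], paste0("algebraic$", nm)))
    else
      list(name = nm, role = "differential", algebraic_rhs = NULL)
  })
  names(sp_defs) <- species

  diff_parsed <- lapply(diffusion, function(row)
    lapply(row, .as_expr, field = "diffusion"))
  kin_parsed <- lapply(kinetics, .as_expr, field = "kinetics")
  init_parsed <- lapply(initial, .as_expr, field = "initial")

  edges <- .edges_for(dimension)
  bcs_full <- lapply(species, function(nm) {
    user <- bcs[[nm]]
    if (is.null(user)) user <- "neumann"
    if (is.character(user) && length(user) == 1L) {
      per <- stats::setNames(rep(list(list(kind = user, data = NULL)), length(edges)), edges)
    } else {
      per <- stats::setNames(vector("list", length(edges)), edges)
      for (ed in edges) {
        per[[ed]] <- if (is.null(user[[ed]])) list(kind = "neumann", data = NULL)
                     else .norm_bc(user[[ed]], sprintf("bcs$%s$%s", nm, ed))
      }
    }
    per
  })
  names(bcs_full) <- species

  if (is.null(views)) {
    views <- list(list(name = species[[1L]], expression = species[[1L]],
                       colormap = "viridis", scaling = "adaptive", colorbar = TRUE))
  }
  views <- lapply(views, function(v) {
    list(name = v$name %||% v$expression,
         expression = .as_expr(v$expression, "view"),
         colormap = v$colormap %||% "viridis",
         scaling = v$scaling %||% "adaptive",
         colorbar = isTRUE(v$colorbar))
  })

  schedule <- if (is.character(scheme)) list(list(t = 0, scheme = scheme)) else scheme

  cfg <- structure(list(
    species = sp_defs,
    diffusion = diff_parsed,
    kinetics = kin_parsed,
    bcs = bcs_full,
    domain = list(dimension = dimension, L_x = L_x,
                  L_y = if (dimension == 2L) L_y else NULL,
                  indicator = if (!is.null(indicator)) .as_expr(indicator, "indicator") else NULL),
    numerics = list(dx = dx, dt = dt, schedule = schedule,
                    steps_per_frame = as.integer(steps_per_frame)),
    params = as.list(params),
    initial = init_parsed,
    views = views,
    brush_events = brush_events,
    images = images,
    seed = as.integer(seed)
  ), class = "pde_config")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symbol sets per expression context --------------------------------------

.coord_syms <- function(cfg) {
  if (cfg$domain$dimension == 2L) c("x", "y", "t") else c("x", "t")
}

.species_names <- function(cfg) names(cfg$species)

.differential_names <- function(cfg)
  names(cfg$species)[vapply(cfg$species, function(s) s$role == "differential", TRUE)]

.algebraic_names <- function(cfg)
  names(cfg$species)[vapply(cfg$species, function(s) s$role == "algebraic", TRUE)]

.allowed_symbols <- function(cfg, context = c("kinetics", "diffusion", "bc",
                                              "indicator", "initial", "view")) {
  context <- match.arg(context)
  sp <- .species_names(cfg)
  pars <- names(cfg$params)
  base <- c(.coord_syms(cfg), pars)
  tokens <- .derivative_tokens(sp)
  if (cfg$domain$dimension == 1L) tokens <- tokens[!grepl("_y(|_b|_f|y)$", tokens)]
  switch(context,
    kinetics  = c(base, sp, tokens),
    view      = c(base, sp, tokens),
    diffusion = c(base, sp),
    bc        = c(base, sp),
    indicator = c(setdiff(base, "t"), character(0)),
    initial   = c(setdiff(base, "t"))
  )
}

# Check one expression against a context; returns character diagnostics.
.check_expr <- function(e, cfg, context, where) {
  if (is.null(e)) return(character(0))
  if (is.null(e$ast))
    return(sprintf("%s: %s", where, e$error))
  out <- character(0)
  allowed <- .allowed_symbols(cfg, context)
  sp <- .species_names(cfg)
  for (s in e$syms) {
    tok <- .split_token(s, sp)
    if (!is.null(tok) && isTRUE(tok$mixed)) {
      out <- c(out, sprintf(
        "%s: symbol '%s' is a mixed spatial derivative; mixed derivatives are not supported",
        where, s))
    } else if (!(s %in% allowed)) {
      if (!is.null(tok) && context %in% c("diffusion", "bc", "indicator", "initial")) {
        out <- c(out, sprintf(
          "%s: derivative token '%s' is not permitted in %s expressions", where, s, context))
      } else {
        out <- c(out, sprintf("%s: unresolved symbol '%s'", where, s))
      }
    }
  }
  if (context %in% c("indicator", "initial") && "t" %in% e$syms)
    out <- c(out, sprintf("%s: 't' is not available in %s expressions", where, context))
  bad_noise <- intersect(c("rand", "randn"), all.names(e$ast))
  if (length(bad_noise) && context != "initial")
    out <- c(out, sprintf("%s: %s() is only available in initial conditions",
                          where, bad_noise[[1L]]))
  out
}

#' Validate a simulation configuration
#'
#' Total validation: never throws on a structurally complete configuration,
#' returning a (possibly empty) list of human-readable diagnostics instead.
#' An empty result means the configuration is runnable.
#'
#' Checks include: at least one differential species and unique names;
#' algebraic definitions present exactly for algebraic species and free of
#' self-reference cycles; all expression symbols resolvable in their context;
#' no mixed-derivative tokens anywhere and no derivative tokens inside
#' diffusivities; periodic boundary conditions paired across each axis;
#' positive domain lengths and steps; a known timestepping scheme; enough
#' grid nodes for the stencils; brush centres inside the domain.
#'
#' @param cfg a [pde_config()].
#' @return list of character diagnostics; empty iff runnable.
#' @export
validate_config <- function(cfg) {
  d <- character(0)
  note <- function(...) d <<- c(d, sprintf(...))
  sp <- .species_names(cfg)

  if (anyDuplicated(sp)) note("species: names must be unique")
  if (length(.differential_names(cfg)) == 0L)
    note("species: at least one species must be differential")
  bad_names <- sp[!grepl("^[A-Za-z][A-Za-z0-9]*$", sp)]
  for (b in bad_names) note("species '%s': name must be a plain identifier", b)
  clash <- intersect(sp, c("x", "y", "t", "pi", names(cfg$params)))
  for (b in clash) note("species '%s': name collides with a coordinate/parameter", b)

  for (nm in .algebraic_names(cfg))
    d <- c(d, .check_expr(cfg$species[[nm]]$algebraic_rhs, cfg, "kinetics",
                          sprintf("algebraic '%s'", nm)))
  ord <- tryCatch(algebraic_order(cfg), error = function(e) e)
  if (inherits(ord, "error")) note("algebraic species: %s", conditionMessage(ord))

  for (nm in names(cfg$kinetics)) {
    if (!(nm %in% .differential_names(cfg)))
      note("kinetics '%s': not a differential species", nm)
    d <- c(d, .check_expr(cfg$kinetics[[nm]], cfg, "kinetics",
                          sprintf("kinetics '%s'", nm)))
  }
  for (i in names(cfg$diffusion)) {
    if (!(i %in% sp)) note("diffusion row '%s': unknown species", i)
    for (j in names(cfg$diffusion[[i]])) {
      if (!(j %in% sp)) note("diffusion['%s']['%s']: unknown species", i, j)
      d <- c(d, .check_expr(cfg$diffusion[[i]][[j]], cfg, "diffusion",
                            sprintf("diffusion['%s']['%s']", i, j)))
    }
    if (!(i %in% .differential_names(cfg)) && i %in% sp)
      note("diffusion row '%s': algebraic species cannot have diffusion terms", i)
  }
  for (nm in names(cfg$initial)) {
    d <- c(d, .check_expr(cfg$initial[[nm]], cfg, "initial",
                          sprintf("initial '%s'", nm)))
  }
  d <- c(d, .check_expr(cfg$domain$indicator, cfg, "indicator", "indicator"))
  for (v in cfg$views)
    d <- c(d, .check_expr(v$expression, cfg, "view", sprintf("view '%s'", v$name)))

  edges <- .edges_for(cfg$domain$dimension)
  axis_pairs <- list(c("left", "right"), c("top", "bottom"))
  for (nm in sp) {
    per <- cfg$bcs[[nm]]
    for (ed in edges) {
      b <- per[[ed]]
      if (!(b$kind %in% .bc_kinds)) {
        note("bcs$%s$%s: unknown kind '%s'", nm, ed, b$kind)
        next
      }
      if (b$kind %in% c("dirichlet", "robin") && is.null(b$data))
        note("bcs$%s$%s: kind '%s' requires a data expression", nm, ed, b$kind)
      d <- c(d, .check_expr(b$data, cfg, "bc", sprintf("bcs$%s$%s", nm, ed)))
    }
    for (pair in axis_pairs) {
      if (!all(pair %in% edges)) next
      k <- c(per[[pair[1L]]]$kind, per[[pair[2L]]]$kind)
      if (xor(k[1L] == "periodic", k[2L] == "periodic"))
        note("bcs$%s: periodic must be paired on the %s/%s axis", nm, pair[1L], pair[2L])
    }
  }

  dom <- cfg$domain
  if (!is.numeric(dom$L_x) || dom$L_x <= 0) note("domain: L_x must be > 0")
  if (dom$dimension == 2L && (!is.numeric(dom$L_y) || dom$L_y <= 0))
    note("domain: L_y must be > 0")
  if (!(dom$dimension %in% c(1L, 2L))) note("domain: dimension must be 1 or 2")
  num <- cfg$numerics
  if (!is.numeric(num$dx) || num$dx <= 0) note("numerics: dx must be > 0")
  if (!is.numeric(num$dt) || num$dt <= 0) note("numerics: dt must be > 0")
  Lmin <- if (dom$dimension == 2L) min(dom$L_x, dom$L_y) else dom$L_x
  if (is.numeric(num$dx) && num$dx > 0 && num$dx >= Lmin)
    note("numerics: dx must be smaller than the shortest domain side")
  for (seg in num$schedule) {
    if (is.null(seg$scheme) || !(seg$scheme %in% .schemes))
      note("numerics: unknown scheme '%s' (known: %s)",
           seg$scheme %||% "<missing>", paste(.schemes, collapse = ", "))
  }
  if (length(d) == 0L) {
    g <- tryCatch(build_grid(dom, num$dx), error = function(e) e)
    if (inherits(g, "error")) {
      note("grid: %s", conditionMessage(g))
    } else {
      if (g$N_x < 3L && .uses_axis_derivatives(cfg, "x"))
        note("grid: x axis has %d nodes; stencils need at least 3", g$N_x)
      if (dom$dimension == 2L && g$N_y < 3L && .uses_axis_derivatives(cfg, "y"))
        note("grid: y axis has %d nodes; y-derivative stencils need at least 3", g$N_y)
      if (!is.null(dom$indicator) && is.null(dom$indicator$error)) {
        m <- tryCatch(build_mask(dom$indicator, g, cfg$params), error = function(e) e)
        if (inherits(m, "error")) note("mask: %s", conditionMessage(m))
      }
      for (k in seq_along(cfg$brush_events)) {
        ev <- cfg$brush_events[[k]]
        if (!is.null(ev$species) && !(ev$species %in% sp))
          note("brush_events[[%d]]: unknown species '%s'", k, ev$species)
        cx <- ev$centre[[1L]]
        cy <- if (dom$dimension == 2L) ev$centre[[2L]] else 0
        if (cx < 0 || cx > dom$L_x ||
            (dom$dimension == 2L && (cy < 0 || cy > dom$L_y)))
          note("brush_events[[%d]]: centre outside the domain", k)
      }
    }
  }
  for (key in names(cfg$images)) {
    if (!(key %in% c("I_S", "I_T"))) note("images: unknown slot '%s'", key)
  }
  as.list(d)
}

# TRUE if the model takes derivatives along the given axis (diffusion acts on
# all axes of the domain; derivative tokens are per-axis).
.uses_axis_derivatives <- function(cfg, axis) {
  if (length(cfg$diffusion)) return(TRUE)
  sp <- .species_names(cfg)
  all_exprs <- c(cfg$kinetics,
                 lapply(cfg$species, function(s) s$algebraic_rhs))
  for (e in all_exprs) {
    if (is.null(e) || is.null(e$ast)) next
    for (s in e$syms) {
      tok <- .split_token(s, sp)
      if (!is.null(tok) && !isTRUE(tok$mixed) && startsWith(tok$suffix, axis))
        return(TRUE)
    }
  }
  FALSE
}

#' Topological order of algebraic species
#'
#' Algebraic species are recomputed from the differential fields before every
#' right-hand-side evaluation; this returns an order in which each algebraic
#' species depends only on differential species and earlier algebraic species.
#' Dependencies are detected through species-value symbols and derivative
#' tokens in the defining expressions.
#'
#' @param cfg a [pde_config()].
#' @return character vector of algebraic species names (possibly empty).
#' @export
algebraic_order <- function(cfg) {
  alg <- .algebraic_names(cfg)
  if (length(alg) == 0L) return(character(0))
  sp <- .species_names(cfg)
  deps <- lapply(alg, function(nm) {
    e <- cfg$species[[nm]]$algebraic_rhs
    if (is.null(e) || is.null(e$ast)) return(character(0))
    used <- character(0)
    for (s in e$syms) {
      if (s %in% alg) used <- c(used, s)
      tok <- .split_token(s, sp)
      if (!is.null(tok) && !isTRUE(tok$mixed) && tok$species %in% alg)
        used <- c(used, tok$species)
    }
    setdiff(unique(used), nm)  # self-reference caught below
  })
  names(deps) <- alg
  for (nm in alg) {
    e <- cfg$species[[nm]]$algebraic_rhs
    if (is.null(e) || is.null(e$ast)) next
    refs_self <- nm %in% e$syms ||
      any(vapply(e$syms, function(s) {
        tok <- .split_token(s, sp)
        !is.null(tok) && !isTRUE(tok$mixed) && identical(tok$species, nm)
      }, TRUE))
    if (refs_self)
      stop(sprintf("algebraic species '%s' references itself", nm), call. = FALSE)
  }
  ordered <- character(0)
  remaining <- alg
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm)
      all(deps[[nm]] %in% ordered), TRUE)]
    if (length(ready) == 0L)
      stop(sprintf("cycle among algebraic species: %s",
                   paste(remaining, collapse = " <-> ")), call. = FALSE)
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

#' @export
print.pde_config <- function(x, ...) {
  dn <- .differential_names(x); an <- .algebraic_names(x)
  cat("<pde_config>\n")
  cat(sprintf("  species: %s%s\n", paste(dn, collapse = ", "),
              if (length(an)) paste0(" | algebraic: ", paste(an, collapse = ", ")) else ""))
  dom <- x$domain
  cat(sprintf("  domain:  %dD, L_x = %g%s%s\n", dom$dimension, dom$L_x,
              if (dom$dimension == 2L) sprintf(", L_y = %g", dom$L_y) else "",
              if (!is.null(dom$indicator)) sprintf(", indicator: %s", dom$indicator$src) else ""))
  cat(sprintf("  numerics: dx = %g, dt = %g, scheme = %s\n",
              x$numerics$dx, x$numerics$dt,
              paste(vapply(x$numerics$schedule, `[[`, "", "scheme"), collapse = " -> ")))
  for (nm in dn) {
    f <- x$kinetics[[nm]]
    dstr <- names(x$diffusion[[nm]])
    cat(sprintf("  d%s/dt = %s%s\n", nm,
                if (length(dstr)) paste(sprintf("div(D[%s,%s] grad %s)", nm, dstr, dstr),
                                        collapse = " + ") else "",
                if (!is.null(f)) paste0(if (length(dstr)) " + " else "", f$src) else ""))
  }
  for (nm in an) cat(sprintf("  %s = %s\n", nm, x$species[[nm]]$algebraic_rhs$src))
  if (length(x$params))
    cat("  params: ", paste(sprintf("%s = %g", names(x$params),
                                    unlist(x$params)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
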