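# JSON (de)serialization of configurations and states. A serialized config is
# the unit of sharing: it captures the model, domain, numerics and views
# exactly (expression sources verbatim), but never runtime state, brush
# history (in the "share" profile) or image pixels -- only image paths.

.expr_or_null <- function(e) if (is.null(e)) NULL else e$src

#' Serialize a configuration to JSON
#'
#' @param cfg a [pde_config()].
#' @param path optional file to write; otherwise the JSON text is returned.
#' @param profile `"share"` (default; excludes brush events, matching the
#'   share-a-link semantics) or `"full"` (includes them).
#' @return JSON text (invisibly if `path` given).
#' @export
serialize_config <- function(cfg, path = NULL, profile = c("share", "full")) {
  profile <- match.arg(profile)
  doc <- list(
    format = "gridpde-config",
    version = 1L,
    species = lapply(cfg$species, function(s)
      list(name = s$name, role = s$role,
           algebraic_rhs = .expr_or_null(s$algebraic_rhs))),
    diffusion = lapply(cfg$diffusion, function(row) lapply(row, .expr_or_null)),
    kinetics = lapply(cfg$kinetics, .expr_or_null),
    bcs = lapply(cfg$bcs, function(per) lapply(per, function(b)
      list(kind = b$kind, data = .expr_or_null(b$data)))),
    domain = list(dimension = cfg$domain$dimension, L_x = cfg$domain$L_x,
                  L_y = cfg$domain$L_y,
                  indicator = .expr_or_null(cfg$domain$indicator)),
    numerics = cfg$numerics,
    params = cfg$params,
    initial = lapply(cfg$initial, .expr_or_null),
    views = lapply(cfg$views, function(v)
      list(name = v$name, expression = .expr_or_null(v$expression),
           colormap = v$colormap, scaling = v$scaling, colorbar = v$colorbar)),
    brush_events = if (profile == "full") cfg$brush_events else list(),
    images = cfg$images,
    seed = cfg$seed
  )
  names(doc$species) <- NULL
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null",
                          pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(as.character(txt))) }
  as.character(txt)
}

.known_keys <- list(
  top = c("format", "version", "species", "diffusion", "kinetics", "bcs",
          "domain", "numerics", "params", "initial", "views", "brush_events",
          "images", "seed"),
  species = c("name", "role", "algebraic_rhs"),
  bc = c("kind", "data"),
  domain = c("dimension", "L_x", "L_y", "indicator"),
  numerics = c("dx", "dt", "schedule", "steps_per_frame"),
  view = c("name", "expression", "colormap", "scaling", "colorbar"),
  brush = c("time", "species", "shape", "centre", "radius", "value", "mode"),
  schedule = c("t", "scheme")
)

.reject_unknown <- function(node, kind, path) {
  unknown <- setdiff(names(node), .known_keys[[kind]])
  if (length(unknown))
    stop(sprintf("unknown field '%s' at %s", unknown[[1L]], path), call. = FALSE)
}

#' Deserialize a configuration from JSON
#'
#' Inverse of [serialize_config()]: rebuilds the `pde_config`, re-parsing all
#' expression strings. Unknown fields anywhere in the document are rejected
#' with an error naming the offending path.
#'
#' @param doc JSON text, or a path to a JSON file.
#' @return a [pde_config()].
#' @export
deserialize_config <- function(doc) {
  if (length(doc) == 1L && !grepl("[{]", doc) && file.exists(doc))
    doc <- paste(readLines(doc, warn = FALSE), collapse = "\n")
  x <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  .reject_unknown(x, "top", "$")
  if (!identical(x$format, "gridpde-config"))
    stop("not a gridpde-config document (field 'format')", call. = FALSE)
  species <- vapply(x$species, function(s) s$name, "")
  algebraic <- list()
  for (s in x$species) {
    .reject_unknown(s, "species", sprintf("$.species[%s]", s$name))
    if (identical(s$role, "algebraic")) algebraic[[s$name]] <- s$algebraic_rhs
  }
  .reject_unknown(x$domain, "domain", "$.domain")
  .reject_unknown(x$numerics, "numerics", "$.numerics")
  for (seg in x$numerics$schedule)
    .reject_unknown(seg, "schedule", "$.numerics.schedule")
  bcs <- lapply(x$bcs, function(per) {
    lapply(per, function(b) {
      .reject_unknown(b, "bc", "$.bcs")
      list(kind = b$kind, data = b$data)
    })
  })
  views <- lapply(x$views, function(v) {
    .reject_unknown(v, "view", "$.views")
    v
  })
  for (ev in x$brush_events) .reject_unknown(ev, "brush", "$.brush_events")
  brush <- lapply(x$brush_events, function(ev) {
    ev$centre <- unlist(ev$centre); ev
  })
  pde_config(
    species = species,
    algebraic = algebraic,
    kinetics = x$kinetics,
    diffusion = x$diffusion,
    bcs = bcs,
    initial = x$initial,
    dimension = x$domain$dimension,
    L_x = x$domain$L_x,
    L_y = x$domain$L_y %||% 1,
    indicator = x$domain$indicator,
    dx = x$numerics$dx,
    dt = x$numerics$dt,
    scheme = lapply(x$numerics$schedule, function(s) list(t = s$t, scheme = s$scheme)),
    steps_per_frame = x$numerics$steps_per_frame,
    params = x$params,
    views = views,
    brush_events = brush,
    images = x$images,
    seed = x$seed
  )
}

#' Field-by-field configuration equality
#'
#' Compares two configurations as shared documents: species, expression
#' sources, boundary conditions, domain, numerics, parameters, views, brush
#' events, images and seed.
#'
#' @param a,b [pde_config()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
config_equal <- function(a, b) {
  identical(serialize_config(a, profile = "full"),
            serialize_config(b, profile = "full"))
}

#' Hash of a configuration
#'
#' MD5 of the canonical full-profile serialization; stored in checkpoints and
#' run manifests so outputs can be traced to the exact configuration.
#'
#' @param cfg a [pde_config()].
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(serialize_config(cfg, profile = "full"), f)
  unname(tools::md5sum(f))
}

#' Save / load a field state as a JSON named-array container
#'
#' States (including checkpoints) are stored as a JSON document holding each
#' species array with its dimensions at full double precision, the model
#' clock, the step index and the config hash.
#'
#' @param state a `pde_state`.
#' @param path output file.
#' @param cfg optional config whose hash to embed.
#' @return `path`, invisibly.
#' @export
save_state <- function(state, path, cfg = NULL) {
  doc <- list(
    format = "gridpde-state",
    t = state$t,
    step_index = state$step_index,
    config_hash = if (!is.null(cfg)) config_hash(cfg) else NULL,
    fields = lapply(state$fields, function(F)
      list(dim = dim(F), values = as.vector(F)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fields <- lapply(x$fields, function(f) matrix(f$values, f$dim[[1L]], f$dim[[2L]]))
  structure(list(fields = fields, t = x$t, step_index = as.integer(x$step_index)),
            class = "pde_state")
}
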