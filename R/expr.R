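# Function whitelist for the expression grammar. Arithmetic (+ - * / ^, unary
# minus, parentheses) is handled structurally; everything else must appear here.
.expr_functions <- c("sin", "cos", "tan", "exp", "log", "sqrt", "abs", "tanh",
                     "min", "max", "heaviside", "I_S", "I_T", "rand", "randn")

.expr_operators <- c("+", "-", "*", "/", "^", "(")

#' Unit step function with heaviside(0) = 1
#'
#' Used throughout expression evaluation, in particular for domain indicator
#' functions, where nodes with indicator value > 0 are simulated. The closed
#' convention at zero makes `heaviside(x - a)` include the locus `x = a`.
#'
#' @param x numeric vector or matrix.
#' @return numeric of the same shape, 1 where `x >= 0`, else 0.
#' @export
heaviside <- function(x) {
  r <- x
  r[] <- as.numeric(x >= 0)
  r
}

# Environment providing the callable functions of the grammar. Parent of every
# evaluation environment. min/max are elementwise over the grid (pmin/pmax).
.expr_funcs_env <- function() {
  e <- new.env(parent = baseenv())
  e$sin <- sin; e$cos <- cos; e$tan <- tan; e$exp <- exp; e$log <- log
  e$sqrt <- sqrt; e$abs <- abs; e$tanh <- tanh
  e$min <- function(...) Reduce(pmin, list(...))
  e$max <- function(...) Reduce(pmax, list(...))
  e$heaviside <- heaviside
  e$pi <- base::pi
  # I_S / I_T / rand / randn are rebound per-config; defaults error clearly.
  e$I_S <- function(x, y) stop("no image bound to I_S", call. = FALSE)
  e$I_T <- function(x, y) stop("no image bound to I_T", call. = FALSE)
  e$rand <- function() stop("rand() is only available in initial conditions", call. = FALSE)
  e$randn <- function() stop("randn() is only available in initial conditions", call. = FALSE)
  e
}

# Collect free symbols of an AST (excluding pi and function names in call
# position). Returns a character vector, possibly empty.
.ast_symbols <- function(ast) {
  syms <- character(0)
  walk <- function(node) {
    if (is.symbol(node)) {
      nm <- as.character(node)
      if (nm != "pi") syms[[length(syms) + 1L]] <<- nm
    } else if (is.call(node)) {
      args <- as.list(node)[-1L]
      for (a in args) walk(a)
    }
  }
  walk(ast)
  unique(syms)
}

# Validate AST structure against the grammar: literals, symbols, whitelisted
# calls, arithmetic operators. Returns NULL if fine, else a message.
.ast_check <- function(ast) {
  bad <- NULL
  walk <- function(node) {
    if (!is.null(bad)) return(invisible())
    if (is.numeric(node) || is.symbol(node)) return(invisible())
    if (is.call(node)) {
      head <- as.character(node[[1L]])
      args <- as.list(node)[-1L]
      if (head %in% .expr_operators) {
        # unary minus/plus arrive as calls with a single argument
      } else if (head %in% .expr_functions) {
        if (head %in% c("I_S", "I_T") && length(args) != 2L) {
          bad <<- sprintf("image function '%s' takes exactly two arguments (x, y)", head)
          return(invisible())
        }
        if (head %in% c("rand", "randn") && length(args) != 0L) {
          bad <<- sprintf("'%s' takes no arguments", head)
          return(invisible())
        }
      } else {
        bad <<- sprintf("unknown function '%s'", head)
        return(invisible())
      }
      for (a in args) walk(a)
    } else {
      bad <<- "unsupported syntax element"
    }
  }
  walk(ast)
  bad
}

#' Parse a model expression
#'
#' Parses the calculator-style expression text used for diffusivities,
#' kinetics, boundary data, indicator functions, initial conditions and views.
#' The grammar is infix arithmetic (`+ - * / ^`, with `^` right-associative),
#' the constant `pi`, the functions `sin, cos, tan, exp, log, sqrt, abs, tanh,
#' min, max, heaviside`, the image functions `I_S(x,y)`, `I_T(x,y)`, and the
#' seeded noise generators `rand()`, `randn()` (initial conditions only).
#' Spatial-derivative tokens are plain symbols named `<species>_x`, `_y`,
#' `_xx`, `_yy` (central differences) and `_x_b`, `_x_f`, `_y_b`, `_y_f`
#' (one-sided/upwind); mixed derivatives do not exist in the token set.
#'
#' @param src expression text, non-empty.
#' @param allowed character vector of permitted free symbols (species names,
#'   coordinates, parameters, derivative tokens). `NULL` skips symbol checks.
#' @return an object of class `pde_expr` (fields `src`, `ast`, `syms`).
#' @examples
#' e <- parse_expr("2^3", allowed = character(0))
#' eval_expr(e, list())            # 8
#' @export
parse_expr <- function(src, allowed = NULL) {
  stopifnot(is.character(src), length(src) == 1L, nzchar(trimws(src)))
  ast <- tryCatch(
    str2lang(src),
    error = function(e) stop(sprintf("syntax error in \"%s\": %s", src,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (is.character(ast) || is.logical(ast))
    stop(sprintf("syntax error in \"%s\": not a numeric expression", src), call. = FALSE)
  structural <- .ast_check(ast)
  if (!is.null(structural))
    stop(sprintf("invalid expression \"%s\": %s", src, structural), call. = FALSE)
  syms <- .ast_symbols(ast)
  if (!is.null(allowed)) {
    unknown <- setdiff(syms, allowed)
    if (length(unknown))
      stop(sprintf("unknown symbol '%s' in \"%s\"", unknown[[1L]], src), call. = FALSE)
  }
  structure(list(src = src, ast = ast, syms = syms), class = "pde_expr")
}

# Internal: parse leniently, capturing failure in the object so that
# validate_config() can report it as a diagnostic instead of throwing.
.parse_expr_soft <- function(src, field) {
  tryCatch(parse_expr(src), error = function(e)
    structure(list(src = src, ast = NULL, syms = character(0),
                   error = conditionMessage(e), field = field),
              class = "pde_expr"))
}

.as_expr <- function(x, field = "expression") {
  if (inherits(x, "pde_expr")) return(x)
  if (is.numeric(x) && length(x) == 1L) x <- format(x, digits = 17)
  if (!is.character(x) || length(x) != 1L)
    stop(sprintf("%s must be an expression string or a number", field), call. = FALSE)
  .parse_expr_soft(x, field)
}

#' Evaluate a parsed expression over a grid context
#'
#' Elementwise evaluation; scalars broadcast over the grid. Division by zero,
#' log of non-positive values and similar produce non-finite values that flow
#' through (blow-up detection downstream owns the user-facing error), never
#' exceptions.
#'
#' @param e a `pde_expr`.
#' @param ctx named list (or environment) binding the free symbols: species
#'   matrices, coordinate fields `x`/`y`, scalar `t`, parameters, derivative
#'   token fields.
#' @param funcs optionally, a prepared function environment (internal use,
#'   carries bound image samplers / noise generators).
#' @return matrix of the common grid shape, or a scalar if no grid-shaped
#'   symbol occurs.
#' @export
eval_expr <- function(e, ctx = list(), funcs = NULL) {
  stopifnot(inherits(e, "pde_expr"))
  if (is.null(e$ast))
    stop(sprintf("cannot evaluate invalid expression \"%s\": %s", e$src, e$error),
         call. = FALSE)
  if (is.null(funcs)) funcs <- .expr_funcs_env()
  env <- if (is.environment(ctx)) ctx else list2env(as.list(ctx), parent = funcs)
  suppressWarnings(eval(e$ast, envir = env))
}

#' @export
print.pde_expr <- function(x, ...) {
  if (is.null(x$ast)) cat(sprintf("<pde_expr (INVALID): %s | %s>\n", x$src, x$error))
  else cat(sprintf("<pde_expr: %s>\n", x$src))
  invisible(x)
}

# Derivative-token machinery ---------------------------------------------

.token_suffixes <- c("x", "y", "xx", "yy", "x_b", "x_f", "y_b", "y_f")
.mixed_suffixes <- c("xy", "yx", "xxy", "xyy", "yx", "xyx")

# Derivative tokens for a set of species names.
.derivative_tokens <- function(species_names) {
  as.vector(outer(species_names, .token_suffixes, paste, sep = "_"))
}

# Split a symbol into (species, suffix) if it is a derivative token of one of
# `species_names`; NULL otherwise.
.split_token <- function(sym, species_names) {
  for (sp in species_names) {
    pre <- paste0(sp, "_")
    if (startsWith(sym, pre)) {
      suf <- substring(sym, nchar(pre) + 1L)
      if (suf %in% .token_suffixes) return(list(species = sp, suffix = suf))
      if (suf %in% .mixed_suffixes) return(list(species = sp, suffix = suf, mixed = TRUE))
    }
  }
  NULL
}
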