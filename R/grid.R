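# Rectangular node lattice and indicator-function masking.
#
# Nodes are placed at cell centres, x_i = (i - 1/2) * dx_eff with
# dx_eff = L_x / N_x and N_x = floor(L_x / dx) (rounding down, so the
# effective spacing is at least the requested one and the cells exactly tile
# [0, L]). A single requested step size applies to both axes. 1D grids have
# N_y = 1 and dy_eff = 1 so that node "areas" reduce to cell widths.

#' Build the rectangular node lattice
#'
#' @param domain domain description: `list(dimension, L_x, L_y)` (the
#'   `domain` element of a [pde_config()] works directly).
#' @param dx requested spatial step; the node count per axis is
#'   `floor(L/dx)` and the effective spacing `L/N`.
#' @return object of class `pde_grid` with fields `dimension`, `N_x`, `N_y`,
#'   `dx_eff`, `dy_eff`, coordinate matrices `X`, `Y` (`N_x` by `N_y`), and
#'   the side lengths.
#' @examples
#' g <- build_grid(list(dimension = 2, L_x = 1, L_y = 1), dx = 0.3)
#' c(g$N_x, g$N_y)        # 3 3
#' g$dx_eff               # 1/3
#' @export
build_grid <- function(domain, dx) {
  if (!is.numeric(dx) || dx <= 0) stop("dx must be > 0", call. = FALSE)
  dim <- as.integer(domain$dimension)
  L_x <- domain$L_x
  if (dx > L_x) stop("dx exceeds L_x", call. = FALSE)
  # tiny relative guard so exact quotients (2.5/0.5) do not round down
  nfloor <- function(L, h) max(1L, as.integer(floor(L / h + 1e-9)))
  N_x <- nfloor(L_x, dx)
  if (N_x < 2L) stop(sprintf("x axis has only %d node", N_x), call. = FALSE)
  if (dim == 2L) {
    L_y <- domain$L_y
    if (dx > L_y) stop("dx exceeds L_y", call. = FALSE)
    N_y <- nfloor(L_y, dx)
    if (N_y < 2L) stop(sprintf("y axis has only %d node(s)", N_y), call. = FALSE)
    dy_eff <- L_y / N_y
  } else {
    L_y <- NULL; N_y <- 1L; dy_eff <- 1
  }
  dx_eff <- L_x / N_x
  xs <- (seq_len(N_x) - 0.5) * dx_eff
  ys <- if (dim == 2L) (seq_len(N_y) - 0.5) * dy_eff else 0
  structure(list(dimension = dim, N_x = N_x, N_y = N_y,
                 dx_eff = dx_eff, dy_eff = dy_eff,
                 L_x = L_x, L_y = L_y,
                 X = matrix(xs, N_x, N_y),
                 Y = matrix(ys, N_x, N_y, byrow = TRUE)),
            class = "pde_grid")
}

#' Carve the simulated subset out of the rectangle
#'
#' A node is simulated iff the indicator expression evaluates to a value
#' strictly greater than zero at its (cell-centre) coordinates. An absent
#' indicator yields the all-true mask. Edges between a simulated node and an
#' excluded node are zero-flux (mirror ghost), the same mechanism as the
#' outer boundary's homogeneous Neumann default.
#'
#' @param indicator a `pde_expr` over `x`, `y` and parameters, or `NULL`.
#' @param grid a [build_grid()] result.
#' @param params named list of parameter values.
#' @return object of class `pde_mask`: logical matrix `inside` plus
#'   precomputed neighbour-exclusion masks used by the stencils.
#' @export
build_mask <- function(indicator, grid, params = list()) {
  if (is.null(indicator)) {
    inside <- matrix(TRUE, grid$N_x, grid$N_y)
  } else {
    ctx <- c(list(x = grid$X, y = grid$Y), as.list(params))
    val <- eval_expr(indicator, ctx)
    inside <- matrix(FALSE, grid$N_x, grid$N_y)
    inside[] <- is.finite(val) & val > 0
  }
  if (!any(inside)) stop("indicator excludes every node (all-false mask)", call. = FALSE)
  structure(c(list(inside = inside), .mask_edges(inside)), class = "pde_mask")
}

# For each of the four neighbour directions, a logical matrix marking inside
# nodes whose neighbour in that direction is excluded (outer ghosts are
# BC-handled and never count as excluded).
.mask_edges <- function(inside) {
  nx <- nrow(inside); ny <- ncol(inside)
  pad <- matrix(TRUE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- inside
  list(
    excl_xm = inside & !pad[1:nx, 2:(ny + 1L)],
    excl_xp = inside & !pad[3:(nx + 2L), 2:(ny + 1L)],
    excl_ym = inside & !pad[2:(nx + 1L), 1:ny],
    excl_yp = inside & !pad[2:(nx + 1L), 3:(ny + 2L)],
    any_excluded = !all(inside)
  )
}

#' @export
print.pde_grid <- function(x, ...) {
  cat(sprintf("<pde_grid %dD: %d x %d nodes, dx_eff = %g%s>\n",
              x$dimension, x$N_x, x$N_y, x$dx_eff,
              if (x$dimension == 2L) sprintf(", dy_eff = %g", x$dy_eff) else ""))
  invisible(x)
}

#' @export
print.pde_mask <- function(x, ...) {
  cat(sprintf("<pde_mask: %d of %d nodes simulated>\n",
              sum(x$inside), length(x$inside)))
  invisible(x)
}
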