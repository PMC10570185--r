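# Views, colormap rendering, image functions, integrals, frame export.

# Colormap anchor tables (RGB in [0,1]); interpolated with colorRamp.
# "viridis": perceptually uniform; "diverging": blue-white-red for signed
# fields; "aurora": a multi-hue map in the style of interactive PDE art;
# "greyscale" for image work. The viridis anchors follow the widely published
# table; see the methods vignette for the accessibility note.
.colormaps <- list(
  viridis = c("#440154", "#46327E", "#365C8D", "#277F8E", "#1FA187",
              "#4AC16D", "#A0DA39", "#FDE725"),
  diverging = c("#2166AC", "#67A9CF", "#D1E5F0", "#F7F7F7",
                "#FDDBC7", "#EF8A62", "#B2182B"),
  aurora = c("#0D0887", "#6A00A8", "#B12A90", "#E16462",
             "#FCA636", "#F0F921"),
  greyscale = c("#000000", "#FFFFFF")
)

.sentinel_rgb <- c(1, 0, 1)  # non-finite values render magenta

#' List available colormaps
#' @return character vector of colormap ids.
#' @export
list_colormaps <- function() names(.colormaps)

#' Evaluate a view expression on the current state
#'
#' A view maps the state to the scalar field actually displayed: any
#' expression over species, coordinates, time, parameters and derivative
#' tokens (e.g. `"u"`, `"u^2 + v^2"`, `"-u_x"`). Masked-out nodes are
#' returned as `NA` (no-data); non-finite evaluation results flow through to
#' be rendered as the sentinel colour, never an exception.
#'
#' @param state a `pde_state`.
#' @param view a view spec `list(name, expression, colormap, scaling,
#'   colorbar)` (as stored in a config) or a bare expression string.
#' @param cfg the [pde_config()] or runtime the state belongs to.
#' @return grid-shaped numeric matrix with `NA` at masked-out nodes.
#' @export
evaluate_view <- function(state, view, cfg) {
  rt <- if (inherits(cfg, "pde_runtime")) cfg else compile_config(cfg)
  if (is.character(view)) view <- list(name = view, expression = .as_expr(view, "view"))
  e <- view$expression
  env <- .make_env(state$fields, rt, state$t)
  pads <- new.env(parent = emptyenv())
  .ensure_tokens(e, env, rt, pads, state$t)
  field <- .as_field(eval_expr(e, env), rt$grid)
  field[!rt$mask$inside] <- NA_real_
  field
}

#' Render a scalar field to an RGB raster
#'
#' Adaptive scaling maps the frame minimum to 0 and maximum to 1 (a flat
#' field maps to the midpoint of the colormap); fixed scaling clamps to the
#' given range. Non-finite/no-data values render as the magenta sentinel.
#' Pixel values are a pure function of (field, view): repeated calls are
#' bit-identical.
#'
#' @param field numeric matrix (`N_x` by `N_y`), e.g. from [evaluate_view()].
#' @param view list with `colormap` id and `scaling` (`"adaptive"` or
#'   `list(min=, max=)` / `c(min, max)` for fixed).
#' @return `N_y` by `N_x` by 3 array in [0,1] (rows top-to-bottom: the image
#'   top row is `y = L_y`), suitable for [png::writePNG].
#' @export
render_frame <- function(field, view = list(colormap = "viridis", scaling = "adaptive")) {
  cmap <- .colormaps[[view$colormap %||% "viridis"]]
  if (is.null(cmap)) stop(sprintf("unknown colormap '%s'", view$colormap), call. = FALSE)
  ramp <- grDevices::colorRamp(cmap, space = "rgb")
  finite <- is.finite(field)
  scaling <- view$scaling %||% "adaptive"
  if (identical(scaling, "adaptive")) {
    if (!any(finite)) { lo <- 0; hi <- 0 }
    else { lo <- min(field[finite]); hi <- max(field[finite]) }
  } else {
    sc <- unlist(scaling, use.names = FALSE)
    lo <- sc[[1L]]; hi <- sc[[2L]]
  }
  z <- field
  if (hi > lo) {
    z[finite] <- pmin(1, pmax(0, (field[finite] - lo) / (hi - lo)))
  } else {
    z[finite] <- 0.5   # degenerate flat range maps to the midpoint
  }
  nx <- nrow(field); ny <- ncol(field)
  out <- array(0, c(ny, nx, 3L))
  rgb <- matrix(.sentinel_rgb, length(field), 3L, byrow = TRUE)
  if (any(finite)) rgb[finite, ] <- ramp(z[finite]) / 255
  # field[i, j] is node (x_i, y_j); image row 1 is the TOP (y = L_y)
  for (ch in 1:3) out[, , ch] <- t(matrix(rgb[, ch], nx, ny))[ny:1, , drop = FALSE]
  out
}

#' Integral of a field over the simulated domain
#'
#' Midpoint quadrature on the cell-centre lattice:
#' `sum(field[inside]) * dx_eff * dy_eff` (with `dy_eff = 1` in 1D, so the 1D
#' integral is `sum * dx_eff`). This is the quantity displayed alongside the
#' clock in interactive use.
#'
#' @param field grid-shaped matrix.
#' @param grid a [build_grid()] result.
#' @param mask optional [build_mask()]; default integrates the full rectangle.
#' @return scalar.
#' @export
compute_integral <- function(field, grid, mask = NULL) {
  inside <- if (is.null(mask)) TRUE else mask$inside
  sum(field[inside]) * grid$dx_eff * grid$dy_eff
}

#' Load a greyscale image function
#'
#' Reads a PNG, converts to luminance with the Rec. 601 weights
#' (0.299 R + 0.587 G + 0.114 B; alpha ignored) and wraps it for use as the
#' spatial functions `I_S(x, y)` / `I_T(x, y)` inside equations. The image x
#' axis maps to the domain `x` in `[0, L_x]`; the image *top* row maps to
#' `y = L_y`. Sampling is bilinear between pixel centres (clamped at the
#' border), so values are continuous in `(x, y)` and lie in [0, 1].
#'
#' @param path readable PNG file.
#' @return object of class `pde_image` (luminance matrix, rows = image rows).
#' @export
load_image_function <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s'", path), call. = FALSE)
  a <- png::readPNG(path)
  lum <- if (length(dim(a)) == 2L) a
         else if (dim(a)[3L] >= 3L) 0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
         else a[, , 1L]
  lum[lum < 0] <- 0
  lum[lum > 1] <- 1
  structure(list(lum = lum, nrow = nrow(lum), ncol = ncol(lum), path = path),
            class = "pde_image")
}

#' Sample an image function at domain coordinates
#'
#' @param img a [load_image_function()] result.
#' @param x,y coordinate matrices/vectors in model units.
#' @param L_x,L_y domain side lengths.
#' @return values in [0,1], same shape as `x`.
#' @export
sample_image <- function(img, x, y, L_x, L_y) {
  H <- img$nrow; W <- img$ncol
  # pixel centres: column j covers x in [(j-1), j] * L_x/W; top row is y = L_y
  cx <- x / L_x * W + 0.5            # continuous column coordinate (1-based centres)
  ry <- (L_y - y) / L_y * H + 0.5    # continuous row coordinate, top row = 1
  # bilinear on the (row, col) lattice of pixel centres, clamped at the border
  c1 <- pmin(pmax(floor(cx), 1L), W); c2 <- pmin(c1 + 1L, W)
  r1 <- pmin(pmax(floor(ry), 1L), H); r2 <- pmin(r1 + 1L, H)
  fx <- pmin(pmax(cx - c1, 0), 1); fy <- pmin(pmax(ry - r1, 0), 1)
  idx <- function(r, c) img$lum[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fy) * ((1 - fx) * idx(r1, c1) + fx * idx(r1, c2)) +
       fy * ((1 - fx) * idx(r2, c1) + fx * idx(r2, c2))
  out <- x
  out[] <- pmin(1, pmax(0, v))
  out
}

#' Export frames as a deterministic PNG sequence
#'
#' Writes one PNG per frame with zero-padded indices
#' (`frame_0001.png`, ...). Re-exporting identical frames produces identical
#' bytes. Animation containers (MP4/GIF) are out of scope; any external
#' encoder can assemble the sequence at the recorded fps.
#'
#' @param frames list of RGB arrays from [render_frame()], all the same size.
#' @param dir output directory (created if needed).
#' @param fps frames per second recorded in the sequence manifest.
#' @param prefix file-name prefix.
#' @return invisibly, the vector of files written.
#' @export
export_animation <- function(frames, dir, fps = 30, prefix = "frame") {
  if (length(frames) == 0L) stop("no frames to export", call. = FALSE)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("frames must all have identical sizes", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  width <- max(4L, nchar(as.character(length(frames))))
  files <- character(length(frames))
  for (k in seq_along(frames)) {
    files[[k]] <- file.path(dir, sprintf("%s_%0*d.png", prefix, width, k))
    png::writePNG(frames[[k]], files[[k]])
  }
  manifest <- list(n_frames = length(frames), fps = fps,
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
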