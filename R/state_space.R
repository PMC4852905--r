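#' Construct the discrete state space of candidate activity centres
#'
#' The state space is a regular axis-aligned grid of square pixels covering
#' `extent` (typically the searched area plus a buffer). Each pixel centroid
#' is a candidate activity centre; pixels flagged unsuitable by the habitat
#' mask are excluded from the activity-centre support but retained in the
#' geometry so rasters round-trip unchanged.
#'
#' @param extent numeric length 4: `c(xmin, xmax, ymin, ymax)` in km
#'   (projected planar coordinates).
#' @param side pixel side length in km (default 0.65).
#' @param mask habitat suitability. Either `NULL` (all pixels suitable), a
#'   logical/0-1 vector of length `nx * ny` in row-major top-left order, or
#'   an `ascii_grid` (see [read_ascii_grid()]) from which each centroid takes
#'   the nearest-cell value; 1 = suitable, 0/NODATA/outside = unsuitable.
#' @return an object of class `state_space`: centroid coordinates `x`, `y`
#'   (row-major from the top-left pixel), `side`, logical `suitable`,
#'   grid dimensions `nx`, `ny` and the lower-left corner `xmin`, `ymin`.
#' @export
build_state_space <- function(extent, side = 0.65, mask = NULL) {
  stopifnot(length(extent) == 4, is.numeric(extent))
  xmin <- extent[1]; xmax <- extent[2]; ymin <- extent[3]; ymax <- extent[4]
  if (!(xmax > xmin) || !(ymax > ymin)) stop("empty extent")
  if (!is.numeric(side) || length(side) != 1 || side <= 0) stop("side must be > 0")
  nx <- as.integer(ceiling((xmax - xmin) / side - 1e-9))
  ny <- as.integer(ceiling((ymax - ymin) / side - 1e-9))
  # row-major from the top-left pixel (ASCII-grid convention)
  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  x <- xmin + (col - 0.5) * side
  y <- ymin + ny * side - (row - 0.5) * side
  G <- nx * ny
  if (is.null(mask)) {
    suitable <- rep(TRUE, G)
  } else if (inherits(mask, "ascii_grid")) {
    v <- grid_value_at(mask, x, y)
    suitable <- !is.na(v) & v == 1
  } else {
    if (length(mask) != G)
      stop("mask vector must have length nx * ny = ", G)
    suitable <- as.logical(mask)
    suitable[is.na(suitable)] <- FALSE
  }
  if (!any(suitable))
    stop("all pixels unsuitable: no support for activity centres")
  structure(
    list(x = x, y = y, side = side, suitable = suitable,
         nx = nx, ny = ny, xmin = xmin, ymin = ymin),
    class = "state_space")
}

#' Areas of a state space
#'
#' @param space a `state_space`.
#' @return `suitable_area()`: area (km^2) of the suitable pixels;
#'   `total_area()`: area of all pixels. Both are pixel counts times `side^2`.
#' @export
suitable_area <- function(space) {
  stopifnot(inherits(space, "state_space"))
  sum(space$suitable) * space$side^2
}

#' @rdname suitable_area
#' @export
total_area <- function(space) {
  stopifnot(inherits(space, "state_space"))
  length(space$x) * space$side^2
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf(
    "state_space: %d x %d pixels of %.3g km (%d suitable of %d; %.2f of %.2f km^2 suitable)\n",
    x$nx, x$ny, x$side, sum(x$suitable), length(x$x),
    suitable_area(x), total_area(x)))
  invisible(x)
}

#' Construct a regular trap grid over the searched extent
#'
#' In search-encounter SECR each grid pixel acts as a detector ("trap");
#' a trap is active on an occasion if any search effort fell in it that day.
#'
#' @param extent numeric length 4: `c(xmin, xmax, ymin, ymax)` in km.
#' @param side trap pixel side in km (default 1).
#' @return an object of class `trap_grid` with centroid coordinates `x`, `y`
#'   (row-major from the top-left), `side`, `nx`, `ny`, `xmin`, `ymin` and
#'   trap count `J`.
#' @export
build_trap_grid <- function(extent, side = 1) {
  g <- build_state_space(extent, side = side, mask = NULL)
  structure(
    list(x = g$x, y = g$y, side = side, nx = g$nx, ny = g$ny,
         xmin = g$xmin, ymin = g$ymin, J = length(g$x)),
    class = "trap_grid")
}

#' @export
print.trap_grid <- function(x, ...) {
  cat(sprintf("trap_grid: %d x %d traps of %.3g km (J = %d)\n",
              x$nx, x$ny, x$side, x$J))
  invisible(x)
}

# Trap pixel index containing each point; NA outside the grid.
trap_index <- function(traps, x, y) {
  col <- floor((x - traps$xmin) / traps$side) + 1
  ymax <- traps$ymin + traps$ny * traps$side
  row <- floor((ymax - y) / traps$side) + 1
  # points exactly on the max edge belong to the last pixel
  col[x == traps$xmin + traps$nx * traps$side] <- traps$nx
  row[y == traps$ymin] <- traps$ny
  ok <- col >= 1 & col <= traps$nx & row >= 1 & row <= traps$ny
  idx <- (row - 1L) * traps$nx + col
  idx[!ok] <- NA_integer_
  as.integer(idx)
}

#' Centroid-to-centroid distance matrix
#'
#' Euclidean distances (km) between state-space pixel centroids and trap
#' centroids, used to evaluate the detection kernel. Both grids must be in
#' the same projected planar coordinate system.
#'
#' @param space a `state_space`.
#' @param traps a `trap_grid`.
#' @param suitable_only if `TRUE` (default) rows cover only suitable pixels,
#'   in the order of `which(space$suitable)`; activity centres live there.
#' @return a `G x J` matrix of distances in km.
#' @export
distance_matrix <- function(space, traps, suitable_only = TRUE) {
  stopifnot(inherits(space, "state_space"), inherits(traps, "trap_grid"))
  keep <- if (suitable_only) space$suitable else rep(TRUE, length(space$x))
  sx <- space$x[keep]; sy <- space$y[keep]
  sqrt(outer(sx, traps$x, "-")^2 + outer(sy, traps$y, "-")^2)
}

# ---- ESRI ASCII grid I/O ------------------------------------------------
# Plain-text raster: 6-line header then nrows lines of ncols values,
# row-major from the top-left (north-west) cell.

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return an `ascii_grid`: list with `ncols`, `nrows`, `xllcorner`,
#'   `yllcorner`, `cellsize`, `nodata` and `values`, a `nrows x ncols`
#'   matrix whose first row is the northernmost. NODATA cells are `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid has ", length(vals), " values; expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  structure(
    list(ncols = as.integer(hdr$ncols), nrows = as.integer(hdr$nrows),
         xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
         cellsize = hdr$cellsize, nodata = nodata, values = m),
    class = "ascii_grid")
}

#' Write an ESRI ASCII grid
#'
#' @param grid an `ascii_grid`.
#' @param path file path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 7) {
  stopifnot(inherits(grid, "ascii_grid"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$xllcorner),
    sprintf("yllcorner %.10g", grid$yllcorner),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  writeLines(apply(m, 1, function(r)
    paste(signif(r, digits), collapse = " ")), con)
  invisible(path)
}

# Nearest-cell lookup; NA outside the raster or on NODATA.
grid_value_at <- function(grid, x, y) {
  col <- floor((x - grid$xllcorner) / grid$cellsize) + 1
  row <- floor((grid$yllcorner + grid$nrows * grid$cellsize - y) /
                 grid$cellsize) + 1
  ok <- col >= 1 & col <= grid$ncols & row >= 1 & row <= grid$nrows
  out <- rep(NA_real_, length(x))
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Convert a per-pixel vector to an ASCII grid in state-space geometry
#'
#' @param space a `state_space`.
#' @param values numeric vector: either length `nx * ny` (all pixels,
#'   row-major from the top-left) or one value per suitable pixel.
#' @param nodata NODATA marker used for unsuitable pixels when `values`
#'   covers only suitable pixels.
#' @return an `ascii_grid`.
#' @export
state_space_grid <- function(space, values, nodata = -9999) {
  stopifnot(inherits(space, "state_space"))
  G <- length(space$x)
  if (length(values) == sum(space$suitable)) {
    full <- rep(NA_real_, G)
    full[space$suitable] <- values
  } else if (length(values) == G) {
    full <- as.numeric(values)
  } else stop("values must cover all pixels or all suitable pixels")
  structure(
    list(ncols = space$nx, nrows = space$ny,
         xllcorner = space$xmin, yllcorner = space$ymin,
         cellsize = space$side, nodata = nodata,
         values = matrix(full, nrow = space$ny, ncol = space$nx,
                         byrow = TRUE)),
    class = "ascii_grid")
}

#' Rebuild a state space from its serialized suitability grid
#'
#' @param grid an `ascii_grid` of 1 (suitable) / 0 (unsuitable) values, as
#'   written by `state_space_grid(space, as.numeric(space$suitable))`.
#' @return a `state_space` identical to the one serialized.
#' @export
state_space_from_grid <- function(grid) {
  stopifnot(inherits(grid, "ascii_grid"))
  extent <- c(grid$xllcorner, grid$xllcorner + grid$ncols * grid$cellsize,
              grid$yllcorner, grid$yllcorner + grid$nrows * grid$cellsize)
  v <- as.vector(t(grid$values))  # row-major from top-left
  build_state_space(extent, side = grid$cellsize, mask = v)
}
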