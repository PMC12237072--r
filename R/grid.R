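#' Land-cover class labels
#'
#' The categorical land-cover vocabulary used throughout the workflow. The
#' two inundation-radar classes are merged into "flooded_vegetation" by
#' [merge_flooded_class()] before any summaries are computed.
#'
#' @export
landcover_classes <- function() {
  c("floodplain_forest", "transition_forest", "terra_firme",
    "flooded_vegetation", "open_water", "crops", "built_area",
    "bare_ground", "sparsely_vegetated")
}

#' Construct a gridded landscape
#'
#' A `land_grid` is a lightweight in-memory raster stack: a list of congruent
#' matrices sharing one cell size and a lower-left origin, using the standard
#' north-up convention (row 1 is the northern edge; x grows with column,
#' y decreases with row). Layers are `elevation` (m), `drainage` (logical),
#' `hand` (m), `cover` (integer codes into [landcover_classes()]) and
#' `canopy` (m).
#'
#' @param layers named list of matrices with identical dimensions.
#' @param cell_size cell edge length in meters (default 30).
#' @param origin numeric length-2, x/y of the lower-left corner (meters).
#' @return an object of class `land_grid`.
#' @export
land_grid <- function(layers, cell_size = 30, origin = c(0, 0)) {
  stopifnot(is.list(layers), length(layers) >= 1)
  dims <- lapply(layers, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", ""))) != 1)
    bp_stop("all land_grid layers must share identical dimensions")
  structure(list(layers = layers, cell_size = cell_size, origin = origin,
                 nrow = nrow(layers[[1]]), ncol = ncol(layers[[1]])),
            class = "land_grid")
}

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("<land_grid> %d x %d cells @ %g m; layers: %s\n",
              x$nrow, x$ncol, x$cell_size,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Cell-center coordinates of a land_grid
#'
#' @param grid a `land_grid`.
#' @return data.frame with `row`, `col`, `x`, `y` for every cell.
#' @export
grid_centers <- function(grid) {
  rows <- seq_len(grid$nrow)
  cols <- seq_len(grid$ncol)
  cc <- expand.grid(row = rows, col = cols)
  cc$x <- grid$origin[1] + (cc$col - 0.5) * grid$cell_size
  cc$y <- grid$origin[2] + (grid$nrow - cc$row + 0.5) * grid$cell_size
  cc
}

# internal: row/col of the cell containing projected point(s)
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- grid$nrow - floor((y - grid$origin[2]) / grid$cell_size)
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow
  if (any(bad)) bp_stop("point(s) fall outside the grid extent")
  cbind(row = row, col = col)
}

#' Height above nearest drainage
#'
#' HAND(c) = max(0, elevation(c) - elevation of the Euclidean-nearest
#' drainage cell); drainage cells themselves get 0. This is the simplest
#' flooding-intensity proxy consistent with a successional gradient away
#' from river channels; flow-path (hydrological) HAND is out of scope.
#'
#' @param elevation elevation matrix (m).
#' @param drainage logical matrix flagging drainage (river-channel) cells.
#' @return matrix of HAND values (m), same dimensions.
#' @export
compute_hand <- function(elevation, drainage) {
  stopifnot(all(dim(elevation) == dim(drainage)))
  if (!any(drainage)) bp_stop("drainage mask is empty")
  dr <- which(drainage, arr.ind = TRUE)
  nr <- nrow(elevation); nc <- ncol(elevation)
  # nearest drainage cell per cell by squared Euclidean distance over cell
  # indices; vectorized over drainage cells (fine at analysis grid sizes)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  best_d <- matrix(Inf, nr, nc)
  best_e <- matrix(NA_real_, nr, nc)
  for (k in seq_len(nrow(dr))) {
    d <- (rows - dr[k, 1])^2 + (cols - dr[k, 2])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_e[upd] <- elevation[dr[k, 1], dr[k, 2]]
  }
  hand <- elevation - best_e
  hand[hand < 0] <- 0
  hand[drainage] <- 0
  hand
}

#' Merge inundation classes into flooded vegetation
#'
#' Cells flagged by either inundation-radar class ("occasionally open water"
#' or "always inundated") are relabeled as flooded vegetation; all other
#' labels are unchanged.
#'
#' @param cover integer matrix of land-cover codes.
#' @param inundated logical matrix (union of the two inundation classes).
#' @return relabeled cover matrix.
#' @export
merge_flooded_class <- function(cover, inundated) {
  stopifnot(all(dim(cover) == dim(inundated)))
  code <- match("flooded_vegetation", landcover_classes())
  cover[inundated] <- code
  cover
}

#' Resample layers to a common grid
#'
#' Categorical layers use nearest-neighbor lookup; continuous layers use
#' bicubic (cubic-convolution, Catmull-Rom kernel) interpolation with edge
#' replication. Source and target grids share the same extent.
#'
#' @param m source matrix.
#' @param out_dim target `c(nrow, ncol)`.
#' @param method "nearest" or "bicubic".
#' @return resampled matrix of dimension `out_dim`.
#' @export
resample_matrix <- function(m, out_dim, method = c("nearest", "bicubic")) {
  method <- match.arg(method)
  nr <- nrow(m); nc <- ncol(m)
  or <- out_dim[1]; oc <- out_dim[2]
  if (or == nr && oc == nc) return(m)
  # fractional source position of each target cell center (same extent)
  src_r <- (seq_len(or) - 0.5) * nr / or + 0.5
  src_c <- (seq_len(oc) - 0.5) * nc / oc + 0.5
  if (method == "nearest") {
    ri <- pmin(pmax(round(src_r), 1), nr)
    ci <- pmin(pmax(round(src_c), 1), nc)
    return(m[ri, ci, drop = FALSE])
  }
  cubic_w <- function(t) {
    # Catmull-Rom weights for the 4-tap neighborhood at fractional offset t
    t2 <- t * t; t3 <- t2 * t
    cbind(-0.5 * t3 + t2 - 0.5 * t,
          1.5 * t3 - 2.5 * t2 + 1,
          -1.5 * t3 + 2 * t2 + 0.5 * t,
          0.5 * t3 - 0.5 * t2)
  }
  idx4 <- function(base, n) pmin(pmax(cbind(base - 1, base, base + 1, base + 2), 1), n)
  rb <- floor(src_r); rt <- src_r - rb
  cb <- floor(src_c); ct <- src_c - cb
  wr <- cubic_w(rt); wc <- cubic_w(ct)
  ir <- idx4(rb, nr); ic <- idx4(cb, nc)
  out <- matrix(0, or, oc)
  for (a in 1:4) for (b in 1:4) {
    out <- out + outer(wr[, a], wc[, b]) * m[ir[, a], ic[, b], drop = FALSE]
  }
  out
}

#' @rdname resample_matrix
#' @param grid a `land_grid`.
#' @param target_cell target cell size in meters (default 30).
#' @param categorical character vector naming the categorical layers.
#' @export
resample_to_common_grid <- function(grid, target_cell = 30,
                                    categorical = c("cover", "drainage")) {
  f <- grid$cell_size / target_cell
  out_dim <- c(round(grid$nrow * f), round(grid$ncol * f))
  layers <- lapply(names(grid$layers), function(nm) {
    m <- grid$layers[[nm]]
    if (nm %in% categorical) {
      storage <- resample_matrix(m + 0, out_dim, "nearest")
      if (is.logical(m)) storage > 0.5 else storage
    } else {
      resample_matrix(m, out_dim, "bicubic")
    }
  })
  names(layers) <- names(grid$layers)
  land_grid(layers, cell_size = target_cell, origin = grid$origin)
}
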