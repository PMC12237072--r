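#' Multi-scale buffer summaries of habitat layers
#'
#' For every point and radius, summarizes the cells whose centers fall within
#' the circular buffer: mean and SD of each continuous layer, percent cover
#' of each land-cover class, and edge density of each class (meters of
#' boundary between class and non-class cells per hectare of buffer). A
#' derived `pct_anthropogenic` column sums crops and built-area cover.
#'
#' Cell membership is by cell-center inclusion; buffer area is the included
#' cell count times the cell area. Edge segments are counted between
#' orthogonally adjacent included cells of differing class membership, so
#' the exterior buffer boundary contributes nothing (interior-adjacency
#' definition; landscape-metric tools differ on this point).
#'
#' @param grid a `land_grid` with `hand`, `canopy` and `cover` layers.
#' @param points data.frame with `site_id`, `x`, `y` (projected meters).
#' @param radii buffer radii in meters (default `c(300, 1000)`).
#' @param continuous names of continuous layers to summarize.
#' @return data.frame keyed by `site_id` and `radius_m` with columns
#'   `mean_<layer>`, `sd_<layer>`, `pct_<class>`, `ed_<class>`,
#'   `pct_anthropogenic`.
#' @export
buffer_summaries <- function(grid, points, radii = c(300, 1000),
                             continuous = c("hand", "canopy")) {
  stopifnot(all(c("site_id", "x", "y") %in% names(points)))
  cc <- grid_centers(grid)
  cover <- grid$layers$cover
  classes <- landcover_classes()
  cell_m <- grid$cell_size
  out <- vector("list", nrow(points) * length(radii))
  k <- 0
  for (i in seq_len(nrow(points))) {
    for (r in radii) {
      inb <- (cc$x - points$x[i])^2 + (cc$y - points$y[i])^2 <= r^2
      if (!any(inb)) bp_stop(sprintf(
        "buffer of %g m around site %s contains no cell centers",
        r, points$site_id[i]))
      sel <- cc[inb, , drop = FALSE]
      idx <- cbind(sel$row, sel$col)
      row1 <- list(site_id = points$site_id[i], radius_m = r)
      for (nm in continuous) {
        v <- grid$layers[[nm]][idx]
        row1[[paste0("mean_", nm)]] <- mean(v)
        row1[[paste0("sd_", nm)]] <- if (length(v) > 1) stats::sd(v) else 0
      }
      cl <- cover[idx]
      n_in <- nrow(sel)
      area_ha <- n_in * cell_m^2 / 1e4
      # adjacency within the included cell set: key cells by linear index
      lin <- (sel$col - 1L) * grid$nrow + sel$row
      inset <- logical(grid$nrow * grid$ncol)
      inset[lin] <- TRUE
      right <- lin + grid$nrow
      down <- lin + 1L
      ok_right <- sel$col < grid$ncol & inset[pmin(right, length(inset))]
      ok_down <- sel$row < grid$nrow & inset[pmin(down, length(inset))]
      sub_r <- which(ok_right)
      sub_d <- which(ok_down)
      for (ci in seq_along(classes)) {
        row1[[paste0("pct_", classes[ci])]] <- 100 * sum(cl == ci) / n_in
        isc <- cover == ci
        e_r <- sum(isc[lin[sub_r]] != isc[right[sub_r]])
        e_d <- sum(isc[lin[sub_d]] != isc[down[sub_d]])
        row1[[paste0("ed_", classes[ci])]] <- (e_r + e_d) * cell_m / area_ha
      }
      row1$pct_anthropogenic <- row1$pct_crops + row1$pct_built_area
      k <- k + 1
      out[[k]] <- as.data.frame(row1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Build the prediction-surface mask
#'
#' The analysis is restricted to cells within `buffer_m` of at least one
#' survey point, inside an optional boundary polygon, and at elevations not
#' exceeding `elev_cap_m` — keeping predictions close in geographic and
#' climatic space to where training data exist.
#'
#' @param grid a `land_grid` with an `elevation` layer.
#' @param points data.frame with `x`, `y`.
#' @param buffer_m buffer width in meters (default 35000).
#' @param elev_cap_m elevation cap in meters (default 350).
#' @param boundary optional polygon as a data.frame of `x`, `y` vertices.
#' @return logical matrix mask (TRUE = inside the prediction surface).
#' @export
build_prediction_surface <- function(grid, points, buffer_m = 35000,
                                     elev_cap_m = 350, boundary = NULL) {
  cc <- grid_centers(grid)
  near <- rep(FALSE, nrow(cc))
  for (i in seq_len(nrow(points))) {
    near <- near |
      (cc$x - points$x[i])^2 + (cc$y - points$y[i])^2 <= buffer_m^2
  }
  keep <- near
  if (!is.null(boundary))
    keep <- keep & point_in_polygon(cc$x, cc$y, boundary$x, boundary$y)
  mask <- matrix(FALSE, grid$nrow, grid$ncol)
  mask[cbind(cc$row, cc$col)] <- keep
  mask <- mask & (grid$layers$elevation <= elev_cap_m)
  if (!any(mask)) bp_stop("prediction surface is empty (elevation cap below all cells?)")
  mask
}

#' Smallest buffer width yielding one connected mask
#'
#' Reports the minimal buffer width (searched over `widths`) for which the
#' union of point buffers forms a single connected region on the grid --
#' the criterion behind the default 35 km width.
#'
#' @param grid a `land_grid`.
#' @param points data.frame with `x`, `y`.
#' @param widths candidate widths in meters, ascending.
#' @return the smallest width achieving a single connected component
#'   (NA if none does).
#' @export
minimal_connected_width <- function(grid, points,
                                    widths = seq(1000, 50000, by = 1000)) {
  for (w in widths) {
    cc <- grid_centers(grid)
    near <- rep(FALSE, nrow(cc))
    for (i in seq_len(nrow(points)))
      near <- near | (cc$x - points$x[i])^2 + (cc$y - points$y[i])^2 <= w^2
    mask <- matrix(FALSE, grid$nrow, grid$ncol)
    mask[cbind(cc$row, cc$col)] <- near
    if (n_components(mask) == 1) return(w)
  }
  NA_real_
}

# internal: 4-connected component count via flood fill
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    comp <- comp + 1L
    stack <- todo[1]
    while (length(stack)) {
      c0 <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[c0] != 0L || !mask[c0]) next
      lab[c0] <- comp
      r <- (c0 - 1L) %% nrow(mask) + 1L
      cl <- (c0 - 1L) %/% nrow(mask) + 1L
      nb <- c(if (r > 1) c0 - 1L, if (r < nrow(mask)) c0 + 1L,
              if (cl > 1) c0 - nrow(mask), if (cl < ncol(mask)) c0 + nrow(mask))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      stack <- c(stack, nb)
    }
    todo <- which(mask & lab == 0L)
  }
  comp
}

# internal: even-odd ray-casting point-in-polygon test
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}
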