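# --- Delaunay triangulation (Bowyer-Watson) -------------------------------
# Small-scale triangulator for electrode layouts (tens of points). Returns a
# matrix of vertex-index triples.
.delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("triangulation needs at least 3 points")
  # super-triangle comfortably enclosing all points
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2]))) * 10 + 1
  P <- rbind(pts, c(cx - 2 * span, cy - span), c(cx + 2 * span, cy - span),
             c(cx, cy + 2 * span))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3)
  circum <- function(tri) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; c <- P[tri[3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) return(c(Inf, Inf, Inf))
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) + (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
           (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
    uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
           (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
    c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
  }
  cc <- matrix(circum(tris[1, ]), ncol = 3)
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- (p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    if (!any(bad)) stop("triangulation failure: point outside all circumcircles")
    # boundary of the cavity = edges of bad triangles that appear exactly once
    edges <- do.call(rbind, lapply(which(bad), function(ti) {
      tr <- tris[ti, ]
      rbind(sort(tr[c(1, 2)]), sort(tr[c(2, 3)]), sort(tr[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    newt <- cbind(boundary, ip)
    tris <- rbind(tris, newt)
    cc <- rbind(cc, t(apply(newt, 1, circum)))
  }
  keep <- apply(tris <= n, 1, all)
  tris[keep, , drop = FALSE]
}

# Barycentric interpolation weights from scattered points onto query points.
# Returns a (n_query x n_points) sparse-in-spirit dense matrix; rows of
# queries outside the convex hull are all-zero.
.barycentric_weights <- function(pts, tris, qx, qy) {
  nq <- length(qx)
  W <- matrix(0, nq, nrow(pts))
  inside <- rep(FALSE, nq)
  tol <- -1e-9
  for (ti in seq_len(nrow(tris))) {
    v <- tris[ti, ]
    a <- pts[v[1], ]; b <- pts[v[2], ]; c <- pts[v[3], ]
    det <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    l1 <- ((b[2] - c[2]) * (qx - c[1]) + (c[1] - b[1]) * (qy - c[2])) / det
    l2 <- ((c[2] - a[2]) * (qx - c[1]) + (a[1] - c[1]) * (qy - c[2])) / det
    l3 <- 1 - l1 - l2
    hit <- !inside & l1 >= tol & l2 >= tol & l3 >= tol
    if (any(hit)) {
      W[hit, v[1]] <- pmax(l1[hit], 0)
      W[hit, v[2]] <- pmax(l2[hit], 0)
      W[hit, v[3]] <- pmax(l3[hit], 0)
      inside[hit] <- TRUE
    }
  }
  sums <- rowSums(W)
  W[inside, ] <- W[inside, , drop = FALSE] / sums[inside]
  attr(W, "inside") <- inside
  W
}

#' Precompute the scalp interpolation operator for a layout
#'
#' Builds the Delaunay triangulation of the electrode positions and the
#' piecewise-linear (barycentric) interpolation weights onto a regular
#' `grid_n` x `grid_n` node grid spanning the bounding square of the head
#' circle. Grid nodes outside the electrodes' convex hull are masked.
#'
#' @param layout A [montage_1020()] layout.
#' @param grid_n Nodes per grid side (default 32).
#' @return An object of class `scalp_interpolator`: weights `W`
#'   (n_unmasked x n_channels), logical `mask` (grid_n x grid_n),
#'   node coordinates, grid spacing and the layout.
#' @export
scalp_interpolator <- function(layout, grid_n = 32) {
  stopifnot(inherits(layout, "montage_layout"))
  pts <- layout$xy
  if (qr(cbind(1, pts))$rank < 3) {
    stop("need at least 3 non-collinear electrodes for interpolation")
  }
  tris <- .delaunay(pts)
  gx <- seq(-layout$head_radius, layout$head_radius, length.out = grid_n)
  gy <- gx
  nodes <- expand.grid(x = gx, y = gy)           # x varies fastest (rows)
  W <- .barycentric_weights(pts, tris, nodes$x, nodes$y)
  inside <- attr(W, "inside")
  structure(list(W = W[inside, , drop = FALSE],
                 mask = matrix(inside, grid_n, grid_n),
                 node_x = gx, node_y = gy,
                 node_xy = as.matrix(nodes)[inside, , drop = FALSE],
                 spacing = gx[2] - gx[1], grid_n = grid_n,
                 tris = tris, layout = layout),
            class = "scalp_interpolator")
}

.as_scalp_map <- function(values, interp, sigma = 0) {
  grid <- matrix(NA_real_, interp$grid_n, interp$grid_n)
  grid[interp$mask] <- values
  structure(list(grid = grid, mask = interp$mask, node_x = interp$node_x,
                 node_y = interp$node_y, spacing = interp$spacing,
                 smoothing_sigma = sigma, interp = interp),
            class = "scalp_map")
}

#' Interpolate per-channel values to a 2-D scalp map
#'
#' Piecewise-linear interpolation on the Delaunay triangulation of the
#' electrode positions; constants and linear fields are reproduced exactly
#' inside the convex hull, and nodes outside the hull are masked (no
#' extrapolation). If `values` is named it is matched to the layout's
#' labels, so channel ordering is immaterial.
#'
#' @param values Finite numeric vector, one value per layout channel.
#' @param layout A [montage_1020()] layout.
#' @param grid_n Grid nodes per side (default 32).
#' @param interp Optional precomputed [scalp_interpolator()] (overrides
#'   `layout` / `grid_n`).
#' @return An object of class `scalp_map` with fields `grid` (grid_n x
#'   grid_n, NA outside the mask), `mask`, node coordinates, `spacing` and
#'   `smoothing_sigma`.
#' @export
interpolate_map <- function(values, layout = montage_1020(), grid_n = 32,
                            interp = NULL) {
  if (is.null(interp)) interp <- scalp_interpolator(layout, grid_n)
  labs <- interp$layout$labels
  if (!is.null(names(values))) {
    if (!setequal(names(values), labs)) {
      stop("names(values) must match the layout's channel labels")
    }
    values <- values[labs]
  }
  if (length(values) != nrow(interp$layout$xy) || any(!is.finite(values))) {
    stop("values must be finite, one per layout channel")
  }
  .as_scalp_map(drop(interp$W %*% values), interp)
}

# Gaussian smoothing operator over the unmasked nodes (rows normalized so
# constants are preserved at the mask boundary)
.smoothing_operator <- function(interp, sigma) {
  xy <- interp$node_xy
  d2 <- outer(xy[, 1], xy[, 1], "-")^2 + outer(xy[, 2], xy[, 2], "-")^2
  G <- exp(-d2 / (2 * sigma^2))
  G / rowSums(G)
}

#' Smooth a scalp map with an isotropic Gaussian kernel
#'
#' Mask-normalized Gaussian convolution over the unmasked nodes: weights are
#' renormalized within the mask so constants are preserved at boundaries;
#' `sigma = 0` is the identity.
#'
#' @param map A `scalp_map`.
#' @param sigma Kernel standard deviation in mm (default 8).
#' @return The smoothed `scalp_map`.
#' @export
smooth_map <- function(map, sigma = 8) {
  stopifnot(inherits(map, "scalp_map"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(map)
  v <- map$grid[map$mask]
  sm <- drop(.smoothing_operator(map$interp, sigma) %*% v)
  out <- .as_scalp_map(sm, map$interp, sigma = sigma)
  out
}

#' @export
print.scalp_map <- function(x, ...) {
  cat(sprintf("Scalp map: %d x %d grid (%.2f mm spacing), %d nodes in mask, sigma = %g mm\n",
              nrow(x$grid), ncol(x$grid), x$spacing, sum(x$mask),
              x$smoothing_sigma))
  invisible(x)
}

#' @export
plot.scalp_map <- function(x, ...) {
  graphics::image(x$node_x, x$node_y, x$grid, asp = 1, xlab = "x (mm)",
                  ylab = "y (mm)", col = grDevices::hcl.colors(64, "RdBu",
                                                               rev = TRUE),
                  ...)
  lay <- x$interp$layout
  graphics::points(lay$xy, pch = 20, cex = 0.6)
  invisible(x)
}

#' Build the full channel-to-map linear operator for a cohort
#'
#' Interpolation followed by Gaussian smoothing is linear in the channel
#' values, so a cohort's maps can be produced with one matrix product. This
#' is the fast path used by the permutation machinery.
#'
#' @param layout A [montage_1020()] layout.
#' @param grid_n Grid nodes per side.
#' @param sigma Smoothing kernel SD in mm.
#' @return An object of class `scalp_mapper`: list with `M` (n_unmasked x
#'   n_channels operator) and the underlying `scalp_interpolator`.
#' @export
scalp_mapper <- function(layout = montage_1020(), grid_n = 32, sigma = 8) {
  interp <- scalp_interpolator(layout, grid_n)
  M <- interp$W
  if (sigma > 0) M <- .smoothing_operator(interp, sigma) %*% M
  structure(list(M = M, interp = interp, sigma = sigma),
            class = "scalp_mapper")
}

#' Per-subject smoothed scalp maps from per-channel shifts
#'
#' @param per_channel Subjects x channels matrix of per-channel log2 shifts
#'   (columns named with channel labels, or ordered as the layout).
#' @param mapper A [scalp_mapper()].
#' @return Subjects x nodes matrix of unmasked node values, with the mapper
#'   attached as attribute `mapper`.
#' @export
cohort_scalp_maps <- function(per_channel, mapper) {
  stopifnot(inherits(mapper, "scalp_mapper"))
  labs <- mapper$interp$layout$labels
  if (!is.null(colnames(per_channel))) {
    per_channel <- per_channel[, labs, drop = FALSE]
  }
  Y <- per_channel %*% t(mapper$M)
  attr(Y, "mapper") <- mapper
  Y
}
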