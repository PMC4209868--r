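#' Foveated view grid of visual angles
#'
#' A square grid of visual angles covering `+/- extent_deg` in each
#' direction. Spacing is closer near the center than in the periphery,
#' reflecting higher acuity near the fovea and guaranteeing that a few
#' rays intersect even the smallest shapes: with `n` evenly spaced points
#' `a` in `[-1, 1]`, the angles are `sign(a) * |a|^warp_exponent *
#' extent_deg`.
#'
#' @param n points per axis (even; default 16).
#' @param extent_deg maximum visual angle in degrees (default 10).
#' @param warp_exponent eccentricity warp (default 1.5; 1 gives uniform
#'   spacing).
#' @return A `view_grid` object with fields `n`, `extent_deg`,
#'   `warp_exponent`, and per-axis angle vectors `angles_x`, `angles_y`
#'   (degrees).
#' @export
build_grid <- function(n = 16L, extent_deg = 10, warp_exponent = 1.5) {
  stopifnot(n %% 2 == 0, extent_deg > 0, warp_exponent > 0)
  a <- seq(-1, 1, length.out = n)
  ang <- sign(a) * abs(a)^warp_exponent * extent_deg
  structure(list(n = as.integer(n), extent_deg = extent_deg,
                 warp_exponent = warp_exponent,
                 angles_x = ang, angles_y = ang),
            class = "view_grid")
}

## Unit ray directions for every grid point. The ray through visual
## angles (ax, ay) passes through the frontoparallel-plane point
## (D tan ax, D tan ay, D) at the fixation distance D.
grid_ray_directions <- function(grid, fixation = 0.75) {
  ax <- grid$angles_x * pi / 180
  ay <- grid$angles_y * pi / 180
  gx <- fixation * tan(ax)
  gy <- fixation * tan(ay)
  ## row index varies over y (vertical), column over x (horizontal)
  P <- cbind(rep(gx, each = grid$n), rep(gy, times = grid$n), fixation)
  P / sqrt(rowSums(P^2))
}

#' Depth along a single ray
#'
#' Distance from the viewpoint at the origin to the first intersection of
#' the ray at visual angles `(angle_x, angle_y)` with a superquadric
#' centered at `(0, 0, fixation)`. The intersection is bracketed by a
#' coarse march along the ray and refined by bisection. Depth is the
#' Euclidean distance along the ray, not the z coordinate.
#'
#' @param sq a [superquadric()] (canonical orientation recommended).
#' @param angle_x,angle_y visual angles in degrees.
#' @param fixation distance of the object center from the viewpoint
#'   (default 0.75 m).
#' @param t_range march interval along the ray, meters (default
#'   `c(0.6, 0.95)`).
#' @param n_march coarse march steps (default 512).
#' @param tol bisection tolerance in meters (default 1e-6).
#' @return Depth in meters, or `NA` for a miss.
#' @export
ray_depth <- function(sq, angle_x, angle_y, fixation = 0.75,
                      t_range = c(0.6, 0.95), n_march = 512L, tol = 1e-6) {
  ax <- angle_x * pi / 180; ay <- angle_y * pi / 180
  p <- c(fixation * tan(ax), fixation * tan(ay), fixation)
  d <- matrix(p / sqrt(sum(p^2)), nrow = 1L)
  depth <- ray_depths_batch(sq, d, fixation = fixation, t_range = t_range,
                            n_march = n_march, tol = tol)
  depth[1L]
}

## Vectorized ray casting: dirs is an m x 3 matrix of unit directions.
## Returns m depths (NA = miss). Finds the first crossing of F = 1 along
## each ray by coarse marching, then bisection to tol. Attribute
## "closest" holds, for every ray, the distance of closest approach to
## the surface (arg-min of F along the ray, parabolically refined) used
## as the continuous miss fill.
ray_depths_batch <- function(sq, dirs, fixation = 0.75,
                             t_range = c(0.6, 0.95), n_march = 512L,
                             tol = 1e-6) {
  stopifnot(inherits(sq, "superquadric"))
  m <- nrow(dirs)
  ts <- seq(t_range[1L], t_range[2L], length.out = n_march)
  R <- rotation_matrix(sq$theta[1L], sq$theta[2L], sq$theta[3L])
  center <- c(0, 0, fixation)
  ## object-frame representation of each ray: origin o = R(-center),
  ## direction u = R d; point at distance t is o + t u
  o <- as.numeric(R %*% (-center))
  U <- dirs %*% t(R)
  ## F at all march points (m x n_march)
  inv2e <- 2 / sq$eps
  Fmat <- 0
  for (k in 1:3) {
    coord <- outer(U[, k], ts) + o[k]
    Fmat <- Fmat + (abs(coord) / sq$A[k])^inv2e[k]
  }
  inside <- Fmat < 1
  first_in <- apply(inside, 1L, function(z) {
    w <- which(z); if (length(w)) w[1L] else NA_integer_
  })
  depth <- rep(NA_real_, m)
  hit <- which(!is.na(first_in) & first_in > 1L)
  ## rays already inside at the first march point: depth = t_range[1]
  depth[!is.na(first_in) & first_in == 1L] <- ts[1L]
  if (length(hit)) {
    lo <- ts[first_in[hit] - 1L]   # outside
    hi <- ts[first_in[hit]]        # inside
    Uh <- U[hit, , drop = FALSE]
    n_iter <- ceiling(log2((ts[2L] - ts[1L]) / tol)) + 1L
    for (it in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      Fm <- (abs(Uh[, 1L] * mid + o[1L]) / sq$A[1L])^inv2e[1L] +
            (abs(Uh[, 2L] * mid + o[2L]) / sq$A[2L])^inv2e[2L] +
            (abs(Uh[, 3L] * mid + o[3L]) / sq$A[3L])^inv2e[3L]
      in_mid <- Fm < 1
      hi[in_mid] <- mid[in_mid]
      lo[!in_mid] <- mid[!in_mid]
    }
    depth[hit] <- (lo + hi) / 2
  }
  ## closest approach along each ray: parabolic refinement of the F
  ## minimum over the march grid (exact for quadratic F, e.g. spheres)
  jstar <- max.col(-Fmat, ties.method = "first")
  jmid <- pmin(pmax(jstar, 2L), n_march - 1L)
  f0 <- Fmat[cbind(seq_len(m), jmid - 1L)]
  f1 <- Fmat[cbind(seq_len(m), jmid)]
  f2 <- Fmat[cbind(seq_len(m), jmid + 1L)]
  denom <- f0 - 2 * f1 + f2
  offs <- ifelse(abs(denom) > 1e-300, (f0 - f2) / (2 * denom), 0)
  offs <- pmin(pmax(offs, -1), 1)
  dt <- ts[2L] - ts[1L]
  attr(depth, "closest") <- ts[jmid] + offs * dt
  depth
}

#' Render an observer-centered depth map
#'
#' Casts one ray per grid point from the viewpoint at the origin toward a
#' superquadric centered at `(0, 0, fixation)` and records the Euclidean
#' distance to the first surface intersection. Rays that miss the object
#' need a fill value; two conventions are available:
#'
#' * `fill = "closest"` (default): the distance along the ray at its
#'   closest approach to the object surface. This extension is
#'   continuous at silhouettes — as a shape grows through tangency with
#'   a ray, the fill converges to the grazing depth — so depth maps (and
#'   their derivative features) vary continuously with shape parameters,
#'   the property the geodesic shape embedding relies on.
#' * `fill = "plane"`: the distance along the ray to a background
#'   frontoparallel plane at `z = background_z`. Simple figure/ground
#'   contrast, but discontinuous at silhouettes (a newly acquired pixel
#'   jumps from the plane to the grazing depth).
#'
#' @param sq a [superquadric()].
#' @param grid a [build_grid()] view grid.
#' @param fixation object-center distance, meters (default 0.75).
#' @param fill miss-fill convention, `"closest"` or `"plane"`.
#' @param background_z depth of the background plane for
#'   `fill = "plane"`, meters (default 0.9).
#' @param ... further arguments passed to the ray caster
#'   (`t_range`, `n_march`, `tol`).
#' @return A `depth_map` object: `values` (n-by-n matrix of distances in
#'   meters; rows index the vertical grid axis), `hit` (logical matrix),
#'   `grid`, `background_z`.
#' @examples
#' dm <- render_depth(superquadric(A = rep(0.05, 3), eps = c(1, 1, 1),
#'                                 label = "sphere-like"), build_grid())
#' dm$values[8, 8]  # close to 0.70 m
#' @export
render_depth <- function(sq, grid = build_grid(), fixation = 0.75,
                         fill = c("closest", "plane"),
                         background_z = 0.9, ...) {
  fill <- match.arg(fill)
  dirs <- grid_ray_directions(grid, fixation)
  depth <- ray_depths_batch(sq, dirs, fixation = fixation, ...)
  bg <- if (fill == "plane") background_z / dirs[, 3L]
        else attr(depth, "closest")
  hit <- !is.na(depth)
  depth[!hit] <- bg[!hit]
  attr(depth, "closest") <- NULL
  structure(list(values = matrix(depth, grid$n, grid$n),
                 hit = matrix(hit, grid$n, grid$n),
                 grid = grid, fixation = fixation, fill = fill,
                 background_z = background_z),
            class = "depth_map")
}

#' Render depth maps for every row of a shape table
#'
#' @param db a `shape_db` or `stimulus_set` (any data frame with the nine
#'   parameter columns and `label`).
#' @param grid a [build_grid()] view grid.
#' @param ... passed to [render_depth()].
#' @return A numeric matrix with one row per shape and `n * n` columns
#'   (column-major flattening of each depth map).
#' @export
render_database <- function(db, grid = build_grid(), ...) {
  out <- matrix(NA_real_, nrow(db), grid$n * grid$n)
  for (i in seq_len(nrow(db)))
    out[i, ] <- as.numeric(render_depth(db_shape(db, i), grid, ...)$values)
  out
}
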