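## 3x3 correlation with replicate padding, same-size output, applied in
## grid-index space (the maps are filtered directly; no rescaling by the
## warped angular spacing). K[u, v] multiplies z(i + u - 2, j + v - 2).
filter3 <- function(z, K) {
  n <- nrow(z); m <- ncol(z)
  zp <- z[c(1L, 1:n, n), c(1L, 1:m, m)]  # replicate pad
  out <- matrix(0, n, m)
  for (u in 1:3) for (v in 1:3) {
    if (K[u, v] == 0) next
    out <- out + K[u, v] * zp[u:(u + n - 1L), v:(v + m - 1L)]
  }
  out
}

## Separable derivative kernels (correlation orientation): [1 1 1]^T
## smooths across the other axis; [1 0 -1] responds positively to depth
## decreasing with increasing index; [0.5 -1 0.5] is the second
## difference.
kernel_d1 <- function() matrix(1, 3, 1) %*% matrix(c(1, 0, -1), 1, 3)
kernel_d2 <- function() matrix(1, 3, 1) %*% matrix(c(0.5, -1, 0.5), 1, 3)

#' CIP-like feature stack of a depth map
#'
#' Stacks the depth map with its horizontal and vertical first and second
#' spatial derivatives, approximated by correlating with separable 3x3
#' kernels (`[1 1 1]^T [1 0 -1]` for first derivatives and
#' `[1 1 1]^T [0.5 -1 0.5]` for second derivatives, plus their
#' transposes), with replicate padding and same-size output. Kernels act
#' in grid-index space. Channel order is fixed: depth `z`, `dz/dx`,
#' `dz/dy`, `d2z/dx2`, `d2z/dy2`; "x" is the horizontal (column) grid
#' axis.
#'
#' @param dm a `depth_map` from [render_depth()], or a bare numeric
#'   matrix.
#' @return A `feature_stack`: list of the five n-by-n channel matrices
#'   with class attribute; flatten with [flatten_stack()].
#' @export
derivative_stack <- function(dm) {
  z <- if (inherits(dm, "depth_map")) dm$values else dm
  stopifnot(is.matrix(z), all(is.finite(z)))
  k1 <- kernel_d1(); k2 <- kernel_d2()
  structure(list(z = z,
                 dx = filter3(z, k1),
                 dy = filter3(z, t(k1)),
                 dxx = filter3(z, k2),
                 dyy = filter3(z, t(k2))),
            class = "feature_stack")
}

#' Flatten a feature stack to a numeric vector
#'
#' Channels are concatenated in the fixed order `z, dx, dy, dxx, dyy`,
#' each channel flattened column-major. For the default 16x16 grid the
#' result has `16 * 16 * 5 = 1280` values. This ordering is the network
#' input contract.
#'
#' @param stack a `feature_stack`.
#' @param channels which channels to include (default all five).
#' @return numeric vector of length `n * n * length(channels)`.
#' @export
flatten_stack <- function(stack, channels = c("z", "dx", "dy", "dxx", "dyy")) {
  stopifnot(all(channels %in% names(stack)))
  unlist(lapply(stack[channels], as.numeric), use.names = FALSE)
}

#' Feature matrix for a set of rendered depth maps
#'
#' @param depth_rows matrix from [render_database()] (one flattened
#'   depth map per row).
#' @param n grid points per axis (default 16).
#' @param channels channels to include; the Isomap uses the four
#'   derivative channels (`c("dx","dy","dxx","dyy")`, 1024 values at
#'   n = 16), the networks all five (1280 values).
#' @return numeric matrix, one row per shape.
#' @export
feature_matrix <- function(depth_rows, n = 16L,
                           channels = c("z", "dx", "dy", "dxx", "dyy")) {
  out <- matrix(NA_real_, nrow(depth_rows), n * n * length(channels))
  for (i in seq_len(nrow(depth_rows))) {
    st <- derivative_stack(matrix(depth_rows[i, ], n, n))
    out[i, ] <- flatten_stack(st, channels)
  }
  out
}

#' Curved-surface stimulus depth
#'
#' The curved surfaces used to probe curvature tuning have depth
#' `z = (K1 x^2 + K2 y^2) / 2`.
#'
#' @param K1,K2 principal curvature parameters (1/m).
#' @param x,y surface coordinates (meters); vectors or matrices.
#' @return depth `z` (same shape as `x`/`y`).
#' @export
surface_depth <- function(K1, K2, x, y) (K1 * x^2 + K2 * y^2) / 2

#' Principal curvature along x of a parametric depth field
#'
#' `Kx = (d2z/dx2) / (1 + (dz/dx)^2)^(3/2)`. At the center of a
#' [surface_depth()] stimulus `dz/dx = 0`, so `Kx = d2z/dx2 = K1`.
#'
#' @param dzdx first derivative of depth along x at the evaluation point.
#' @param d2zdx2 second derivative of depth along x.
#' @return curvature `Kx` (1/m).
#' @export
principal_curvature_x <- function(dzdx, d2zdx2) {
  d2zdx2 / (1 + dzdx^2)^1.5
}

#' Curvedness and shape index
#'
#' The polar decomposition of the two principal curvatures:
#' `C = sqrt((Kmax^2 + Kmin^2) / 2)` measures magnitude and
#' `SI = (2/pi) * atan((Kmax + Kmin) / (Kmax - Kmin))` the shape class in
#' `[-1, 1]`, where `Kmax`/`Kmin` are the larger and smaller of the two
#' inputs. A symmetric cap (`K1 = K2`) takes the limit `SI = +/-1`
#' (sign of the common curvature).
#'
#' @param K1,K2 principal curvature parameters (1/m); vectorized.
#' @return `curvedness`: `C >= 0`; `shape_index`: `SI` in `[-1, 1]`.
#' @export
curvedness <- function(K1, K2) {
  kmax <- pmax(K1, K2); kmin <- pmin(K1, K2)
  sqrt((kmax^2 + kmin^2) / 2)
}

#' @rdname curvedness
#' @export
shape_index <- function(K1, K2) {
  kmax <- pmax(K1, K2); kmin <- pmin(K1, K2)
  num <- kmax + kmin; den <- kmax - kmin
  si <- ifelse(den == 0, sign(num), (2 / pi) * atan(num / den))
  ifelse(den == 0 & num == 0, 0, si)
}

#' Expanded nonlinear tuning variables
#'
#' Appends the channels `(3 X^2 - 1) / 2` and `(3 Y^2 - 1) / 2` computed
#' elementwise from the second-derivative channels `X = d2z/dx2` and
#' `Y = d2z/dy2`. These are the nonlinear functions whose linear
#' reconstruction from populations of LIF neurons tuned to `X` and `Y` is
#' most accurate, which motivates offering them as extra tuning variables
#' for curvature-selective cells.
#'
#' @param stack a `feature_stack`.
#' @return The stack with two extra channels `leg_x`, `leg_y`.
#' @export
legendre_expand <- function(stack) {
  stopifnot(inherits(stack, "feature_stack"))
  stack$leg_x <- (3 * stack$dxx^2 - 1) / 2
  stack$leg_y <- (3 * stack$dyy^2 - 1) / 2
  stack
}

#' Disparity-tuned channels modeled on V3A response classes
#'
#' Applies seven pointwise nonlinear functions of depth, modeled on the
#' classical disparity-tuning classes: five Gaussians ("tuned near",
#' "tuned zero", "tuned far" and neighbors) with centers spread around
#' the fixation depth, and two complementary sigmoids ("near" and "far")
#' centered at fixation. The near and far sigmoids sum to 1 at every
#' depth.
#'
#' @param dm a `depth_map` or numeric matrix of depths (meters).
#' @param centers Gaussian centers in meters (default
#'   `c(0.65, 0.70, 0.75, 0.80, 0.85)`).
#' @param sd Gaussian width in meters (default 0.05).
#' @param sigmoid_center sigmoid midpoint in meters (default 0.75).
#' @param sigmoid_slope sigmoid slope in 1/m (default 25; the near
#'   channel uses `-slope`).
#' @return A `v3a_stack`: list of 7 matrices, channels
#'   `gauss_1..gauss_5, near, far`.
#' @export
v3a_channels <- function(dm, centers = c(0.65, 0.70, 0.75, 0.80, 0.85),
                         sd = 0.05, sigmoid_center = 0.75,
                         sigmoid_slope = 25) {
  z <- if (inherits(dm, "depth_map")) dm$values else dm
  stopifnot(is.matrix(z), length(centers) == 5L)
  ch <- lapply(centers, function(c0) exp(-(z - c0)^2 / (2 * sd^2)))
  names(ch) <- paste0("gauss_", seq_along(centers))
  ch$near <- 1 / (1 + exp(sigmoid_slope * (z - sigmoid_center)))
  ch$far <- 1 / (1 + exp(-sigmoid_slope * (z - sigmoid_center)))
  structure(ch, class = "v3a_stack")
}
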