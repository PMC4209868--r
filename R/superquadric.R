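#' Superquadric shapes
#'
#' A superquadric is described by nine free parameters: three semi-axis
#' scales `A` (meters), three shape exponents `eps` (dimensionless; values
#' near 0 give squared edges, values near 1 rounded edges), and three
#' rotation angles `theta` (radians). The implicit surface is the level set
#' `F = 1` of the inside-outside function
#' \deqn{F(x,y,z) = (|x|/A_1)^{2/\epsilon_1} + (|y|/A_2)^{2/\epsilon_2} +
#'   (|z|/A_3)^{2/\epsilon_3},}
#' with `F < 1` inside and `F > 1` outside. A sphere of radius `A` has
#' `A1 = A2 = A3 = A` and all exponents equal to 1.
#'
#' @param A numeric length-3; semi-axis scales in meters, all > 0. The
#'   object's width along axis i is `2 * A[i]`.
#' @param eps numeric length-3; shape exponents, all > 0.
#' @param theta numeric length-3; rotation angles in radians (see
#'   [rotation_matrix()]).
#' @param label shape class, one of `"sphere-like"`, `"box-like"`,
#'   `"cylinder-like"`, `"plate-like"`.
#' @return An object of class `superquadric`.
#' @examples
#' sq <- superquadric(A = c(0.05, 0.05, 0.05), eps = c(1, 1, 1))
#' inside_outside(c(0.05, 0, 0), sq)  # 1: on the surface
#' @export
superquadric <- function(A, eps = c(1, 1, 1), theta = c(0, 0, 0),
                         label = c("box-like", "sphere-like",
                                   "cylinder-like", "plate-like")) {
  label <- match.arg(label)
  A <- as.numeric(A); eps <- as.numeric(eps); theta <- as.numeric(theta)
  if (length(A) != 3L || length(eps) != 3L || length(theta) != 3L)
    stop("A, eps and theta must each have length 3")
  if (any(!is.finite(A)) || any(A <= 0))
    stop("invalid parameter: semi-axis scales A must be positive and finite")
  if (any(!is.finite(eps)) || any(eps <= 0))
    stop("invalid parameter: exponents eps must be positive and finite")
  if (any(!is.finite(theta)))
    stop("invalid parameter: angles theta must be finite")
  structure(list(A = A, eps = eps, theta = theta, label = label),
            class = "superquadric")
}

#' @export
print.superquadric <- function(x, ...) {
  cat("superquadric [", x$label, "]\n", sep = "")
  cat(sprintf("  A     = (%.4f, %.4f, %.4f) m\n", x$A[1], x$A[2], x$A[3]))
  cat(sprintf("  eps   = (%.3f, %.3f, %.3f)\n", x$eps[1], x$eps[2], x$eps[3]))
  cat(sprintf("  theta = (%.4f, %.4f, %.4f) rad\n",
              x$theta[1], x$theta[2], x$theta[3]))
  invisible(x)
}

#' Inside-outside function of a superquadric
#'
#' Evaluates `F` at points given in object-centered, object-aligned
#' coordinates (no rotation is applied here; see [sq_implicit_world()] for
#' world-frame evaluation).
#'
#' @param point numeric length-3 vector, or an n-by-3 matrix of points
#'   (meters, object frame).
#' @param sq a [superquadric()].
#' @return `F` values; `F < 1` inside, `F = 1` on the surface, `F > 1`
#'   outside.
#' @export
inside_outside <- function(point, sq) {
  stopifnot(inherits(sq, "superquadric"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3L)
  if (ncol(p) != 3L) stop("point must have 3 columns")
  f <- (abs(p[, 1L]) / sq$A[1L])^(2 / sq$eps[1L]) +
       (abs(p[, 2L]) / sq$A[2L])^(2 / sq$eps[2L]) +
       (abs(p[, 3L]) / sq$A[3L])^(2 / sq$eps[3L])
  if (is.matrix(point)) f else as.numeric(f)
}

#' Rotation matrix of a superquadric
#'
#' The orientation convention used throughout the package: a world-frame
#' point `p` is mapped into the object frame by `R %*% (p - center)`.
#'
#' @param theta1,theta2,theta3 rotation angles in radians.
#' @return A 3-by-3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(theta1, theta2, theta3) {
  c1 <- cos(theta1); s1 <- sin(theta1)
  c2 <- cos(theta2); s2 <- sin(theta2)
  c3 <- cos(theta3); s3 <- sin(theta3)
  matrix(c(
    c2 * c3,  c1 * s3 + s1 * s2 * c3,  s1 * s3 - c1 * s2 * c3,
    -c2 * s3, c1 * c3 - s1 * s2 * s3,  s1 * c3 + c1 * s2 * s3,
    s2,       -s1 * c2,                c1 * c2
  ), nrow = 3L, byrow = TRUE)
}

## Recover (theta1, theta2, theta3) from a rotation matrix in the
## package's convention. Gimbal-locked matrices (|cos(theta2)| ~ 0) get
## theta3 = 0 by convention.
angles_from_rotation <- function(R) {
  s2 <- max(-1, min(1, R[3L, 1L]))
  theta2 <- asin(s2)
  if (abs(cos(theta2)) > 1e-9) {
    theta1 <- atan2(-R[3L, 2L], R[3L, 3L])
    theta3 <- atan2(-R[2L, 1L], R[1L, 1L])
  } else {
    theta3 <- 0
    if (s2 > 0) theta1 <- atan2(R[1L, 2L], R[2L, 2L])
    else        theta1 <- atan2(-R[1L, 2L], R[2L, 2L])
  }
  c(theta1, theta2, theta3)
}

#' Evaluate the implicit function in world coordinates
#'
#' Applies the object's rotation and center offset, then evaluates
#' [inside_outside()].
#'
#' @param points n-by-3 matrix of world-frame points (meters).
#' @param sq a [superquadric()].
#' @param center world position of the object center (default
#'   `c(0, 0, 0.75)`, the fixation distance used for rendering).
#' @return numeric vector of `F` values.
#' @export
sq_implicit_world <- function(points, sq, center = c(0, 0, 0.75)) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  R <- rotation_matrix(sq$theta[1L], sq$theta[2L], sq$theta[3L])
  q <- sweep(points, 2L, center) %*% t(R)
  as.numeric(inside_outside(q, sq))
}

## The 24 proper signed-permutation matrices (the rotation group of the
## cube). Used to enumerate box-like parameter relabelings.
octahedral_rotations <- function() {
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- list()
  for (p in perms) {
    for (k in seq_len(nrow(signs))) {
      S <- matrix(0, 3L, 3L)
      for (i in 1:3) S[i, p[i]] <- signs[k, i]
      if (abs(det(S) - 1) < 1e-12) out[[length(out) + 1L]] <- S
    }
  }
  out
}

.pkg_cache <- new.env(parent = emptyenv())

get_octahedral_rotations <- function() {
  if (is.null(.pkg_cache$oct))
    .pkg_cache$oct <- octahedral_rotations()
  .pkg_cache$oct
}

#' Canonicalize a superquadric's orientation parameters
#'
#' Several parameter vectors can describe the same surface: every
#' superquadric is symmetric under half-turns about its own axes, box-like
#' shapes are additionally equivalent under axis relabelings (with the
#' matching permutation of scales and exponents), cylinder-like shapes are
#' rotationally symmetric about their long axis, and sphere-like shapes are
#' fully rotationally symmetric. `canonicalize` maps any parameter vector
#' to a unique representative so that the shape-to-depth-map function
#' becomes invertible within each class:
#'
#' * sphere-like: angles set to `(0, 0, 0)`;
#' * cylinder-like: the axis direction is reduced to a hemisphere and
#'   expressed with `theta3 = 0`, `theta1, theta2` in `[-pi/2, pi/2]`;
#' * box-like / plate-like: all 24 axis relabelings are enumerated and the
#'   representative with the smallest maximum absolute angle is kept
#'   (angles near the restricted range `[-pi/4, pi/4]`), relabeling `A` and
#'   `eps` accordingly.
#'
#' The mapping is idempotent and preserves the rendered surface.
#'
#' @param sq a [superquadric()].
#' @return An equivalent, canonical [superquadric()].
#' @export
canonicalize <- function(sq) {
  stopifnot(inherits(sq, "superquadric"))
  if (sq$label == "sphere-like") {
    sq$theta <- c(0, 0, 0)
    return(sq)
  }
  if (sq$label == "cylinder-like") {
    R <- rotation_matrix(sq$theta[1L], sq$theta[2L], sq$theta[3L])
    u <- R[3L, ]  # world direction of the object's z (long) axis
    ## reduce axis to a hemisphere (u and -u describe the same line)
    if (u[3L] < 0 || (abs(u[3L]) < 1e-12 &&
                      (u[2L] < 0 || (abs(u[2L]) < 1e-12 && u[1L] < 0))))
      u <- -u
    theta2 <- asin(max(-1, min(1, u[1L])))
    theta1 <- atan2(-u[2L], u[3L])
    sq$theta <- c(theta1, theta2, 0)
    return(sq)
  }
  ## box-like / plate-like: enumerate the cube rotation group
  R <- rotation_matrix(sq$theta[1L], sq$theta[2L], sq$theta[3L])
  best <- NULL
  for (S in get_octahedral_rotations()) {
    Rp <- t(S) %*% R
    th <- angles_from_rotation(Rp)
    sigma <- apply(abs(S) > 0.5, 1L, which)  # S[i, sigma(i)] != 0
    Ap <- numeric(3L); Ep <- numeric(3L)
    Ap[sigma] <- sq$A; Ep[sigma] <- sq$eps
    key <- c(max(abs(th)), round(th, 9), round(Ap, 9))
    if (is.null(best) || lex_less(key, best$key))
      best <- list(key = key, theta = th, A = Ap, eps = Ep)
  }
  superquadric(A = best$A, eps = best$eps, theta = best$theta,
               label = sq$label)
}

## strict lexicographic comparison of numeric keys (with tolerance on the
## leading max-angle entry so near-ties break on the remaining entries)
lex_less <- function(a, b, tol = 1e-9) {
  for (i in seq_along(a)) {
    t <- if (i == 1L) tol else 0
    if (a[i] < b[i] - t) return(TRUE)
    if (a[i] > b[i] + t) return(FALSE)
  }
  FALSE
}
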