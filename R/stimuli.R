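#' Base shapes for the augmented tuning-curve stimulus set
#'
#' Four graspable base shapes — sphere, cube, plate, cylinder — at their
#' reference (largest) size. Dimensions keep every semi-axis within
#' `[0.01, 0.06]` m across the four size scalings.
#'
#' @return Named list of [superquadric()] objects.
#' @export
base_stimulus_shapes <- function() {
  list(
    sphere   = superquadric(A = c(0.04, 0.04, 0.04), eps = c(1, 1, 1),
                            label = "sphere-like"),
    cube     = superquadric(A = c(0.04, 0.04, 0.04), eps = c(0.05, 0.05, 0.05),
                            label = "box-like"),
    plate    = superquadric(A = c(0.06, 0.06, 0.02), eps = c(0.05, 0.05, 0.05),
                            label = "plate-like"),
    cylinder = superquadric(A = c(0.02, 0.02, 0.06), eps = c(1, 1, 0.05),
                            label = "cylinder-like"))
}

## Pose realizations. Each base shape has a distinguished object z axis
## (cylinder: long axis; plate: thin/normal axis; cube/sphere: arbitrary).
## Poses: 1 horizontal, 2 vertical, 3 tilted forward 45 deg,
## 4 tilted backward 45 deg. Angles are rotations in the package's
## convention (see rotation_matrix); tilts rotate about the horizontal
## x axis, "horizontal" points the distinguished axis along world x.
pose_theta <- function(shape_name, pose) {
  if (shape_name == "sphere") return(c(0, 0, 0))
  if (shape_name == "cube") {
    ## upright cube; pose 2 (vertical) is a quarter turn, poses 3/4 tilts
    return(switch(pose, c(0, 0, 0), c(pi / 2, 0, 0),
                  c(pi / 4, 0, 0), c(-pi / 4, 0, 0)))
  }
  ## cylinder (long axis = object z) and plate (normal = object z):
  ## horizontal: axis along world x; vertical: axis along world y;
  ## tilts: +/-45 deg from vertical in the y-z plane.
  ## For the plate the distinguished axis is its normal, so "horizontal"
  ## has the normal vertical (plate lying flat) and "vertical" has the
  ## normal toward the viewer (plate standing, facing the observer).
  if (shape_name == "cylinder") {
    return(switch(pose, c(0, pi / 2, 0), c(pi / 2, 0, 0),
                  c(pi / 4, 0, 0), c(-pi / 4, 0, 0)))
  }
  if (shape_name == "plate") {
    return(switch(pose, c(pi / 2, 0, 0), c(0, 0, 0),
                  c(pi / 4, 0, 0), c(-pi / 4, 0, 0)))
  }
  stop("unknown base shape: ", shape_name)
}

## Orientation-duplicate ruleset implied by each base shape's rotational
## symmetry: value = pose kept as representative (NA = pose is distinct).
## sphere: all poses equivalent (1 kept); cube: a quarter turn maps
## horizontal to vertical and tilt-forward to tilt-backward (2 kept);
## plate/cylinder: only the two tilts are equivalent (3 kept).
pose_duplicate_map <- function(shape_name) {
  switch(shape_name,
         sphere   = c(NA, 1L, 1L, 1L),
         cube     = c(NA, 1L, NA, 3L),
         plate    = c(NA, NA, NA, 3L),
         cylinder = c(NA, NA, NA, 3L),
         stop("unknown base shape: ", shape_name))
}

#' Enumerate the augmented tuning-curve stimulus set
#'
#' Builds the grid of base shapes x sizes x orientations (horizontal,
#' vertical, tilted forward 45 degrees, tilted backward 45 degrees) and
#' removes orientations that each shape's rotational symmetry makes
#' redundant: all four poses of a sphere are the same stimulus, a cube
#' keeps 2 of 4 (horizontal = vertical and the two tilts coincide under a
#' quarter turn), and plate and cylinder each keep 3 of 4 (the two tilts
#' are equivalent). With the default 4 x 4 x 4 design this yields exactly
#' 36 stimuli. Sizes scale all three semi-axes uniformly.
#'
#' @param shapes named list of base shapes (default
#'   [base_stimulus_shapes()]); names must be `sphere`, `cube`, `plate`,
#'   `cylinder`.
#' @param sizes numeric vector of uniform scale factors, default
#'   `c(3, 4, 5, 6) / 6` (largest = reference size).
#' @param poses integer pose ids to consider, default `1:4`.
#' @return A `stimulus_set` data frame: one row per distinct stimulus with
#'   `shape`, `shape_id`, `size_id`, `orient_id`, `pose_angle_deg`, the
#'   nine superquadric parameters and `label`. The removed duplicates and
#'   the representative each maps to are kept in attribute `duplicates`.
#' @examples
#' stim <- enumerate_stimuli()
#' nrow(stim)  # 36
#' @export
enumerate_stimuli <- function(shapes = base_stimulus_shapes(),
                              sizes = c(3, 4, 5, 6) / 6,
                              poses = 1:4) {
  stopifnot(all(names(shapes) %in% c("sphere", "cube", "plate", "cylinder")))
  ## pose angle (deg) used as the 1-axis orientation coordinate in tuning
  ## features: vertical = 0, horizontal = 90, tilts = +/-45.
  pose_angle <- c(90, 0, 45, -45)
  rows <- list(); dups <- list()
  for (si in seq_along(shapes)) {
    nm <- names(shapes)[si]
    base <- shapes[[nm]]
    dup <- pose_duplicate_map(nm)
    for (zi in seq_along(sizes)) {
      A <- base$A * sizes[zi]
      for (po in poses) {
        row <- data.frame(
          shape = nm, shape_id = si, size_id = zi, orient_id = po,
          pose_angle_deg = pose_angle[po], size_scale = sizes[zi],
          A1 = A[1], A2 = A[2], A3 = A[3],
          eps1 = base$eps[1], eps2 = base$eps[2], eps3 = base$eps[3],
          theta1 = pose_theta(nm, po)[1], theta2 = pose_theta(nm, po)[2],
          theta3 = pose_theta(nm, po)[3],
          label = base$label)
        if (is.na(dup[po])) {
          rows[[length(rows) + 1L]] <- row
        } else if (!is.na(dup[po])) {
          row$kept_orient_id <- dup[po]
          dups[[length(dups) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "duplicates") <- if (length(dups)) do.call(rbind, dups) else NULL
  class(out) <- c("stimulus_set", "data.frame")
  out
}

#' Extract one stimulus as a superquadric
#'
#' @param stim a `stimulus_set` (or its `duplicates` attribute).
#' @param i row index.
#' @return A [superquadric()].
#' @export
stimulus_shape <- function(stim, i) db_shape(stim, i)

## Depth-map comparison up to the viewing-ensemble grid symmetries.
## Orientation duplicates removed by enumerate_stimuli are congruent to
## their representative via the identity or a half-turn about the viewing
## axis; combined with the stimuli's own left-right mirror symmetry this
## group is {identity, left-right flip, up-down flip, 180-deg rotation}.
depth_map_discrepancy <- function(v1, v2) {
  m2 <- list(v2,
             v2[nrow(v2):1, , drop = FALSE],
             v2[, ncol(v2):1, drop = FALSE],
             v2[nrow(v2):1, ncol(v2):1, drop = FALSE])
  min(vapply(m2, function(m) max(abs(v1 - m)), numeric(1)))
}

#' Verify the stimulus symmetry ruleset with the renderer
#'
#' Renders every orientation duplicate removed by [enumerate_stimuli()]
#' together with its kept representative and measures the residual
#' depth-map discrepancy under the viewing-ensemble grid symmetries
#' (identity, left-right flip, up-down flip, half-turn). Also checks that
#' stimuli kept as distinct do **not** match under those symmetries.
#'
#' @param stim a `stimulus_set` from [enumerate_stimuli()].
#' @param grid a [build_grid()] view grid.
#' @param tol match tolerance in meters (default `1e-6`).
#' @return List with `max_duplicate_discrepancy` (meters; should be below
#'   `tol`), `min_distinct_discrepancy` (should be well above `tol`),
#'   `n_duplicates_checked`, `n_distinct_checked` and `count`
#'   (`nrow(stim)`).
#' @export
verify_stimulus_symmetries <- function(stim, grid = build_grid(), tol = 1e-6) {
  dups <- attr(stim, "duplicates")
  maps <- new.env(parent = emptyenv())
  render_key <- function(row) {
    key <- paste(row$shape_id, row$size_id, row$orient_id, sep = "_")
    if (is.null(maps[[key]]))
      maps[[key]] <- render_depth(db_shape(row, 1L), grid)$values
    maps[[key]]
  }
  max_dup <- 0; n_dup <- 0L
  if (!is.null(dups)) {
    for (i in seq_len(nrow(dups))) {
      removed <- dups[i, , drop = FALSE]
      kept <- stim[stim$shape_id == removed$shape_id &
                   stim$size_id == removed$size_id &
                   stim$orient_id == removed$kept_orient_id, , drop = FALSE]
      d <- depth_map_discrepancy(render_depth(db_shape(removed, 1L),
                                              grid)$values,
                                 render_key(kept))
      max_dup <- max(max_dup, d)
      n_dup <- n_dup + 1L
    }
  }
  ## distinct stimuli must not collapse: compare all kept pairs within the
  ## same shape and size
  min_dist <- Inf; n_dist <- 0L
  for (si in unique(stim$shape_id)) {
    for (zi in unique(stim$size_id)) {
      sel <- which(stim$shape_id == si & stim$size_id == zi)
      if (length(sel) < 2L) next
      for (a in seq_along(sel)) {
        for (b in seq_len(a - 1L)) {
          d <- depth_map_discrepancy(render_key(stim[sel[a], , drop = FALSE]),
                                     render_key(stim[sel[b], , drop = FALSE]))
          min_dist <- min(min_dist, d)
          n_dist <- n_dist + 1L
        }
      }
    }
  }
  list(max_duplicate_discrepancy = max_dup,
       min_distinct_discrepancy = min_dist,
       n_duplicates_checked = n_dup,
       n_distinct_checked = n_dist,
       count = nrow(stim))
}

#' Stimulus feature vectors for cosine-tuning fits
#'
#' Encodes each stimulus as the vector over which AIP-model neurons are
#' cosine tuned. For the augmented stimulus set the rotation is about one
#' axis only, so the orientation is encoded as a 2D direction vector
#' `(cos psi, sin psi)` of the pose angle `psi` instead of the raw angle,
#' avoiding wrap-around discontinuities. Together with three scales and
#' three exponents this gives an 8-dimensional stimulus space.
#'
#' @param stim a `stimulus_set`.
#' @param scale if `TRUE` (default), columns are affinely mapped to
#'   `[-1, 1]` over the set (per-column min/max), keeping the fitted
#'   preferred-direction components comparable across units.
#' @return numeric matrix, one row per stimulus.
#' @export
stimulus_features <- function(stim, scale = TRUE) {
  psi <- stim$pose_angle_deg * pi / 180
  X <- cbind(stim$A1, stim$A2, stim$A3, stim$eps1, stim$eps2, stim$eps3,
             cos(psi), sin(psi))
  colnames(X) <- c("A1", "A2", "A3", "eps1", "eps2", "eps3",
                   "cos_psi", "sin_psi")
  if (scale) {
    lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
    span <- ifelse(hi - lo < 1e-12, 1, hi - lo)
    X <- sweep(sweep(X, 2L, (lo + hi) / 2), 2L, span / 2, "/")
  }
  X
}
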