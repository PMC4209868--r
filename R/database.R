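#' Sample the squared-edge exponent distribution
#'
#' Squared edges use exponents drawn from a shifted exponential density
#' `p(e) = 10 H(e - eta) exp(-(e - eta)/0.1)` with `eta = 0.01`, where `H`
#' is the Heaviside step. The shift away from 0 (perfectly sharp corners)
#' avoids numerical problems in the implicit surface. The mean is
#' `eta + 0.1 = 0.11`.
#'
#' @param n number of draws.
#' @param eta shift (minimum exponent), default 0.01.
#' @param scale exponential scale, default 0.1.
#' @return numeric vector of exponents, all `>= eta`.
#' @export
sample_edge_exponent <- function(n, eta = 0.01, scale = 0.1) {
  eta + stats::rexp(n, rate = 1 / scale)
}

#' Generate a database of random superquadric shapes
#'
#' Emulates the shape database used to train and validate the CIP-to-AIP
#' mapping networks: box-like, sphere-like and cylinder-like shapes in
#' roughly equal numbers, semi-axis scales uniform on `[0.01, 0.06]` m
#' (widths 0.02-0.12 m), squared edges drawn from
#' [sample_edge_exponent()], round edges fixed at 1, and random rotations
#' drawn uniformly per angle over each class's canonical range (rotations
#' that symmetry makes redundant are not sampled). Each shape has nine
#' free parameters. The database is split 70/30 into train and validation
#' sets.
#'
#' @param n number of shapes (`>= 1`).
#' @param seed integer RNG seed; the database is reproducible from it.
#' @param class_mix named proportions for `box`, `sphere`, `cylinder`
#'   (default equal).
#' @param train_frac fraction assigned to the training split (default 0.7).
#' @return A `shape_db` object: a data frame with columns `A1..A3`,
#'   `eps1..eps3`, `theta1..theta3`, `label`, `split`, plus attributes
#'   `seed` and `class_mix`.
#' @examples
#' db <- sample_database(30, seed = 1)
#' table(db$label)
#' @export
sample_database <- function(n, seed = 1L,
                            class_mix = c(box = 1, sphere = 1, cylinder = 1) / 3,
                            train_frac = 0.7) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("invalid argument: n must be >= 1")
  n <- as.integer(n)
  stopifnot(all(c("box", "sphere", "cylinder") %in% names(class_mix)))
  class_mix <- class_mix / sum(class_mix)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  ## largest-remainder apportionment of class counts
  raw <- n * class_mix[c("box", "sphere", "cylinder")]
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }

  blocks <- list()
  if (cnt[["box"]] > 0) {
    m <- cnt[["box"]]
    blocks$box <- data.frame(
      A1 = stats::runif(m, 0.01, 0.06),
      A2 = stats::runif(m, 0.01, 0.06),
      A3 = stats::runif(m, 0.01, 0.06),
      eps1 = sample_edge_exponent(m),
      eps2 = sample_edge_exponent(m),
      eps3 = sample_edge_exponent(m),
      theta1 = stats::runif(m, -pi / 4, pi / 4),
      theta2 = stats::runif(m, -pi / 4, pi / 4),
      theta3 = stats::runif(m, -pi / 4, pi / 4),
      label = "box-like")
  }
  if (cnt[["sphere"]] > 0) {
    m <- cnt[["sphere"]]
    r <- stats::runif(m, 0.01, 0.06)
    blocks$sphere <- data.frame(
      A1 = r, A2 = r, A3 = r,
      eps1 = 1, eps2 = 1, eps3 = 1,
      theta1 = 0, theta2 = 0, theta3 = 0,
      label = "sphere-like")
  }
  if (cnt[["cylinder"]] > 0) {
    m <- cnt[["cylinder"]]
    ar <- stats::runif(m, 0.01, 0.05)           # cross-section radius
    a3 <- ar + stats::runif(m) * (0.06 - ar)    # elongated long axis
    blocks$cylinder <- data.frame(
      A1 = ar, A2 = ar, A3 = a3,
      eps1 = 1, eps2 = 1,
      eps3 = sample_edge_exponent(m),           # squared ends
      theta1 = stats::runif(m, -pi / 2, pi / 2),
      theta2 = stats::runif(m, -pi / 2, pi / 2),
      theta3 = 0,
      label = "cylinder-like")
  }
  db <- do.call(rbind, blocks)
  rownames(db) <- NULL
  ## shuffle so classes interleave, then split
  db <- db[sample.int(nrow(db)), , drop = FALSE]
  rownames(db) <- NULL
  n_train <- round(train_frac * n)
  split <- rep("validation", n)
  split[seq_len(n_train)] <- "train"
  db$split <- split
  attr(db, "seed") <- as.integer(seed)
  attr(db, "class_mix") <- class_mix
  class(db) <- c("shape_db", "data.frame")
  db
}

#' Extract one shape from a database row
#'
#' @param db a `shape_db` (or any data frame with the nine parameter
#'   columns and a `label` column).
#' @param i row index.
#' @return A [superquadric()].
#' @export
db_shape <- function(db, i) {
  r <- db[i, , drop = FALSE]
  superquadric(A = c(r$A1, r$A2, r$A3),
               eps = c(r$eps1, r$eps2, r$eps3),
               theta = c(r$theta1, r$theta2, r$theta3),
               label = r$label)
}

#' Number of free numeric parameters per database entry
#'
#' @param db a `shape_db`.
#' @return integer, 9 (three scales, three exponents, three angles).
#' @export
n_shape_parameters <- function(db) {
  param_cols <- c("A1", "A2", "A3", "eps1", "eps2", "eps3",
                  "theta1", "theta2", "theta3")
  stopifnot(all(param_cols %in% names(db)))
  length(param_cols)
}

#' Canonical parameter matrix of a database
#'
#' Returns the 9-column numeric matrix of shape parameters, optionally
#' re-encoding as network regression targets (see `angle_encoding`).
#'
#' @param db a `shape_db`.
#' @param angle_encoding `"raw"` keeps the three angles as-is;
#'   `"direction"` replaces each angle `t` by the 2D direction vector
#'   `(cos t, sin t)`, avoiding wrap-around discontinuities (12 columns).
#' @return numeric matrix, one row per shape.
#' @export
db_parameters <- function(db, angle_encoding = c("raw", "direction")) {
  angle_encoding <- match.arg(angle_encoding)
  base <- as.matrix(db[, c("A1", "A2", "A3", "eps1", "eps2", "eps3")])
  th <- as.matrix(db[, c("theta1", "theta2", "theta3")])
  if (angle_encoding == "raw") return(cbind(base, th))
  cbind(base, cos(th[, 1]), sin(th[, 1]), cos(th[, 2]), sin(th[, 2]),
        cos(th[, 3]), sin(th[, 3]))
}

#' Write / read a shape database as CSV + JSON metadata
#'
#' @param db a `shape_db`.
#' @param path CSV file path; metadata goes to `<path>.json`.
#' @return `write_database` returns `path` invisibly; `read_database`
#'   returns the `shape_db`.
#' @export
write_database <- function(db, path) {
  utils::write.csv(as.data.frame(db), path, row.names = FALSE)
  meta <- list(seed = attr(db, "seed"), n = nrow(db),
               class_mix = as.list(attr(db, "class_mix")),
               eps_distribution = "eta + Exp(scale = 0.1), eta = 0.01",
               width_range_m = c(0.02, 0.12))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(db, "seed") <- meta$seed
  }
  class(db) <- c("shape_db", "data.frame")
  db
}
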