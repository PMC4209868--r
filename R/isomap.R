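## Squared Euclidean distance matrix via the Gram-matrix identity
## (BLAS-backed; much faster than dist() for wide feature matrices).
squared_distance_matrix <- function(X, Y = X) {
  G <- X %*% t(Y)
  nx <- rowSums(X^2); ny <- rowSums(Y^2)
  D2 <- outer(nx, ny, "+") - 2 * G
  D2[D2 < 0] <- 0
  D2
}

## k-nearest-neighbor graph (union-symmetrized, edge weights = Euclidean
## distances) as an igraph object.
knn_graph <- function(D2, k) {
  n <- nrow(D2)
  stopifnot(k >= 1, k < n)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    edges[[i]] <- cbind(i, nb, sqrt(D2[i, nb]))
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e[, 1:2, drop = FALSE], directed = FALSE)
  igraph::E(g)$weight <- e[, 3]
  g <- igraph::simplify(g, edge.attr.comb = "min")
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

## classical MDS of a squared-distance matrix; returns coordinates,
## eigenvalues and eigenvectors with a fixed sign convention (the
## largest-magnitude entry of each eigenvector is positive).
classical_mds <- function(Delta2, d) {
  n <- nrow(Delta2)
  rm_ <- rowMeans(Delta2); gm <- mean(Delta2)
  B <- -0.5 * (sweep(sweep(Delta2, 1L, rm_), 2L, rm_) + gm)
  eg <- eigen(B, symmetric = TRUE)
  d <- min(d, sum(eg$values > 1e-10))
  V <- eg$vectors[, seq_len(d), drop = FALSE]
  lam <- eg$values[seq_len(d)]
  for (j in seq_len(d)) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  list(coords = V %*% diag(sqrt(lam), d), eigenvalues = lam, vectors = V)
}

#' Isomap embedding of shape features
#'
#' Nonlinear dimension reduction preserving geodesic distances: a
#' k-nearest-neighbor graph is built on Euclidean feature distances,
#' all-pairs shortest-path (Dijkstra) distances approximate geodesics
#' along the shape manifold, and classical MDS embeds them in `d`
#' dimensions. Because geodesic proximity follows the depth-map manifold
#' rather than any parameter chart, similar shapes land close together —
#' the embedding has no discontinuities of the kind superquadric angle
#' parameters have at their canonical-range boundaries.
#'
#' For datasets above `landmark_threshold` points a landmark variant is
#' used: geodesics are computed from `n_landmarks` sampled points only,
#' landmarks are embedded by classical MDS, and the remaining points by
#' the Nystrom out-of-sample formula.
#'
#' @param features numeric matrix, one shape per row (the derivative
#'   channels of the depth maps; 1024 values per shape at the default
#'   grid). Channels are used in native units, unstandardized, unless
#'   `standardize = TRUE`.
#' @param k neighborhood size (default 10). A disconnected neighborhood
#'   graph is an error (reporting component sizes), not silently
#'   repaired, so that geodesics stay interpretable.
#' @param d embedding dimension (presets of interest: 8, 16, 32).
#' @param standardize z-score columns first (default FALSE).
#' @param landmark_threshold exact Isomap is used at or below this size
#'   (default 5000).
#' @param n_landmarks landmarks for the large-scale variant (default
#'   2000).
#' @param seed RNG seed for landmark sampling.
#' @return An `isomap_embedding`: `coordinates` (n x d, centered),
#'   `eigenvalues`, `residual_variance` (1 - R^2 between geodesic and
#'   embedding distances), `k`, `d`, graph and training data needed by
#'   [isomap_transform()].
#' @export
isomap_fit <- function(features, k = 10L, d = 8L, standardize = FALSE,
                       landmark_threshold = 5000L, n_landmarks = 2000L,
                       seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  stopifnot(n >= 3L, k >= 1L)
  center <- colMeans(X); scl <- rep(1, ncol(X))
  if (standardize) {
    scl <- apply(X, 2L, stats::sd); scl[scl < 1e-12] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  }
  D2 <- squared_distance_matrix(X)
  g <- knn_graph(D2, k)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("neighborhood graph is disconnected (component sizes: ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "),
         "); increase k or inspect the features")

  exact <- n <= landmark_threshold
  if (exact) {
    landmarks <- seq_len(n)
    Dg <- igraph::distances(g, algorithm = "dijkstra")
    mds <- classical_mds(Dg^2, d)
    coords <- mds$coords
    geo_landmark <- Dg
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    landmarks <- sort(sample.int(n, min(n_landmarks, n)))
    Dg <- igraph::distances(g, v = landmarks, algorithm = "dijkstra")
    Dm <- Dg[, landmarks, drop = FALSE]       # landmark x landmark
    mds <- classical_mds(Dm^2, d)
    d_eff <- ncol(mds$coords)
    Lsharp <- mds$vectors %*% diag(1 / sqrt(mds$eigenvalues), d_eff)
    mu <- rowMeans(Dm^2)
    coords <- 0.5 * t(Lsharp) %*% (mu - Dg^2)  # d x n (Nystrom, all points)
    coords <- t(coords)
    geo_landmark <- Dm
  }
  d_eff <- ncol(mds$coords)
  lam <- mds$eigenvalues
  Lsharp <- mds$vectors %*% diag(1 / sqrt(lam), d_eff)
  mu <- rowMeans(geo_landmark^2)

  ## residual variance between geodesic and embedding distances
  emb_d <- sqrt(squared_distance_matrix(coords[landmarks, , drop = FALSE]))
  ut <- upper.tri(emb_d)
  rv <- 1 - stats::cor(geo_landmark[ut], emb_d[ut])^2

  ## training nearest-neighbor scale, for out-of-support warnings
  nn_d <- sqrt(apply(D2 + diag(Inf, n), 1L, min))

  structure(list(coordinates = coords, d = d_eff, k = as.integer(k),
                 eigenvalues = lam,
                 residual_variance = rv,
                 feature_space = "first+second derivatives, horizontal and vertical",
                 graph = g, landmarks = landmarks,
                 Lsharp = Lsharp, mu = mu,
                 geo_landmark_from_all = if (exact) NULL else Dg,
                 geo = if (exact) Dg else NULL,
                 train_features = X,
                 standardize = standardize, center = center, scale = scl,
                 nn_q95 = stats::quantile(nn_d, 0.95, names = FALSE)),
            class = "isomap_embedding")
}

#' Residual variance of an embedding at a different dimension
#'
#' Re-embeds the stored geodesic matrix at dimension `d` (nested
#' eigenspaces: no graph recomputation) and reports the residual
#' variance. Non-increasing in `d` on a fixed graph.
#'
#' @param embedding an [isomap_fit()] result (exact mode).
#' @param d target dimension.
#' @return residual variance in `[0, 1]`.
#' @export
residual_variance_at <- function(embedding, d) {
  stopifnot(inherits(embedding, "isomap_embedding"))
  Dg <- if (is.null(embedding$geo)) {
    embedding$geo_landmark_from_all[, embedding$landmarks, drop = FALSE]
  } else embedding$geo
  mds <- classical_mds(Dg^2, d)
  emb_d <- sqrt(squared_distance_matrix(mds$coords))
  ut <- upper.tri(emb_d)
  1 - stats::cor(Dg[ut], emb_d[ut])^2
}

#' Out-of-sample extension of an Isomap embedding
#'
#' Embeds new feature vectors without refitting: geodesic distances from
#' a new point to the training landmarks are estimated through its k
#' nearest training neighbors (`min_j (||x - x_j|| + geo(x_j, .))`), and
#' the Nystrom formula projects them onto the training eigenbasis. A
#' training point maps exactly to its training coordinate. Queries far
#' outside the training support (nearest-neighbor distance beyond the
#' 95th percentile of training nearest-neighbor distances) are flagged
#' via the `out_of_support` attribute.
#'
#' @param embedding an [isomap_fit()] result.
#' @param new_features numeric vector (one shape) or matrix (one per
#'   row), same feature space as the training data.
#' @return d-column matrix of embedding coordinates with logical
#'   attribute `out_of_support`.
#' @export
isomap_transform <- function(embedding, new_features) {
  stopifnot(inherits(embedding, "isomap_embedding"))
  Xn <- if (is.matrix(new_features)) new_features else
    matrix(new_features, nrow = 1L)
  if (embedding$standardize)
    Xn <- sweep(sweep(Xn, 2L, embedding$center), 2L, embedding$scale, "/")
  Xt <- embedding$train_features
  D2n <- squared_distance_matrix(Xn, Xt)       # m x n_train
  Dn <- sqrt(D2n)
  geo_to_landmarks <- if (is.null(embedding$geo)) {
    t(embedding$geo_landmark_from_all)          # n_train x n_landmark
  } else {
    embedding$geo[, embedding$landmarks, drop = FALSE]
  }
  k <- embedding$k
  m <- nrow(Xn)
  out <- matrix(NA_real_, m, embedding$d)
  oos <- logical(m)
  for (i in seq_len(m)) {
    ord <- order(Dn[i, ])[seq_len(k)]
    ## geodesic estimate through each near neighbor, minimized
    cand <- geo_to_landmarks[ord, , drop = FALSE] + Dn[i, ord]
    delta <- apply(cand, 2L, min)               # length n_landmark
    out[i, ] <- 0.5 * as.numeric(t(embedding$Lsharp) %*%
                                 (embedding$mu - delta^2))
    oos[i] <- Dn[i, ord[1L]] > embedding$nn_q95
  }
  if (any(oos))
    warning(sum(oos), " query point(s) outside the training support")
  attr(out, "out_of_support") <- oos
  out
}

#' Paired histograms of embedding distances and prediction errors
#'
#' Compares the distribution of pairwise distances between shapes in
#' embedding space with the distribution of per-shape root-sum-square
#' prediction errors, on shared binning. A useful mapping should
#' concentrate errors far below typical inter-shape distances.
#'
#' @param embedding an [isomap_fit()] result, or a coordinate matrix.
#' @param prediction_errors per-shape root-sum-square errors (e.g. from
#'   [evaluate_net()]'s `per_shape_error`).
#' @param breaks number of bins (default 50).
#' @return list with `breaks`, `distance_counts`, `error_counts`,
#'   `median_distance`, `median_error`.
#' @export
distance_histograms <- function(embedding, prediction_errors, breaks = 50L) {
  coords <- if (inherits(embedding, "isomap_embedding"))
    embedding$coordinates else as.matrix(embedding)
  pd <- sqrt(squared_distance_matrix(coords))
  pd <- pd[upper.tri(pd)]
  lo <- 0; hi <- max(pd, prediction_errors)
  br <- seq(lo, hi, length.out = breaks + 1L)
  list(breaks = br,
       distance_counts = hist(pd, breaks = br, plot = FALSE)$counts,
       error_counts = hist(prediction_errors, breaks = br,
                           plot = FALSE)$counts,
       median_distance = stats::median(pd),
       median_error = stats::median(prediction_errors))
}
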