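# ---- feature tensor ---------------------------------------------------------

#' Build the per-node geometric feature tensor
#'
#' Crops `margin` mm transition zones at both ends of the lattice (640
#' stations over 80 mm with the 5 mm default keep exactly 560) and fills the
#' 8 feature channels per kept node, in order:
#' `X, Y, Z` (node coordinates, mm), `C` (station curvature, 1/mm),
#' `A = 2*pi*(k-1)/n_theta` (circumferential angle, rad), and the
#' station-level lesion parameters `d, a, b` (eccentric offset and
#' cross-section semi-axes of the blended profile; `0, R0, R0` where
#' nominal).
#'
#' @param lattice a `surface_lattice`.
#' @param margin excluded transition length at each end, mm (default 5).
#' @param dims optional `c(n_axial, n_theta)` the full lattice must match
#'   (shape error otherwise); `NULL` skips the check.
#' @return An `input_tensor`: numeric array (n_kept x n_theta x 8) with
#'   attributes `station_s`, `station_index`, `feature_names`.
#' @export
build_feature_tensor <- function(lattice, margin = 5, dims = NULL) {
  stopifnot(inherits(lattice, "surface_lattice"))
  if (!is.null(dims) &&
      !(lattice$n_axial == dims[1] && lattice$n_theta == dims[2]))
    stop(sprintf("shape: lattice is %d x %d, expected %d x %d",
                 lattice$n_axial, lattice$n_theta, dims[1], dims[2]))
  keep <- crop_station_indices(lattice$n_axial, lattice$station_s, margin)
  n <- length(keep); m <- lattice$n_theta
  prof <- lattice$profile
  A_ang <- 2 * pi * (seq_len(m) - 1L) / m
  x <- array(0, c(n, m, 8L))
  x[, , 1:3] <- lattice$node_xyz[keep, , , drop = FALSE]
  x[, , 4] <- matrix(lattice$station_curvature[keep], n, m)
  x[, , 5] <- matrix(A_ang, n, m, byrow = TRUE)
  x[, , 6] <- matrix(prof$off[keep], n, m)
  x[, , 7] <- matrix(prof$a[keep], n, m)
  x[, , 8] <- matrix(prof$b[keep], n, m)
  structure(x,
            station_s = lattice$station_s[keep], station_index = keep,
            feature_names = c("X", "Y", "Z", "C", "A", "d", "a", "b"),
            class = "input_tensor")
}

#' @export
print.input_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<input_tensor> %d x %d x %d (%d features)\n",
              d[1], d[2], d[3], prod(d)))
  invisible(x)
}

# ---- WSS-to-grid mapping ----------------------------------------------------

#' Map scattered WSS samples onto the analysis grid
#'
#' Each kept grid node receives the WSS value of its nearest sample point in
#' Euclidean 3D distance; exact ties are broken by the lowest sample index.
#'
#' @param points numeric matrix (p x 3) of sample locations, mm.
#' @param wss numeric vector of length p, WSS magnitudes in Pa.
#' @param lattice a `surface_lattice`.
#' @param margin crop margin in mm (default 5).
#' @return A `wss_field` on the cropped lattice.
#' @export
map_wss_to_grid <- function(points, wss, lattice, margin = 5) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("input: need at least one sample point")
  stopifnot(length(wss) == nrow(points))
  keep <- crop_station_indices(lattice$n_axial, lattice$station_s, margin)
  n <- length(keep); m <- lattice$n_theta
  grid <- matrix(aperm(lattice$node_xyz[keep, , , drop = FALSE],
                       c(2L, 1L, 3L)), n * m, 3L)   # k fastest
  # exact squared distances, one sample at a time, so that exact ties
  # resolve to the lowest sample index (strict improvement required)
  best <- rep(Inf, n * m)
  nearest <- integer(n * m)
  for (j in seq_len(nrow(points))) {
    d2 <- (grid[, 1L] - points[j, 1L])^2 + (grid[, 2L] - points[j, 2L])^2 +
      (grid[, 3L] - points[j, 3L])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    nearest[upd] <- j
  }
  vals <- matrix(wss[nearest], n, m, byrow = TRUE)
  new_wss_field(vals, lattice$station_s[keep], keep, m)
}

# ---- target normalization ---------------------------------------------------

#' Training-set WSS normalization statistics
#'
#' The standard target transform is `z = (log(wss + eps) - mean) / sd` with
#' `eps = 1e-6`; `mean` and `sd` (population convention) are computed once
#' over all nodes of the training fields and frozen.
#'
#' @param fields list of `wss_field` objects (the training split).
#' @param eps_log log stabilizer (default 1e-6).
#' @return A list of class `wss_normalizer` with `mean`, `sd`, `eps_log`.
#' @export
wss_normalizer <- function(fields, eps_log = 1e-6) {
  if (inherits(fields, "wss_field") || is.matrix(fields))
    fields <- list(fields)
  v <- unlist(lapply(fields, function(f) {
    vals <- if (inherits(f, "wss_field")) f$values else f
    as.vector(log(vals + eps_log))
  }))
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) stop("degenerate-statistics: constant training targets")
  structure(list(mean = mu, sd = sdv, eps_log = eps_log),
            class = "wss_normalizer")
}

#' Apply / invert the log-z WSS transform
#'
#' @param field a `wss_field` (or bare numeric matrix of Pa values).
#' @param stats a [wss_normalizer()].
#' @return `normalize_wss` a numeric matrix on the z scale;
#'   `denormalize_wss` a matrix of Pa values (the exact inverse).
#' @export
normalize_wss <- function(field, stats) {
  v <- if (inherits(field, "wss_field")) field$values else field
  (log(v + stats$eps_log) - stats$mean) / stats$sd
}

#' @rdname normalize_wss
#' @param z numeric matrix on the z scale.
#' @export
denormalize_wss <- function(z, stats) {
  exp(z * stats$sd + stats$mean) - stats$eps_log
}

# ---- hybrid vessel graph ----------------------------------------------------

#' Build the hybrid grid/spatial vessel graph
#'
#' Nodes are the kept lattice nodes (row-major, circumferential index
#' fastest). Grid edges connect each node to its 8 structured neighbours
#' (4 direct axial/circumferential plus 4 diagonal), with circumferential
#' wrap and no axial wrap. Spatial edges connect node pairs within
#' `spatial_radius` that are not already grid-connected, capped at
#' `max_spatial_degree` nearest partners per node. Every edge carries the
#' weight `w_ij = exp(-||x_i - x_j|| / 0.1)` (distance in mm).
#'
#' @param lattice a `surface_lattice`.
#' @param tensor the matching `input_tensor` (provides the crop).
#' @param spatial_radius proximity threshold in mm (default 0.3; must be
#'   positive).
#' @param max_spatial_degree per-node cap on spatial edges (default 6).
#' @param length_scale weight decay scale in mm (default 0.1).
#' @return A `vessel_graph`: `n_nodes`, `edges` (E x 2, i < j), `weights`,
#'   `is_grid`, `node_xyz`, `dims = c(n_axial, n_theta)`, and `geometry`
#'   (per-node `R`, `kappa`, `s`, `theta` for the physics loss).
#' @export
build_graph <- function(lattice, tensor, spatial_radius = 0.3,
                        max_spatial_degree = 6L, length_scale = 0.1) {
  if (spatial_radius <= 0) stop("parameter: spatial_radius must be positive")
  keep <- attr(tensor, "station_index")
  n <- length(keep); m <- lattice$n_theta
  node_xyz <- matrix(aperm(lattice$node_xyz[keep, , , drop = FALSE],
                           c(2L, 1L, 3L)), n * m, 3L)

  ge <- grid_edges(n, m)
  sp <- spatial_candidate_pairs(node_xyz, keep, lattice, spatial_radius,
                                method = "window")
  if (nrow(sp$pairs)) {
    gkey <- ge[, 1] * (n * m + 1) + ge[, 2]
    skey <- sp$pairs[, 1] * (n * m + 1) + sp$pairs[, 2]
    fresh <- !(skey %in% gkey)
    sp$pairs <- sp$pairs[fresh, , drop = FALSE]
    sp$dist <- sp$dist[fresh]
    # degree cap: admit shortest edges first while both endpoints have room
    o <- order(sp$dist)
    degree <- integer(n * m)
    keep_e <- logical(length(o))
    for (e in o) {
      a <- sp$pairs[e, 1]; b <- sp$pairs[e, 2]
      if (degree[a] < max_spatial_degree && degree[b] < max_spatial_degree) {
        keep_e[e] <- TRUE
        degree[a] <- degree[a] + 1L; degree[b] <- degree[b] + 1L
      }
    }
    sp$pairs <- sp$pairs[keep_e, , drop = FALSE]
    sp$dist <- sp$dist[keep_e]
  }

  edges <- rbind(ge, sp$pairs)
  is_grid <- rep(c(TRUE, FALSE), c(nrow(ge), nrow(sp$pairs)))
  dvec <- sqrt(rowSums((node_xyz[edges[, 1], , drop = FALSE] -
                          node_xyz[edges[, 2], , drop = FALSE])^2))
  weights <- exp(-dvec / length_scale)

  # per-node geometry for the continuity/boundary terms
  th <- 2 * pi * (seq_len(m) - 1L) / m
  h <- lattice$station_s[2] - lattice$station_s[1]
  acc <- .fd_mat(.fd_mat(lattice$centerline$xyz, h), h)
  th_c <- numeric(n)
  for (ii in seq_len(n)) {
    i0 <- keep[ii]
    if (lattice$station_curvature[i0] > 1e-9) {
      an <- sum(acc[i0, ] * lattice$frames$normal[i0, ])
      ab <- sum(acc[i0, ] * lattice$frames$binormal[i0, ])
      th_c[ii] <- atan2(ab, an)
    }
  }
  geometry <- data.frame(
    R = rep(lattice$station_radius[keep], each = m),
    kappa = rep(lattice$station_curvature[keep], each = m),
    s = rep(lattice$station_s[keep], each = m),
    theta = as.vector(t(outer(rep(1, n), th))) - rep(th_c, each = m))

  structure(list(n_nodes = n * m, edges = edges, weights = weights,
                 is_grid = is_grid, node_xyz = node_xyz,
                 dims = c(n, m), geometry = geometry,
                 edge_dist = dvec),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes (%d x %d), %d grid + %d spatial edges\n",
              x$n_nodes, x$dims[1], x$dims[2], sum(x$is_grid),
              sum(!x$is_grid)))
  invisible(x)
}

# undirected 8-neighbourhood edges of an n x m lattice (k fastest, wrap on k)
grid_edges <- function(n, m) {
  id <- function(i, k) (i - 1L) * m + ((k - 1L) %% m) + 1L
  i <- rep(seq_len(n), each = m)
  k <- rep(seq_len(m), n)
  e <- list()
  # within-ring: (i,k)-(i,k+1); axial: (i,k)-(i+1,k); diagonals
  e[[1]] <- cbind(id(i, k), id(i, k + 1L))
  ax <- i < n
  e[[2]] <- cbind(id(i[ax], k[ax]), id(i[ax] + 1L, k[ax]))
  e[[3]] <- cbind(id(i[ax], k[ax]), id(i[ax] + 1L, k[ax] + 1L))
  e[[4]] <- cbind(id(i[ax], k[ax]), id(i[ax] + 1L, k[ax] - 1L))
  e <- do.call(rbind, e)
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# candidate node pairs within radius; "window" prunes station pairs by a
# centerline-distance bound (node separation >= |c_i - c_j| - R_i - R_j),
# "bruteforce" is the exhaustive O(N^2) scan used as a test oracle
spatial_candidate_pairs <- function(node_xyz, keep, lattice, radius,
                                    method = c("window", "bruteforce")) {
  method <- match.arg(method)
  N <- nrow(node_xyz)
  m <- lattice$n_theta
  if (method == "bruteforce") {
    d2 <- as.matrix(stats::dist(node_xyz))
    hit <- which(upper.tri(d2) & d2 <= radius, arr.ind = TRUE)
    return(list(pairs = unname(hit[, c(1, 2), drop = FALSE]),
                dist = d2[hit]))
  }
  n <- length(keep)
  ctr <- lattice$centerline$xyz[keep, , drop = FALSE]
  Rst <- apply(matrix(sqrt(rowSums(
    (node_xyz - ctr[rep(seq_len(n), each = m), ])^2)), n, m, byrow = TRUE),
    1L, max)
  pairs <- NULL; dists <- NULL
  for (i in seq_len(n)) {
    dc <- sqrt(rowSums((ctr - matrix(ctr[i, ], n, 3L, byrow = TRUE))^2))
    cand <- which(seq_len(n) >= i & dc <= radius + Rst[i] + Rst)
    if (!length(cand)) next
    rows_i <- ((i - 1L) * m + 1L):(i * m)
    rows_j <- as.vector(vapply(cand, function(j) ((j - 1L) * m + 1L):(j * m),
                               integer(m)))
    gi <- node_xyz[rows_i, , drop = FALSE]
    gj <- node_xyz[rows_j, , drop = FALSE]
    d2 <- outer(rowSums(gi^2), rowSums(gj^2), "+") - 2 * gi %*% t(gj)
    d2[d2 < 0] <- 0
    hit <- which(sqrt(d2) <= radius, arr.ind = TRUE)
    if (!nrow(hit)) next
    a <- rows_i[hit[, 1]]; b <- rows_j[hit[, 2]]
    sel <- a < b
    if (!any(sel)) next
    pairs <- rbind(pairs, cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
    dists <- c(dists, sqrt(d2[hit])[sel])
  }
  if (is.null(pairs)) return(list(pairs = matrix(0L, 0L, 2L), dist = numeric(0)))
  dup <- duplicated(pairs[, 1] * (N + 1) + pairs[, 2])
  list(pairs = pairs[!dup, , drop = FALSE], dist = dists[!dup])
}

#' Sparse (weighted) adjacency of a vessel graph
#'
#' @param graph a `vessel_graph`.
#' @param self_loops add unit self-loop weights (default FALSE).
#' @return A symmetric `Matrix::dgCMatrix`.
#' @export
graph_adjacency <- function(graph, self_loops = FALSE) {
  N <- graph$n_nodes
  i <- c(graph$edges[, 1], graph$edges[, 2])
  j <- c(graph$edges[, 2], graph$edges[, 1])
  w <- c(graph$weights, graph$weights)
  if (self_loops) { i <- c(i, seq_len(N)); j <- c(j, seq_len(N)); w <- c(w, rep(1, N)) }
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(N, N))
}

#' Grid degree of every node (number of grid edges incident)
#' @param graph a `vessel_graph`.
#' @return Integer vector of length `n_nodes`.
#' @export
grid_degree <- function(graph) {
  e <- graph$edges[graph$is_grid, , drop = FALSE]
  tabulate(c(e[, 1], e[, 2]), nbins = graph$n_nodes)
}
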