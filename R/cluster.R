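# Fuzzy KNN connectivity graphs, Leiden partitioning over iterative
# marker-scoped rounds, UMAP embedding, and median-fluorescence cluster
# profiles.

#' Build a fuzzy k-nearest-neighbour connectivity graph
#'
#' Exact Euclidean k-nearest neighbours (kd-tree search), converted to fuzzy
#' simplicial-set connectivities: per event i, `rho_i` is the distance to its
#' nearest neighbour, `sigma_i` is calibrated by bisection so that the
#' smoothed weights `exp(-(d_ij - rho_i)/sigma_i)` sum to `log2(k)`, and the
#' directed weights are symmetrised by the probabilistic union
#' `w = a + b - a*b`. Every event's nearest-neighbour edge has weight 1
#' before symmetrisation.
#'
#' @param dataset a `pooled_dataset` or a numeric matrix.
#' @param k number of neighbours (`2 <= k < n`).
#' @param seed integer seed (carried for provenance; the search is exact and
#'   deterministic).
#' @return class `neighbor_graph`: `nn_index` (n x k), `nn_dist`,
#'   `connectivity` (sparse symmetric dgCMatrix), `k`, `metric`, `seed`.
#' @export
build_knn_graph <- function(dataset, k = 15, seed = 1L) {
  X <- if (inherits(dataset, "pooled_dataset")) dataset$values else as.matrix(dataset)
  n <- nrow(X)
  if (k < 2) stopf("build_knn_graph: k must be >= 2")
  if (k >= n) stopf("build_knn_graph: k (%d) must be < n (%d)", k, n)

  nn <- RANN::nn2(X, X, k = k + 1, treetype = "kd", searchtype = "standard")
  # drop self-matches (usually column 1; guard against exact duplicates)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    row <- nn$nn.idx[i, ]; d <- nn$nn.dists[i, ]
    self <- match(i, row)
    if (is.na(self)) self <- 1L
    keep <- seq_len(k + 1)[-self][seq_len(k)]
    idx[i, ] <- row[keep]; dst[i, ] <- d[keep]
  }

  rho <- dst[, 1]
  target <- log2(k)
  sigma <- vapply(seq_len(n), function(i) {
    d <- pmax(dst[i, ] - rho[i], 0)
    if (all(d == 0)) return(1)
    lo <- 1e-8; hi <- max(d) * 10
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-d / mid))
      if (abs(s - target) < 1e-6) break
      if (s > target) hi <- mid else lo <- mid
    }
    mid
  }, numeric(1))

  w <- exp(-pmax(dst - rho, 0) / sigma)
  i <- rep(seq_len(n), k)
  j <- as.vector(idx)
  A <- Matrix::sparseMatrix(i = i, j = j, x = as.vector(w), dims = c(n, n))
  A <- methods::as(A, "CsparseMatrix")
  W <- A + Matrix::t(A) - A * Matrix::t(A)
  Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)

  structure(list(nn_index = idx, nn_dist = dst, connectivity = W,
                 k = as.integer(k), metric = "euclidean",
                 seed = as.integer(seed)),
            class = "neighbor_graph")
}

#' RB-configuration partition quality
#'
#' `Q(gamma) = sum_c (e_c - gamma * K_c^2 / (2m))` over clusters, where `e_c`
#' is the total intra-cluster edge weight and `K_c` the summed degree of the
#' cluster, on the symmetric weighted connectivity graph. The Leiden
#' optimiser maximises this quality (igraph's resolution-parameterised
#' modularity equals `Q/(2m)`, so the argmax is identical).
#'
#' @param graph a `neighbor_graph`.
#' @param membership integer cluster id per event.
#' @param resolution the resolution parameter gamma.
#' @return the quality value.
#' @export
rb_quality <- function(graph, membership, resolution = 1) {
  W <- graph$connectivity
  m2 <- sum(W)  # = 2m on the symmetric matrix
  deg <- Matrix::rowSums(W)
  q <- 0
  for (c in unique(membership)) {
    ix <- which(membership == c)
    e_c <- sum(W[ix, ix]) / 2
    K_c <- sum(deg[ix])
    q <- q + e_c - resolution * K_c^2 / (2 * m2)
  }
  q
}

#' Leiden partition of a connectivity graph
#'
#' Runs the Leiden algorithm on the symmetrised weighted graph, locally
#' maximising the resolution-parameterised (RB-configuration) quality.
#' Cluster ids are relabelled in order of decreasing size. Deterministic
#' given the seed.
#'
#' @param graph a `neighbor_graph`.
#' @param resolution resolution gamma; default 1.
#' @param seed integer seed.
#' @param n_iterations Leiden refinement iterations.
#' @return class `cluster_assignment`: `cluster` (integer per event),
#'   `lineage` (character per cluster id), `resolution`, `seed`,
#'   `annotation` (NULL until annotated).
#' @export
leiden_partition <- function(graph, resolution = 1, seed = 1L, n_iterations = 5L) {
  W <- graph$connectivity
  if (nrow(W) == 0) stopf("leiden_partition: empty graph")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  memb <- with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           weights = igraph::E(g)$weight,
                           resolution = resolution,
                           n_iterations = n_iterations)$membership
  })
  memb <- order_clusters_by_size(memb)
  structure(list(cluster = memb,
                 lineage = stats::setNames(as.character(sort(unique(memb))),
                                           sort(unique(memb))),
                 resolution = resolution, seed = as.integer(seed),
                 annotation = NULL),
            class = "cluster_assignment")
}

#' @noRd
order_clusters_by_size <- function(memb) {
  sizes <- sort(table(memb), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  as.integer(map[as.character(memb)])
}

#' Iterative marker-scoped subclustering
#'
#' Each round restricts to the events of the targeted parent clusters,
#' rebuilds the KNN graph on that round's marker subset, re-partitions with
#' Leiden, and records the cluster lineage (`parent/child` paths). Events
#' outside the targeted clusters keep their labels.
#'
#' @param dataset a `pooled_dataset`.
#' @param plan list of rounds, each a list with `targets` (parent cluster
#'   ids; `NULL` in round 1 = all events), `markers` (subset for the round's
#'   graph; default all), `k`, `resolution`.
#' @param seed integer seed (fanned out per round).
#' @return a `cluster_assignment` with depth-reflecting lineage paths.
#' @export
iterative_subcluster <- function(dataset, plan, seed = 1L) {
  n <- nrow(dataset$values)
  cluster <- rep(1L, n)
  path <- rep("", n)  # per-event lineage path, grown one segment per round
  first <- TRUE
  for (ri in seq_along(plan)) {
    round <- plan[[ri]]
    targets <- round$targets %||% unique(cluster)
    if (length(setdiff(targets, cluster))) {
      stopf("iterative_subcluster: round %d targets unknown cluster(s) %s", ri,
            paste(setdiff(targets, cluster), collapse = ", "))
    }
    sel <- cluster %in% targets
    if (!any(sel)) stopf("iterative_subcluster: round %d targets no events", ri)
    markers <- round$markers %||% dataset$markers
    miss <- setdiff(markers, dataset$markers)
    if (length(miss)) stopf("iterative_subcluster: unknown marker(s): %s",
                            paste(miss, collapse = ", "))
    X <- dataset$values[sel, markers, drop = FALSE]
    g <- build_knn_graph(X, k = round$k %||% 15,
                         seed = derive_seed(seed, ri, 1))
    part <- leiden_partition(g, resolution = round$resolution %||% 1,
                             seed = derive_seed(seed, ri, 2))
    # events outside the targeted clusters keep their labels verbatim
    new_ids <- if (first) part$cluster else max(cluster) + part$cluster
    path[sel] <- ifelse(path[sel] == "", as.character(new_ids),
                        paste(path[sel], new_ids, sep = "/"))
    cluster[sel] <- new_ids
    first <- FALSE
  }
  lineage <- vapply(sort(unique(cluster)),
                    function(c) path[match(c, cluster)], character(1))
  names(lineage) <- sort(unique(cluster))
  structure(list(cluster = cluster, lineage = lineage,
                 resolution = NA_real_, seed = as.integer(seed),
                 annotation = NULL),
            class = "cluster_assignment")
}

#' UMAP embedding
#'
#' Two-dimensional UMAP of the standardized markers, seeded and
#' single-threaded for determinism. The embedding is for reporting only:
#' clustering always reads the connectivity graph, never these coordinates.
#'
#' @param dataset a `pooled_dataset` or numeric matrix.
#' @param seed integer seed.
#' @param n_neighbors UMAP neighbourhood size; default 15.
#' @return an `n x 2` coordinate matrix.
#' @export
umap_embed <- function(dataset, seed = 1L, n_neighbors = 15) {
  X <- if (inherits(dataset, "pooled_dataset")) dataset$values else as.matrix(dataset)
  coords <- with_seed(seed, {
    uwot::umap(X, n_neighbors = n_neighbors, n_components = 2,
               n_threads = 1, n_sgd_threads = 1, batch = TRUE)
  })
  colnames(coords) <- c("umap1", "umap2")
  coords
}

#' Median-fluorescence cluster profiles
#'
#' Per-cluster, per-marker medians of the transformed (not z-scored)
#' intensities, plus a per-marker min-max scaled copy in `[0, 1]` across
#' clusters — the scaled MFI heatmap representation used to annotate
#' clusters. Empty clusters are excluded with a warning.
#'
#' @param assignment a `cluster_assignment`.
#' @param dataset the `pooled_dataset` the assignment covers (its
#'   `transformed` slot supplies the intensities), or a plain matrix of
#'   transformed intensities.
#' @return class `cluster_profile`: `mfi` (clusters x markers), `scaled`.
#' @export
cluster_profiles <- function(assignment, dataset) {
  V <- if (inherits(dataset, "pooled_dataset")) dataset$transformed else as.matrix(dataset)
  if (length(assignment$cluster) != nrow(V)) {
    stopf("cluster_profiles: assignment covers %d events, data has %d",
          length(assignment$cluster), nrow(V))
  }
  ids <- sort(unique(assignment$cluster))
  mfi <- t(vapply(ids, function(c) {
    apply(V[assignment$cluster == c, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(V))))
  rownames(mfi) <- ids
  colnames(mfi) <- colnames(V)
  rng <- apply(mfi, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  scaled <- sweep(sweep(mfi, 2, rng[1, ]), 2, span, "/")
  structure(list(mfi = mfi, scaled = scaled), class = "cluster_profile")
}
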