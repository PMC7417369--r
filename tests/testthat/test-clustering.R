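# Fuzzy KNN graphs, Leiden partitioning, iterative subclustering, UMAP and
# MFI profiles.

test_that("fuzzy KNN connectivities have unit nearest-neighbour edges and are symmetric", {
  ds <- make_blob_dataset(n_per = 100, seed = 3)
  g <- build_knn_graph(ds, k = 10, seed = 1)
  W <- g$connectivity
  expect_equal(max(abs(W - Matrix::t(W))), 0)
  expect_equal(unname(Matrix::diag(W)), rep(0, nrow(W)))
  # nearest-neighbour weight is 1 before symmetrisation, hence still 1 after
  # the probabilistic union
  nn1 <- g$nn_index[, 1]
  w_nn <- vapply(seq_len(nrow(W)), function(i) W[i, nn1[i]], 0)
  expect_equal(w_nn, rep(1, nrow(W)), tolerance = 1e-12)
  # every event keeps at least one positive-weight neighbour
  expect_true(all(Matrix::rowSums(W > 0) >= 1))
  expect_error(build_knn_graph(ds, k = 1e6), "k")
})

test_that("well-separated blobs produce no cross-blob edges (brute-force check)", {
  ds <- make_blob_dataset(n_per = 60, sd = 0.25,
                          centers = rbind(c(0, 0), c(20, 0), c(0, 20)),
                          seed = 5)
  lab <- attr(ds, "labels")
  g <- build_knn_graph(ds, k = 10, seed = 1)
  # brute-force neighbours agree with the kd-tree search
  D <- as.matrix(dist(ds$values))
  diag(D) <- Inf
  for (i in sample(nrow(D), 25)) {
    expect_setequal(g$nn_index[i, ], order(D[i, ])[1:10])
  }
  ij <- which(as.matrix(g$connectivity) > 0, arr.ind = TRUE)
  expect_true(all(lab[ij[, 1]] == lab[ij[, 2]]))
})

test_that("Leiden separates disconnected cliques and recovers planted blobs", {
  # two tight far-apart blobs of 10 events with k = 9: two complete components
  ds <- make_blob_dataset(n_per = 10, sd = 0.05,
                          centers = rbind(c(0, 0), c(100, 100)), seed = 2)
  g <- build_knn_graph(ds, k = 9, seed = 1)
  part <- leiden_partition(g, resolution = 1, seed = 1)
  expect_equal(length(unique(part$cluster)), 2)
  expect_equal(ari_pair_counting(part$cluster, attr(ds, "labels")), 1)

  # five planted blobs: at a resolution matched to the blob scale the raw
  # partition recovers them exactly
  ds5 <- make_blob_dataset(n_per = 200, seed = 7)
  g5 <- build_knn_graph(ds5, k = 15, seed = 1)
  lab5 <- attr(ds5, "labels")
  p5_lo <- leiden_partition(g5, resolution = 0.1, seed = 2)
  expect_gte(ari_pair_counting(p5_lo$cluster, lab5), 0.9)

  # at the default resolution the optimiser sub-divides blobs (the expected
  # resolution-limit behaviour) but never mixes them: clusters stay pure and
  # the majority-merged partition matches the blobs
  p5 <- leiden_partition(g5, resolution = 1, seed = 2)
  purity <- vapply(unique(p5$cluster),
                   function(c) max(table(lab5[p5$cluster == c])) /
                     sum(p5$cluster == c), 0)
  expect_true(all(purity == 1))
  merged <- majority_overlap_map(p5$cluster, lab5)[as.character(p5$cluster)]
  expect_gte(ari_pair_counting(merged, lab5), 0.9)

  # determinism and size-ordered ids
  p5b <- leiden_partition(g5, resolution = 1, seed = 2)
  expect_identical(p5$cluster, p5b$cluster)
  sizes <- as.numeric(table(p5$cluster))
  expect_true(all(diff(sizes) <= 0))
})

test_that("partition quality never falls below the connected-component baseline", {
  ds <- make_blob_dataset(n_per = 50, sd = 0.1,
                          centers = rbind(c(0, 0), c(50, 50), c(100, 0)),
                          seed = 9)
  g <- build_knn_graph(ds, k = 8, seed = 1)
  part <- leiden_partition(g, resolution = 1, seed = 3)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(g$connectivity, "undirected",
                                        weighted = TRUE))$membership
  expect_gte(rb_quality(g, part$cluster, 1), rb_quality(g, comp, 1) - 1e-9)
})

test_that("raising the resolution never reduces the cluster count", {
  ds <- make_blob_dataset(n_per = 150, seed = 13)
  g <- build_knn_graph(ds, k = 15, seed = 1)
  ks <- vapply(c(0.5, 1, 2), function(r) {
    length(unique(leiden_partition(g, resolution = r, seed = 4)$cluster))
  }, 0)
  expect_true(all(diff(ks) >= 0))
})

test_that("clustering is invariant to event order up to relabelling", {
  ds <- make_blob_dataset(n_per = 120, seed = 17)
  withr::with_seed(5, perm <- sample(nrow(ds$values)))
  ds_perm <- ds
  ds_perm$values <- ds$values[perm, ]
  p1 <- leiden_partition(build_knn_graph(ds, k = 12, seed = 1), seed = 2)
  p2 <- leiden_partition(build_knn_graph(ds_perm, k = 12, seed = 1), seed = 2)
  expect_equal(ari_pair_counting(p1$cluster[perm], p2$cluster), 1)
})

test_that("iterative subclustering respects targets and records lineage", {
  ds <- make_blob_dataset(n_per = 150, seed = 21)
  plan1 <- list(list(targets = NULL, k = 12, resolution = 0.1))
  a1 <- iterative_subcluster(ds, plan1, seed = 3)
  expect_gte(ari_pair_counting(a1$cluster, attr(ds, "labels")), 0.9)
  expect_true(all(nchar(a1$lineage) > 0))

  # a second round targeting cluster 1 must not touch other events
  plan2 <- list(list(targets = NULL, k = 12, resolution = 0.1),
                list(targets = 1L, k = 10, resolution = 1.5))
  a2 <- iterative_subcluster(ds, plan2, seed = 3)
  outside <- a1$cluster != 1
  expect_identical(a2$cluster[outside], a1$cluster[outside])
  depth <- vapply(strsplit(unname(a2$lineage), "/"), length, 0L)
  re_ids <- unique(a2$cluster[!outside])
  expect_true(all(depth[match(as.character(re_ids), names(a2$lineage))] == 2))

  expect_error(iterative_subcluster(ds, list(list(targets = 99))), "targets")
  expect_error(
    iterative_subcluster(ds, list(list(targets = NULL, markers = "nope"))),
    "nope")
})

test_that("a CD44-scoped round splits committed from uncommitted progenitors", {
  spec <- build_default_thymus_spec(events_per_sample = 2500, master_seed = 31,
                                    n_samples = c(mnc = 4, cd34 = 4))
  cohort <- simulate_cohort(spec, "cd34")
  pre <- lapply(cohort, preprocess_sample,
                spillover = spec_spillover(spec, "cd34"),
                gates = panel_default_gates("cd34"))
  pooled <- pool_and_standardize(pre, panel_retained_markers("cd34")$markers)
  truth <- unlist(lapply(pre, function(s) s$truth$event_labels))

  # cluster on CD44/CD7/CD5/CD123, excluding CD34
  plan <- list(list(targets = NULL, markers = c("CD44", "CD7", "CD5", "CD123"),
                    k = 15, resolution = 1))
  a <- iterative_subcluster(pooled, plan, seed = 1)
  pred <- majority_overlap_map(a$cluster, truth)[as.character(a$cluster)]
  fm <- f_measure_report(unname(pred), truth, pooled$sample_id,
                         populations = c("lin-CD34+CD1a-", "lin-CD34+CD1a+"))
  med <- aggregate(F ~ population, fm, median)
  expect_true(all(med$F >= 0.9))
})

test_that("UMAP embeds blobs apart, deterministically", {
  ds <- make_blob_dataset(n_per = 80, seed = 23)
  co <- umap_embed(ds, seed = 6)
  expect_equal(dim(co), c(nrow(ds$values), 2))
  lab <- attr(ds, "labels")
  cents <- t(vapply(unique(lab), function(l) colMeans(co[lab == l, ]),
                    numeric(2)))
  intra <- mean(vapply(unique(lab), function(l) {
    mean(sqrt(rowSums(sweep(co[lab == l, ], 2, colMeans(co[lab == l, ]))^2)))
  }, 0))
  inter <- mean(dist(cents))
  expect_gt(inter, intra)
  expect_identical(co, umap_embed(ds, seed = 6))
})

test_that("MFI profiles are medians of transformed intensities with min-max scaling", {
  ds <- make_blob_dataset(n_per = 50, seed = 25)
  g <- build_knn_graph(ds, k = 10, seed = 1)
  part <- leiden_partition(g, seed = 1)
  prof <- cluster_profiles(part, ds)
  # brute-force sort-and-pick median oracle on every cluster
  for (c in unique(part$cluster)) {
    for (j in seq_len(ncol(ds$transformed))) {
      v <- sort(ds$transformed[part$cluster == c, j])
      n <- length(v)
      med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
      expect_equal(prof$mfi[as.character(c), j], med)
    }
  }
  expect_equal(unname(apply(prof$scaled, 2, min)), rep(0, ncol(prof$scaled)))
  expect_equal(unname(apply(prof$scaled, 2, max)), rep(1, ncol(prof$scaled)))

  # a cluster of identical events profiles to that event
  one <- structure(list(values = matrix(1, 5, 2), transformed = matrix(7, 5, 2),
                        sample_id = rep("s", 5), batch = rep("b", 5),
                        age_days = rep(1, 5), origin = rep("full", 5),
                        markers = c("x", "y")), class = "pooled_dataset")
  pa <- structure(list(cluster = rep(1L, 5), lineage = c("1" = "1"),
                       resolution = 1, seed = 1L, annotation = NULL),
                  class = "cluster_assignment")
  expect_equal(unname(cluster_profiles(pa, one)$mfi[1, ]), c(7, 7))
})
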