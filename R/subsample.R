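# Subsampling of pooled cytometry data: stratified random draws, geometric
# sketching (grid-cover sampling that enriches rare populations), the
# combination of the two, and the frequency-bias assessment that validates
# them against reference clusters.

#' @noRd
subsample_result <- function(indices, origin, n_target, seed) {
  stopifnot(!anyDuplicated(indices))
  structure(list(indices = as.integer(indices), origin = origin,
                 n_target = as.integer(n_target), seed = as.integer(seed)),
            class = "subsample_result")
}

#' @noRd
canonical_order <- function(X) {
  # event order defined by content, not row position: selection built on it
  # is equivariant under row permutation
  do.call(order, c(as.data.frame(X), list(method = "radix")))
}

#' Random subsample, stratified per sample
#'
#' Uniform sampling without replacement, stratified so that every sample
#' contributes proportionally to its size (largest-remainder apportionment of
#' the target across samples). Deterministic given the seed, and equivariant
#' under permutation of the input rows (selection keys attach to event
#' content, not row position).
#'
#' @param dataset a `pooled_dataset`.
#' @param n_target number of events to retain; if `>= n`, all events are
#'   returned.
#' @param seed integer seed.
#' @return a `subsample_result` with fields `indices`, `origin`, `n_target`,
#'   `seed`.
#' @export
random_subsample <- function(dataset, n_target, seed) {
  n <- nrow(dataset$values)
  if (n_target < 1) stopf("random_subsample: n_target must be >= 1")
  if (n_target >= n) {
    return(subsample_result(seq_len(n), rep("random", n), n_target, seed))
  }
  sid <- dataset$sample_id
  tab <- table(sid)
  quota <- as.numeric(tab) / n * n_target
  base <- floor(quota)
  rem <- n_target - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  names(base) <- names(tab)
  idx <- with_seed(seed, {
    unlist(lapply(sort(names(tab)), function(s) {
      pool <- which(sid == s)
      ord <- canonical_order(dataset$values[pool, , drop = FALSE])
      keys <- stats::runif(length(pool))
      m <- min(base[[s]], length(pool))
      pool[ord][order(keys)[seq_len(m)]]
    }), use.names = FALSE)
  })
  idx <- sort(idx)
  subsample_result(idx, rep("random", length(idx)), n_target, seed)
}

#' Geometric sketch
#'
#' Covers the data's geometry with equal-volume axis-aligned boxes and
#' samples one event per box, which enriches rare populations relative to
#' their abundance: project to `n_components` principal components, min-max
#' scale to the unit hypercube, binary-search a common box side length until
#' the number of occupied boxes approximates `n_target` (within 2% or 40
#' iterations; ties resolved toward the lower box count), then choose
#' `n_target` occupied boxes uniformly (all, if fewer) and one member event
#' per chosen box. Deterministic given the seed.
#'
#' @param dataset a `pooled_dataset`.
#' @param n_target sketch size; must be `< n`.
#' @param seed integer seed.
#' @param n_components number of principal components; default all markers.
#' @return a `subsample_result`.
#' @export
geometric_sketch <- function(dataset, n_target, seed,
                             n_components = ncol(dataset$values)) {
  X <- dataset$values
  n <- nrow(X)
  if (n_target >= n) stopf("geometric_sketch: n_target must be < n")
  if (n_components > ncol(X)) stopf("geometric_sketch: n_components > marker count")

  if (n_components < ncol(X)) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
    X <- pc$x
  }
  rng_lo <- apply(X, 2, min)
  rng_w <- pmax(apply(X, 2, max) - rng_lo, 1e-12)
  U <- sweep(sweep(X, 2, rng_lo), 2, rng_w, "/")

  # box membership: integer grid coordinates pasted into one key
  occupied <- function(delta) {
    g <- pmin(floor(U / delta), ceiling(1 / delta) - 1)
    id <- do.call(paste, c(as.data.frame(g), sep = ","))
    id
  }

  lo <- 1e-4; hi <- 1
  best <- NULL
  for (it in 1:40) {
    mid <- sqrt(lo * hi)
    id <- occupied(mid)
    k <- length(unique(id))
    if (is.null(best) ||
        abs(k - n_target) < abs(best$k - n_target) ||
        (abs(k - n_target) == abs(best$k - n_target) && k < best$k)) {
      best <- list(delta = mid, k = k, id = id)
    }
    if (abs(k - n_target) <= 0.02 * n_target) break
    if (k > n_target) lo <- mid else hi <- mid
  }

  idx <- with_seed(seed, {
    boxes <- sort(unique(best$id))
    chosen <- if (length(boxes) > n_target) sample(boxes, n_target) else boxes
    vapply(chosen, function(b) {
      members <- which(best$id == b)
      if (length(members) == 1) return(members)
      ord <- canonical_order(U[members, , drop = FALSE])
      members[ord][sample.int(length(members), 1)]
    }, integer(1), USE.NAMES = FALSE)
  })
  idx <- sort(idx)
  subsample_result(idx, rep("sketch", length(idx)), n_target, seed)
}

#' Combined random + sketch subsample
#'
#' Union of a stratified random draw and a geometric sketch; indices selected
#' by both carry origin `"both"`. By default the total budget is split 50:50.
#'
#' @param dataset a `pooled_dataset`.
#' @param n_random,n_sketch per-method budgets (`n_random + n_sketch >= 1`).
#' @param seed integer seed (fanned out per method).
#' @return a `subsample_result`.
#' @export
combined_subsample <- function(dataset, n_random, n_sketch, seed) {
  if (n_random + n_sketch < 1) stopf("combined_subsample: empty budget")
  r <- if (n_random > 0) random_subsample(dataset, n_random, derive_seed(seed, 1))
  s <- if (n_sketch > 0) geometric_sketch(dataset, n_sketch, derive_seed(seed, 2))
  ri <- if (is.null(r)) integer(0) else r$indices
  si <- if (is.null(s)) integer(0) else s$indices
  idx <- sort(union(ri, si))
  origin <- ifelse(idx %in% ri & idx %in% si, "both",
                   ifelse(idx %in% ri, "random", "sketch"))
  subsample_result(idx, origin, n_random + n_sketch, seed)
}

#' Assess subsampling-induced frequency bias
#'
#' Builds reference populations without using the planted truth: per sample,
#' events are split into 10 equal random bins and each bin is clustered by
#' k-means with `k = round(bin_size / 500)` (clamped to 1 with a warning for
#' small bins). Per reference cluster, the frequency in the full data and
#' within the subsample are compared; the coefficient of determination
#' (R-squared) of the after-vs-before linear fit quantifies the bias.
#'
#' @param dataset a `pooled_dataset`.
#' @param result a `subsample_result` over `dataset`.
#' @param seed integer seed for binning and k-means.
#' @param cells_per_cluster target reference-cluster size; default 500.
#' @param n_bins bins per sample; default 10.
#' @return class `bias_report`: data frame `clusters` (cluster, freq_before,
#'   freq_after) plus `r_squared`, `seed`.
#' @export
assess_subsampling_bias <- function(dataset, result, seed,
                                    cells_per_cluster = 500, n_bins = 10) {
  n <- nrow(dataset$values)
  stopifnot(all(result$indices >= 1), all(result$indices <= n))
  cl <- rep(NA_character_, n)
  with_seed(seed, {
    for (s in unique(dataset$sample_id)) {
      ix <- which(dataset$sample_id == s)
      bins <- sample(rep_len(seq_len(n_bins), length(ix)))
      for (b in seq_len(n_bins)) {
        bix <- ix[bins == b]
        if (!length(bix)) next
        k <- round(length(bix) / cells_per_cluster)
        if (k < 1) {
          warnf("assess_subsampling_bias: bin of %d events < %d; k clamped to 1",
                length(bix), cells_per_cluster)
          k <- 1
        }
        k <- min(k, length(bix))
        km <- if (k == 1) rep(1L, length(bix)) else {
          stats::kmeans(dataset$values[bix, , drop = FALSE], centers = k,
                        iter.max = 50, nstart = 1)$cluster
        }
        cl[bix] <- sprintf("%s_b%d_c%d", s, b, km)
      }
    }
  })
  levs <- sort(unique(cl))
  before <- as.numeric(table(factor(cl, levs))) / n
  inside <- cl[result$indices]
  after <- as.numeric(table(factor(inside, levs))) / length(inside)
  ss_tot <- sum((after - mean(after))^2)
  r2 <- if (ss_tot < 1e-24) {
    # degenerate: no spread in the reference frequencies; perfect iff equal
    as.numeric(max(abs(after - before)) < 1e-12)
  } else {
    # suppress summary.lm's note on an exactly perfect fit (identity subsample)
    suppressWarnings(summary(stats::lm(after ~ before))$r.squared)
  }
  structure(list(clusters = data.frame(cluster = levs, freq_before = before,
                                       freq_after = after),
                 r_squared = r2, seed = as.integer(seed)),
            class = "bias_report")
}

#' Export a bias report
#'
#' Writes the per-cluster frequency table as TSV and a JSON summary
#' (R-squared, seed, parameters).
#'
#' @param report a `bias_report`.
#' @param tsv_path,json_path output paths.
#' @export
write_bias_report <- function(report, tsv_path, json_path) {
  write_tsv_out(report$clusters, tsv_path)
  jsonlite::write_json(list(r_squared = report$r_squared, seed = report$seed,
                            n_clusters = nrow(report$clusters)),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
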