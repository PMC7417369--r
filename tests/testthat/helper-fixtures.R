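# Shared fixture builders: everything is generated in code at test time.

# small two-population pooled dataset with known structure
make_two_pop_dataset <- function(n = 1000, p_rare = 0.1, n_samples = 2,
                                 sep = 6, seed = 42) {
  withr::with_seed(seed, {
    lab <- sample(c("common", "rare"), n, replace = TRUE,
                  prob = c(1 - p_rare, p_rare))
    X <- matrix(rnorm(n * 3, 0, 1), n, 3)
    X[lab == "rare", ] <- X[lab == "rare", ] + sep
    colnames(X) <- c("m1", "m2", "m3")
    structure(
      list(values = scale(X), transformed = X,
           sample_id = rep(paste0("s", seq_len(n_samples)), length.out = n),
           batch = rep("day1", n), age_days = rep(100, n),
           origin = rep("full", n), markers = colnames(X),
           center = colMeans(X), scale = apply(X, 2, sd)),
      class = "pooled_dataset"
    ) -> ds
    attr(ds, "labels") <- lab
    ds
  })
}

# k well-separated Gaussian blobs as a pooled dataset; truth in attr "labels"
make_blob_dataset <- function(n_per = 200, centers = NULL, sd = 0.3,
                              seed = 7) {
  withr::with_seed(seed, {
    if (is.null(centers)) {
      centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10), c(5, 18))
    }
    k <- nrow(centers)
    n_per <- rep_len(n_per, k)
    X <- do.call(rbind, lapply(seq_len(k), function(i) {
      sweep(matrix(rnorm(n_per[i] * ncol(centers), 0, sd), n_per[i]), 2,
            centers[i, ], "+")
    }))
    colnames(X) <- paste0("m", seq_len(ncol(X)))
    lab <- rep(seq_len(k), n_per)
    ord <- sample(nrow(X))
    X <- X[ord, , drop = FALSE]; lab <- lab[ord]
    ds <- structure(
      list(values = X, transformed = X,
           sample_id = rep("s1", nrow(X)), batch = rep("day1", nrow(X)),
           age_days = rep(100, nrow(X)), origin = rep("full", nrow(X)),
           markers = colnames(X), center = colMeans(X),
           scale = apply(X, 2, sd)),
      class = "pooled_dataset"
    )
    attr(ds, "labels") <- lab
    ds
  })
}

# adjusted Rand index by brute-force pair counting
ari_pair_counting <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# tiny transformed-scale branch generator for transfer tests: CD1a-maturation
# structure shared by the CD4 and CD8b branches
make_branch <- function(n_per, branch = c("cd8", "cd4"), seed = 1) {
  branch <- match.arg(branch)
  withr::with_seed(seed, {
    lab <- rep(c("CD1a hi", "CD1a lo"), each = n_per)
    cd1a <- c(rnorm(n_per, 3.8, 0.15), rnorm(n_per, 2.4, 0.15))
    cd69 <- c(rnorm(n_per, 3.4, 0.15), rnorm(n_per, 0.8, 0.15))
    cd28 <- rnorm(2 * n_per, 3.4, 0.15)
    cd4 <- rnorm(2 * n_per, if (branch == "cd4") 3.5 else 0.8, 0.15)
    cd8 <- rnorm(2 * n_per, if (branch == "cd8") 3.5 else 0.8, 0.15)
    list(x = cbind(CD1a = cd1a, CD69 = cd69, CD28 = cd28),
         full = cbind(CD1a = cd1a, CD69 = cd69, CD28 = cd28,
                      CD4 = cd4, CD8b = cd8),
         labels = lab)
  })
}
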