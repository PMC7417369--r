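# Random subsampling, geometric sketching, their combination, and the
# frequency-bias assessment.

test_that("random subsampling saturates, is deterministic, and preserves frequencies", {
  ds <- make_two_pop_dataset(n = 20000, p_rare = 0.1, seed = 1)
  lab <- attr(ds, "labels")

  all_of_it <- random_subsample(ds, 1e6, seed = 5)
  expect_identical(all_of_it$indices, seq_len(20000))

  r1 <- random_subsample(ds, 5000, seed = 9)
  r2 <- random_subsample(ds, 5000, seed = 9)
  expect_identical(r1$indices, r2$indices)
  expect_length(r1$indices, 5000)
  expect_false(anyDuplicated(r1$indices) > 0)

  # 90/10 mixture, 50% subsample: inside the central 99% binomial band
  half <- random_subsample(ds, 10000, seed = 3)
  n_rare <- sum(lab[half$indices] == "rare")
  p_rare_true <- mean(lab == "rare")
  band <- qbinom(c(0.005, 0.995), 10000, p_rare_true)
  expect_gte(n_rare, band[1])
  expect_lte(n_rare, band[2])

  # stratification: each sample contributes proportionally
  contrib <- table(ds$sample_id[half$indices])
  expect_equal(as.numeric(contrib), rep(5000, 2), tolerance = 0.001)
})

test_that("random subsampling is unbiased over many seeds", {
  ds <- make_two_pop_dataset(n = 5000, p_rare = 0.1, seed = 2)
  lab <- attr(ds, "labels")
  p_true <- mean(lab == "rare")
  fr <- vapply(1:200, function(s) {
    idx <- random_subsample(ds, 1000, seed = s)$indices
    mean(lab[idx] == "rare")
  }, 0)
  # finite-population MC standard error of the mean over 200 draws
  se <- sd(fr) / sqrt(200)
  expect_lt(abs(mean(fr) - p_true), 3 * se + 1e-12)
})

test_that("geometric sketching covers distinct points and enriches rare blobs", {
  # k distinct points, n_target >= k: every point represented
  pts <- matrix(rep(c(0, 1, 2, 5, 9), each = 40), ncol = 1)
  ds <- make_two_pop_dataset(n = 200, seed = 3)
  ds$values <- cbind(pts, pts)
  sk <- geometric_sketch(ds, 150, seed = 1)
  expect_setequal(unique(ds$values[sk$indices, 1]), c(0, 1, 2, 5, 9))

  # output size approximates the target (box search stops within 2%) and
  # equals it exactly when occupied boxes exceed the target
  ds2 <- make_two_pop_dataset(n = 20000, p_rare = 0.01, sep = 8, seed = 4)
  sk2 <- geometric_sketch(ds2, 2000, seed = 2)
  expect_lte(abs(length(sk2$indices) - 2000), 0.02 * 2000)
  sk_small <- geometric_sketch(ds2, 500, seed = 2)
  expect_lte(length(sk_small$indices), 500)
  expect_gte(length(sk_small$indices), 490)

  # 99:1 blobs, 10% sketch: rare fraction at least doubles
  lab2 <- attr(ds2, "labels")
  rare_in <- mean(lab2 == "rare")
  rare_sk <- mean(lab2[sk2$indices] == "rare")
  expect_gte(rare_sk, 2 * rare_in)

  expect_error(geometric_sketch(ds2, 20000, seed = 1), "n_target")
})

test_that("sketch enrichment is monotone in rarity on equal-volume blobs", {
  withr::with_seed(8, {
    freqs <- c(0.70, 0.20, 0.07, 0.03)
    n <- 40000
    lab <- sample(seq_along(freqs), n, replace = TRUE, prob = freqs)
    centers <- rbind(c(0, 0), c(12, 0), c(0, 12), c(12, 12))
    X <- centers[lab, ] + matrix(rnorm(2 * n, 0, 0.5), n, 2)
    ds <- make_two_pop_dataset(n = 10, seed = 1)
    ds$values <- X; ds$transformed <- X
    ds$sample_id <- rep("s1", n); ds$batch <- rep("day1", n)
    ds$age_days <- rep(1, n); ds$origin <- rep("full", n)
    sk <- geometric_sketch(ds, 4000, seed = 5)
    enrich <- as.numeric(table(factor(lab[sk$indices], 1:4)) / 4000) / freqs
    expect_true(all(diff(enrich) > 0))  # rarer blobs gain more
    expect_lt(enrich[1], 1)             # the common blob loses
  })
})

test_that("subsampling is equivariant under permutation of event order", {
  ds <- make_two_pop_dataset(n = 4000, p_rare = 0.2, seed = 6)
  withr::with_seed(31, perm <- sample(4000))
  ds_perm <- ds
  ds_perm$values <- ds$values[perm, ]
  ds_perm$transformed <- ds$transformed[perm, ]
  ds_perm$sample_id <- ds$sample_id[perm]
  ds_perm$batch <- ds$batch[perm]
  ds_perm$age_days <- ds$age_days[perm]
  ds_perm$origin <- ds$origin[perm]

  r <- random_subsample(ds, 800, seed = 17)$indices
  rp <- random_subsample(ds_perm, 800, seed = 17)$indices
  expect_setequal(match(r, perm), rp)

  s <- geometric_sketch(ds, 800, seed = 17)$indices
  sp <- geometric_sketch(ds_perm, 800, seed = 17)$indices
  expect_setequal(match(s, perm), sp)
})

test_that("combined subsampling unions the draws and tags origins", {
  ds <- make_two_pop_dataset(n = 5000, seed = 5)
  cb <- combined_subsample(ds, 1000, 1000, seed = 4)
  expect_lte(length(cb$indices), 2000)
  expect_false(anyDuplicated(cb$indices) > 0)
  expect_setequal(unique(cb$origin), intersect(c("random", "sketch", "both"),
                                               unique(cb$origin)))

  # n_sketch = 0 degenerates to the stratified random draw
  cb0 <- combined_subsample(ds, 1000, 0, seed = 4)
  r <- random_subsample(ds, 1000, derive_seed(4, 1))
  expect_identical(cb0$indices, r$indices)
  expect_true(all(cb0$origin == "random"))

  # indices picked by both methods appear once, tagged "both"
  r_idx <- random_subsample(ds, 4900, derive_seed(4, 2))$indices
  s_idx <- geometric_sketch(ds, 4000, derive_seed(4, 3))$indices
  cb2 <- combined_subsample(ds, 4900, 4000, seed = 4)
  expect_false(anyDuplicated(cb2$indices) > 0)
  expect_true(any(cb2$origin == "both"))
})

test_that("bias assessment returns R2 = 1 for the identity subsample and matches the lm oracle", {
  ds <- make_two_pop_dataset(n = 20000, p_rare = 0.15, seed = 10)
  idn <- random_subsample(ds, 20000, seed = 1)
  rep_id <- assess_subsampling_bias(ds, idn, seed = 2)
  expect_equal(rep_id$r_squared, 1)
  expect_equal(rep_id$clusters$freq_before, rep_id$clusters$freq_after)

  half <- random_subsample(ds, 10000, seed = 3)
  rep_half <- assess_subsampling_bias(ds, half, seed = 2)
  expect_true(all(abs(rep_half$clusters$freq_before) <= 1),
              all(rep_half$clusters$freq_before >= 0))
  expect_equal(sum(rep_half$clusters$freq_before), 1, tolerance = 1e-12)
  expect_equal(sum(rep_half$clusters$freq_after), 1, tolerance = 1e-12)

  # definitional oracle: R2 = 1 - SSres/SStot of the least-squares line
  x <- rep_half$clusters$freq_before; y <- rep_half$clusters$freq_after
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  ss_res <- sum((y - alpha - beta * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(rep_half$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)

  # small bins clamp k to 1 with a warning (one per tiny bin)
  tiny <- make_two_pop_dataset(n = 300, seed = 11)
  warns <- capture_warnings(
    assess_subsampling_bias(tiny, random_subsample(tiny, 150, 1), seed = 1))
  expect_true(all(grepl("clamped", warns)))
  expect_gt(length(warns), 0)

  # report export
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_bias_report(rep_half, tsv, js)
  expect_equal(jsonlite::read_json(js)$r_squared, rep_half$r_squared)
})
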